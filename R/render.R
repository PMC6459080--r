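#' Render a pre/post-lodging DEM pair for a synthetic field
#'
#' The pre-lodging surface is a flat ground plane at elevation zero, plus a
#' per-plot standing canopy height inside each plot polygon, plus i.i.d.
#' pixel noise.  The post-lodging surface adds the between-flight growth
#' offset to every plot pixel and subtracts the plot's mean canopy drop on a
#' spatially contiguous lodged patch covering `lodged_fraction` of the
#' plot's pixels, placed at a seeded random end of the plot; alleys between
#' plots stay at ground level.  Pre and post carry independent pixel noise
#' (two flights), so the expected differential of a plot pixel is
#' `lodged * mean_drop - growth_offset`.
#'
#' @param layout A `field_layout`.
#' @param lodging A `true_lodging` data.frame from [simulate_plot_lodging()].
#' @param config A [sim_config()] object.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List with elements `pre` and `post`, both `dem_raster`.
#' @export
render_dem_pair <- function(layout, lodging, config, seed = config$seed) {
  validate_sim_config(config)
  px <- config$pixel_size_m
  ppp <- floor(config$plot_width_m / px) * floor(config$plot_length_m / px)
  if (ppp < 25) {
    stop("pixel_size_m too coarse: ", ppp,
         " pixels per plot (< 25); refine the grid")
  }
  ext <- layout_extent(layout, config)
  nc <- ceiling((ext["x_max"] - ext["x_min"]) / px)
  nr <- ceiling((ext["y_max"] - ext["y_min"]) / px)

  set.seed(stage_seed(seed, "raster"))
  pre_sig <- matrix(0, nr, nc)
  post_sig <- matrix(0, nr, nc)

  xc <- ext[["x_min"]] + (seq_len(nc) - 0.5) * px
  yc <- ext[["y_min"]] + (nr - seq_len(nr) + 0.5) * px  # row 1 = north

  st <- lodging[match(layout$plot_id, lodging$plot_id), ]
  for (i in seq_len(nrow(layout))) {
    cols <- which(xc > layout$x_min[i] & xc < layout$x_max[i])
    rows <- which(yc > layout$y_min[i] & yc < layout$y_max[i])
    if (length(cols) == 0 || length(rows) == 0) next
    h <- st$canopy_height[i]
    pre_sig[rows, cols] <- h
    post_plot <- matrix(h + config$growth_offset_m,
                        length(rows), length(cols))
    n_pix <- length(rows) * length(cols)
    n_lodged <- round(st$lodged_fraction[i] * n_pix)
    if (n_lodged > 0) {
      # contiguous patch filled row by row from a seeded random end of the
      # plot (lodging is spatially clustered in the field)
      from_south <- stats::runif(1) < 0.5
      ord <- if (from_south) rev(seq_along(rows)) else seq_along(rows)
      flat <- as.vector(t(post_plot[ord, , drop = FALSE]))
      flat[seq_len(n_lodged)] <- flat[seq_len(n_lodged)] - st$mean_drop[i]
      post_plot[ord, ] <- matrix(flat, length(rows), length(cols),
                                 byrow = TRUE)
    }
    post_sig[rows, cols] <- post_plot
  }

  sd <- config$pixel_noise_sd_m
  pre <- pre_sig + if (sd > 0) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
                   else 0
  post <- post_sig + if (sd > 0) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
                     else 0
  list(pre = dem_raster(pre, xll = ext[["x_min"]], yll = ext[["y_min"]],
                        pixel_size = px),
       post = dem_raster(post, xll = ext[["x_min"]], yll = ext[["y_min"]],
                         pixel_size = px))
}

#' Simulate a complete synthetic field study
#'
#' Convenience wrapper chaining the layout, genotype, breeding-value,
#' lodging, raster, visual-score and tag-count generators under one root
#' seed.
#'
#' @param config A [sim_config()] object.
#' @param render Logical; render the DEM pair (default TRUE).  Skipping the
#'   rasters is useful for purely genetic simulations.
#' @param prop_2ns Proportion of lines carrying the alien segment
#'   (default 0.75).
#' @param tag_depth Tag depth for [simulate_tag_counts()] (default 100).
#' @return List of class `synthetic_field` with `config`, `layout`,
#'   `genotypes`, `breeding_values`, `lodging`, `visual`, `tags`, and (if
#'   rendered) `pre`/`post` rasters.
#' @export
simulate_field <- function(config, render = TRUE, prop_2ns = 0.75,
                           tag_depth = 100L) {
  validate_sim_config(config)
  layout <- build_alpha_lattice_layout(config)
  G <- simulate_genotypes(config)
  bv <- simulate_breeding_values(G, h2 = config$h2_lodging,
                                 n_qtl = config$n_qtl,
                                 major_effect = config$major_locus_effect,
                                 seed = config$seed)
  lodging <- simulate_plot_lodging(layout, bv, config)
  visual <- simulate_visual_scores(lodging, config)
  set.seed(stage_seed(config$seed, "tags"))
  line_ids <- rownames(G$calls)
  true_2ns <- stats::runif(length(line_ids)) < prop_2ns
  tags <- simulate_tag_counts(line_ids, true_2ns, depth = tag_depth,
                              seed = config$seed)
  out <- list(config = config, layout = layout, genotypes = G,
              breeding_values = bv, lodging = lodging, visual = visual,
              tags = tags)
  if (render) {
    dems <- render_dem_pair(layout, lodging, config)
    out$pre <- dems$pre
    out$post <- dems$post
  }
  class(out) <- "synthetic_field"
  out
}
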