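#' Build an alpha-lattice field layout
#'
#' Lays the configured trials out on a rectangular plot grid and randomises
#' entries to plots within each replicate under the seed.  Trials sit side by
#' side along the column (x) axis; within a trial the replicate blocks are
#' stacked along the range (y) axis and each range is one sub-block of
#' `plots_per_subblock` plots.  Checks are shared across trials; non-check
#' entries are unique to their trial, so leaving one trial out removes a
#' whole family group.
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame` (class `field_layout`) with one row per plot:
#'   `plot_id`, `trial`, `rep`, `subblock`, `entry_id`, `is_check`,
#'   `range_idx`, `col_idx` and the plot rectangle corners
#'   `x_min`, `x_max`, `y_min`, `y_max` in meters (local planar CRS).
#' @export
build_alpha_lattice_layout <- function(config) {
  validate_sim_config(config)
  c0 <- config
  per_rep <- c0$subblocks_per_rep * c0$plots_per_subblock

  checks <- if (c0$checks_per_trial > 0) {
    sprintf("CHK%02d", seq_len(c0$checks_per_trial))
  } else character(0)

  pitch_x <- c0$plot_width_m + c0$gap_col_m
  pitch_y <- c0$plot_length_m + c0$gap_range_m

  set.seed(stage_seed(c0$seed, "layout"))
  rows <- vector("list", c0$n_trials * c0$n_reps)
  k <- 0L
  for (t in seq_len(c0$n_trials)) {
    entries <- if (c0$entries_per_trial > 0) {
      sprintf("T%02dE%02d", t, seq_len(c0$entries_per_trial))
    } else character(0)
    pool <- c(entries, checks)
    for (r in seq_len(c0$n_reps)) {
      placed <- sample(pool, length(pool), replace = FALSE)
      plot_in_rep <- seq_len(per_rep)
      subblock <- ((plot_in_rep - 1L) %/% c0$plots_per_subblock) + 1L
      pos <- ((plot_in_rep - 1L) %% c0$plots_per_subblock) + 1L
      range_idx <- (r - 1L) * c0$subblocks_per_rep + subblock
      col_idx <- (t - 1L) * c0$plots_per_subblock + pos
      k <- k + 1L
      rows[[k]] <- data.frame(
        trial = t, rep = r, subblock = subblock,
        entry_id = placed, is_check = placed %in% checks,
        range_idx = range_idx, col_idx = col_idx,
        stringsAsFactors = FALSE
      )
    }
  }
  layout <- do.call(rbind, rows)
  layout$plot_id <- sprintf("P%04d", seq_len(nrow(layout)))
  # rectangle corners; gaps are split evenly around each plot
  layout$x_min <- (layout$col_idx - 1L) * pitch_x + c0$gap_col_m / 2
  layout$x_max <- layout$x_min + c0$plot_width_m
  layout$y_min <- (layout$range_idx - 1L) * pitch_y + c0$gap_range_m / 2
  layout$y_max <- layout$y_min + c0$plot_length_m
  layout <- layout[, c("plot_id", "trial", "rep", "subblock", "entry_id",
                       "is_check", "range_idx", "col_idx",
                       "x_min", "x_max", "y_min", "y_max")]
  rownames(layout) <- NULL
  class(layout) <- c("field_layout", "data.frame")
  layout
}

#' Field extent implied by a layout
#'
#' @param layout A `field_layout`.
#' @param config The [sim_config()] the layout was built from.
#' @return Named vector `c(x_min, x_max, y_min, y_max)` in meters, including
#'   the outer half-gaps so every polygon is interior to the extent.
#' @export
layout_extent <- function(layout, config) {
  c(x_min = 0,
    x_max = max(layout$x_max) + config$gap_col_m / 2,
    y_min = 0,
    y_max = max(layout$y_max) + config$gap_range_m / 2)
}

#' Plot polygons as a coordinate list
#'
#' @param layout A `field_layout`.
#' @return Named list (by `plot_id`) of 4x2 corner matrices in
#'   counter-clockwise order.
#' @export
layout_polygons <- function(layout) {
  polys <- lapply(seq_len(nrow(layout)), function(i) {
    with(layout[i, ], matrix(c(x_min, y_min,
                               x_max, y_min,
                               x_max, y_max,
                               x_min, y_max),
                             ncol = 2, byrow = TRUE,
                             dimnames = list(NULL, c("x", "y"))))
  })
  names(polys) <- layout$plot_id
  polys
}

#' Write plot polygons as GeoJSON
#'
#' One Feature per plot with the design factors as properties; coordinates
#' are in the local planar frame (meters).
#'
#' @param layout A `field_layout`.
#' @param path Output `.geojson` path.
#' @export
write_plots_geojson <- function(layout, path) {
  feats <- lapply(seq_len(nrow(layout)), function(i) {
    row <- layout[i, ]
    ring <- list(c(row$x_min, row$y_min), c(row$x_max, row$y_min),
                 c(row$x_max, row$y_max), c(row$x_min, row$y_max),
                 c(row$x_min, row$y_min))
    list(
      type = "Feature",
      properties = list(plot_id = row$plot_id, trial = row$trial,
                        rep = row$rep, subblock = row$subblock,
                        entry_id = row$entry_id, is_check = row$is_check,
                        range_idx = row$range_idx, col_idx = row$col_idx),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read plot polygons from GeoJSON
#'
#' Inverse of [write_plots_geojson()]: expects rectangular plot features with
#' the design-factor properties.
#'
#' @param path GeoJSON path.
#' @return A `field_layout` data.frame.
#' @export
read_plots_geojson <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(fc$type) || fc$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection: ", path)
  }
  rows <- lapply(fc$features, function(f) {
    p <- f$properties
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(pt) as.numeric(pt[[1]]), numeric(1))
    ys <- vapply(ring, function(pt) as.numeric(pt[[2]]), numeric(1))
    data.frame(plot_id = p$plot_id, trial = p$trial, rep = p$rep,
               subblock = p$subblock, entry_id = p$entry_id,
               is_check = isTRUE(p$is_check),
               range_idx = p$range_idx, col_idx = p$col_idx,
               x_min = min(xs), x_max = max(xs),
               y_min = min(ys), y_max = max(ys),
               stringsAsFactors = FALSE)
  })
  layout <- do.call(rbind, rows)
  class(layout) <- c("field_layout", "data.frame")
  layout
}
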