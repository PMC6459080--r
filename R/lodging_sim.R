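#' Simulate true plot-level lodging states
#'
#' Plot liability = entry breeding value + replicate effect + sub-block
#' effect + residual.  The residual variance is set from the configured
#' entry-mean heritability: `sigma2_e = n_reps * (1 - h2) / h2 * sigma2_G`,
#' so that `sigma2_G / (sigma2_G + sigma2_e / n_reps) = h2` exactly (when
#' `h2 = 0` the genetic values are zero and `sigma2_e = 1`).  Liability maps
#' monotonically to the lodged area fraction through a logistic with slope
#' `config$liability_slope`, and to a severity angle through a clipped
#' linear map (45 + 20 x liability, clamped to `[0, 90]` degrees).  The mean
#' canopy drop of lodged pixels is `canopy_height * (1 - cos(angle))`.
#'
#' @param layout A `field_layout`.
#' @param bv A `breeding_values` object (or a named numeric liability
#'   vector covering every `entry_id`).
#' @param config A [sim_config()] object.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return data.frame of class `true_lodging`: one row per plot with
#'   `plot_id`, `entry_id`, `liability`, `lodged_fraction`,
#'   `severity_angle`, `canopy_height`, `mean_drop` and
#'   `true_dl = lodged_fraction * mean_drop` (the quantity both digital
#'   measures estimate).
#' @export
simulate_plot_lodging <- function(layout, bv, config, seed = config$seed) {
  validate_sim_config(config)
  u <- if (inherits(bv, "breeding_values")) bv$u else bv
  sigma2_G <- if (inherits(bv, "breeding_values")) bv$sigma2_G
              else stats::var(u)
  h2 <- config$h2_lodging
  missing_entries <- setdiff(unique(layout$entry_id), names(u))
  if (length(missing_entries) > 0) {
    stop("no breeding value for entries: ",
         paste(utils::head(missing_entries, 5), collapse = ", "))
  }
  sigma2_e <- if (h2 <= 0 || sigma2_G == 0) 1
              else if (h2 >= 1) 0
              else config$n_reps * (1 - h2) / h2 * sigma2_G

  set.seed(stage_seed(seed, "lodging"))
  rep_key <- interaction(layout$trial, layout$rep, drop = TRUE)
  sub_key <- interaction(layout$trial, layout$rep, layout$subblock,
                         drop = TRUE)
  rep_eff <- stats::rnorm(nlevels(rep_key), 0, sqrt(config$sigma2_rep))
  sub_eff <- stats::rnorm(nlevels(sub_key), 0, sqrt(config$sigma2_subblock))
  resid <- stats::rnorm(nrow(layout), 0, sqrt(sigma2_e))

  liab <- u[layout$entry_id] + rep_eff[as.integer(rep_key)] +
    sub_eff[as.integer(sub_key)] + resid
  lodged_fraction <- stats::plogis(config$liability_slope *
                                     (liab - config$liability_center))
  severity_angle <- pmin(90, pmax(0, 45 + 20 * liab))
  canopy <- pmax(0.2, stats::rnorm(nrow(layout), config$canopy_height_m,
                                   config$canopy_height_sd_m))
  mean_drop <- canopy * (1 - cos(severity_angle * pi / 180))
  mean_drop[lodged_fraction == 0] <- 0

  out <- data.frame(plot_id = layout$plot_id, entry_id = layout$entry_id,
                    liability = as.numeric(liab),
                    lodged_fraction = lodged_fraction,
                    severity_angle = severity_angle,
                    canopy_height = canopy, mean_drop = mean_drop,
                    true_dl = lodged_fraction * mean_drop,
                    stringsAsFactors = FALSE)
  class(out) <- c("true_lodging", "data.frame")
  out
}

#' Simulate observer visual lodging scores
#'
#' Emulates ground-truth scoring: lodging incidence
#' `LOI = 100 x lodged_fraction + noise`, rounded to the nearest 5 and
#' clipped to `[0, 100]`; severity `LOS = severity_angle / 9 + noise`,
#' rounded to integer and clipped to `[0, 10]`; and the combined index
#' `LI = LOI x LOS`.
#'
#' @param lodging A `true_lodging` data.frame.
#' @param config A [sim_config()] object (observer noise sds).
#' @param seed Integer seed (defaults to `config$seed`).
#' @return data.frame: `plot_id`, `LOI`, `LOS`, `LI`.
#' @export
simulate_visual_scores <- function(lodging, config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(stage_seed(seed, "visual"))
  n <- nrow(lodging)
  loi_raw <- 100 * lodging$lodged_fraction +
    stats::rnorm(n, 0, config$loi_noise_sd)
  LOI <- pmin(100, pmax(0, 5 * round(loi_raw / 5)))
  los_raw <- lodging$severity_angle / 9 + stats::rnorm(n, 0, config$los_noise_sd)
  LOS <- pmin(10, pmax(0, round(los_raw)))
  data.frame(plot_id = lodging$plot_id, LOI = LOI, LOS = LOS,
             LI = LOI * LOS, stringsAsFactors = FALSE)
}
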