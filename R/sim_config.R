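#' Simulation configuration for a synthetic lodging field study
#'
#' Builds and validates the configuration object used by the synthetic-field
#' generator.  Defaults reproduce the study design the package emulates:
#' 11 trials of 53 entries plus 7 shared checks, two complete replicate
#' blocks of 120 plots per trial, each replicate split into six sub-blocks
#' of 10 plots, 1.3 m x 3.8 m plots with 52 cm / 80 cm column and range
#' gaps, for 1,320 plots in total.
#'
#' @param seed Integer root seed; every stochastic stage derives its own
#'   stream from it.
#' @param n_trials Number of trials (default 11).
#' @param entries_per_trial Unique (non-check) entries per trial (default 53).
#' @param checks_per_trial Check varieties repeated in every trial (default 7).
#' @param n_reps Complete replicate blocks per trial (default 2).
#' @param subblocks_per_rep Incomplete sub-blocks per replicate (default 6).
#' @param plots_per_subblock Plots per sub-block (default 10).
#' @param plot_length_m,plot_width_m Plot dimensions in meters
#'   (defaults 3.8, 1.3).
#' @param gap_range_m,gap_col_m Plot-to-plot gaps between ranges and columns
#'   in meters (defaults 0.80, 0.52).
#' @param pixel_size_m Raster ground-sampling distance in meters
#'   (default 0.03).
#' @param n_markers Number of simulated SNP markers.
#' @param maf_range Interval in (0, 0.5] for base minor-allele frequencies.
#' @param missing_rate,het_rate Per-call missing and heterozygous rates used
#'   when exercising the marker QC filters (defaults 0).
#' @param fst Trial-level allele-frequency divergence (Balding-Nichols style)
#'   making within-trial relatedness exceed between-trial (default 0.05).
#' @param h2_lodging Target entry-mean heritability of the lodging liability
#'   at `n_reps` replicates, in `[0, 1]` (default 0.6).
#' @param n_qtl Number of causal markers for the polygenic liability.
#' @param major_locus_effect Liability-scale effect of one designated
#'   alien-segment-like locus (default 0 = absent).
#' @param growth_offset_m Uniform canopy growth between the two flights in
#'   meters, applied to every pixel (default 0; the study design leaves the
#'   two-week growth correction open, so it is exposed as a probe).
#' @param canopy_height_m,canopy_height_sd_m Mean and between-plot sd of
#'   standing canopy height in meters (defaults 1.0, 0.05).
#' @param pixel_noise_sd_m Per-pixel elevation noise sd in meters
#'   (default 0.03, the coarser of the two reported DEM resolutions).
#' @param loi_noise_sd Observer noise sd on the visual incidence score, in
#'   percent points (default 5).
#' @param los_noise_sd Observer noise sd on the visual severity score, in
#'   score points (default 0.5).
#' @param sigma2_rep,sigma2_subblock Variances of the replicate and sub-block
#'   spatial effects on the liability scale (defaults 0.1, 0.1).
#' @param liability_slope Slope of the logistic liability-to-lodged-fraction
#'   map (default 1).
#' @param liability_center Liability at which half the plot area lodges
#'   (default 0; raise it to simulate milder or absent lodging events).
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_trials = 11L,
                       entries_per_trial = 53L,
                       checks_per_trial = 7L,
                       n_reps = 2L,
                       subblocks_per_rep = 6L,
                       plots_per_subblock = 10L,
                       plot_length_m = 3.8,
                       plot_width_m = 1.3,
                       gap_range_m = 0.80,
                       gap_col_m = 0.52,
                       pixel_size_m = 0.03,
                       n_markers = 1000L,
                       maf_range = c(0.05, 0.5),
                       missing_rate = 0,
                       het_rate = 0,
                       fst = 0.05,
                       h2_lodging = 0.6,
                       n_qtl = 100L,
                       major_locus_effect = 0,
                       growth_offset_m = 0,
                       canopy_height_m = 1.0,
                       canopy_height_sd_m = 0.05,
                       pixel_noise_sd_m = 0.03,
                       loi_noise_sd = 5,
                       los_noise_sd = 0.5,
                       sigma2_rep = 0.1,
                       sigma2_subblock = 0.1,
                       liability_slope = 1,
                       liability_center = 0) {
  cfg <- list(
    seed = as.integer(seed),
    n_trials = as.integer(n_trials),
    entries_per_trial = as.integer(entries_per_trial),
    checks_per_trial = as.integer(checks_per_trial),
    n_reps = as.integer(n_reps),
    subblocks_per_rep = as.integer(subblocks_per_rep),
    plots_per_subblock = as.integer(plots_per_subblock),
    plot_length_m = plot_length_m,
    plot_width_m = plot_width_m,
    gap_range_m = gap_range_m,
    gap_col_m = gap_col_m,
    pixel_size_m = pixel_size_m,
    n_markers = as.integer(n_markers),
    maf_range = as.numeric(maf_range),
    missing_rate = missing_rate,
    het_rate = het_rate,
    fst = fst,
    h2_lodging = h2_lodging,
    n_qtl = as.integer(n_qtl),
    major_locus_effect = major_locus_effect,
    growth_offset_m = growth_offset_m,
    canopy_height_m = canopy_height_m,
    canopy_height_sd_m = canopy_height_sd_m,
    pixel_noise_sd_m = pixel_noise_sd_m,
    loi_noise_sd = loi_noise_sd,
    los_noise_sd = los_noise_sd,
    sigma2_rep = sigma2_rep,
    sigma2_subblock = sigma2_subblock,
    liability_slope = liability_slope,
    liability_center = liability_center
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with(cfg, {
    if (length(seed) != 1L || is.na(seed)) stop("seed must be a single integer")
    counts <- c(n_trials, entries_per_trial, checks_per_trial, n_reps,
                subblocks_per_rep, plots_per_subblock, n_markers, n_qtl)
    if (any(counts < 0L)) stop("counts must be non-negative")
    if (n_trials < 1L || n_reps < 1L) stop("need at least one trial and rep")
    per_rep <- subblocks_per_rep * plots_per_subblock
    if (entries_per_trial + checks_per_trial != per_rep) {
      stop("entries_per_trial + checks_per_trial (",
           entries_per_trial + checks_per_trial,
           ") must equal subblocks_per_rep * plots_per_subblock (",
           per_rep, ")")
    }
    lens <- c(plot_length_m, plot_width_m, gap_range_m, gap_col_m,
              pixel_size_m, canopy_height_m, canopy_height_sd_m,
              pixel_noise_sd_m, loi_noise_sd, los_noise_sd,
              sigma2_rep, sigma2_subblock)
    if (any(!is.finite(lens)) || any(lens < 0)) {
      stop("lengths, noise and variance parameters must be finite and >= 0")
    }
    if (pixel_size_m <= 0 || plot_length_m <= 0 || plot_width_m <= 0) {
      stop("plot dimensions and pixel size must be positive")
    }
    if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2]) {
      stop("maf_range must be an interval within (0, 0.5]")
    }
    if (h2_lodging < 0 || h2_lodging > 1) stop("h2_lodging must be in [0, 1]")
    for (p in c(missing_rate, het_rate, fst)) {
      if (p < 0 || p >= 1) stop("rates must be in [0, 1)")
    }
  })
  invisible(cfg)
}

# Derive a per-stage seed from the root seed. Offsets are fixed per stage so
# that stages are independent but the whole run is reproducible from one
# integer; kept below 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(layout = 101L, genotypes = 211L, breeding = 307L,
               lodging = 401L, raster = 503L, visual = 601L,
               tags = 701L, gwas = 809L, predict = 907L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}
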