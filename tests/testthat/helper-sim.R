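# Shared fixtures, all generated in code.

# Small field config: 2 trials, coarse 10 cm pixels (494 px/plot), few
# markers; fast enough for repeated end-to-end runs.
small_config <- function(seed = 7, ...) {
  sim_config(seed = seed, n_trials = 2, n_markers = 150,
             pixel_size_m = 0.1, ...)
}

# Inbred-style random marker matrix without population structure.
random_markers <- function(n, m, seed = 1) {
  set.seed(seed)
  matrix(sample(c(-1L, 1L), n * m, replace = TRUE), n, m,
         dimnames = list(sprintf("L%04d", seq_len(n)),
                         sprintf("M%04d", seq_len(m))))
}

# Hardy-Weinberg outbred genotypes (het calls present) for kinship checks.
hwe_markers <- function(n, m, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.5)
  g <- vapply(seq_len(m),
              function(j) rbinom(n, 2L, p[j]) - 1L,
              integer(n))
  dimnames(g) <- list(sprintf("L%04d", seq_len(n)),
                      sprintf("M%04d", seq_len(m)))
  g
}

# Polygenic trait on a marker matrix; returns y (named) and heritability.
polygenic_trait <- function(W, h2 = 0.6, seed = 1) {
  set.seed(seed)
  beta <- rnorm(ncol(W), 0, 1)
  g <- drop(W %*% beta)
  g <- (g - mean(g)) / sd(g)
  y <- g + rnorm(nrow(W), 0, sqrt((1 - h2) / h2))
  names(y) <- rownames(W)
  list(y = y, g = g, h2 = h2)
}

# Hand-built one-plot layout + true lodging state for raster unit tests.
one_plot_layout <- function(frac, drop, canopy = 1, plot_w = 1.3,
                            plot_l = 3.8) {
  layout <- data.frame(plot_id = "P0001", trial = 1L, rep = 1L,
                       subblock = 1L, entry_id = "E1", is_check = FALSE,
                       range_idx = 1L, col_idx = 1L,
                       x_min = 0.26, x_max = 0.26 + plot_w,
                       y_min = 0.4, y_max = 0.4 + plot_l,
                       stringsAsFactors = FALSE)
  class(layout) <- c("field_layout", "data.frame")
  lodging <- data.frame(plot_id = "P0001", entry_id = "E1", liability = 0,
                        lodged_fraction = frac, severity_angle = 45,
                        canopy_height = canopy, mean_drop = drop,
                        true_dl = frac * drop, stringsAsFactors = FALSE)
  list(layout = layout, lodging = lodging)
}
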