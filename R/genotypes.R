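#' Simulate a line x marker genotype matrix with trial structure
#'
#' Markers are biallelic with base minor-allele frequencies drawn uniformly
#' from `config$maf_range`.  Lines belong to trials (families); each trial
#' draws its own marker allele frequencies around the base frequency with a
#' Balding-Nichols Beta model at divergence `config$fst`, so that
#' within-trial relatedness exceeds between-trial relatedness and
#' leave-one-trial-out cross-validation is genuinely harder than random
#' folds.  Calls are coded -1/0/1 (0 = heterozygous) with `NA` as the
#' missing sentinel; optional `missing_rate` and `het_rate` exist to
#' exercise the marker QC filters.
#'
#' @param config A [sim_config()] object.
#' @param line_ids Optional character vector of line names; defaults to the
#'   entries and checks implied by the design.  When supplied, lines are
#'   split into `config$n_trials` contiguous trial groups.
#' @return A list of class `genotype_matrix`: `calls` (lines x markers
#'   integer matrix), `map` (marker_id, chrom, pos), `line_trial` (named
#'   integer; 0 marks check lines present in every trial).
#' @export
simulate_genotypes <- function(config, line_ids = NULL) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "genotypes"))
  if (is.null(line_ids)) {
    entries <- unlist(lapply(seq_len(config$n_trials), function(t) {
      if (config$entries_per_trial > 0)
        sprintf("T%02dE%02d", t, seq_len(config$entries_per_trial))
      else character(0)
    }))
    checks <- if (config$checks_per_trial > 0)
      sprintf("CHK%02d", seq_len(config$checks_per_trial)) else character(0)
    line_ids <- c(entries, checks)
    line_trial <- c(rep(seq_len(config$n_trials),
                        each = config$entries_per_trial),
                    rep(0L, length(checks)))
  } else {
    line_trial <- as.integer(cut(seq_along(line_ids), config$n_trials,
                                 labels = FALSE))
  }
  names(line_trial) <- line_ids
  n <- length(line_ids)
  m <- config$n_markers

  p_base <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  calls <- matrix(NA_integer_, n, m,
                  dimnames = list(line_ids, sprintf("M%05d", seq_len(m))))
  fst <- config$fst
  groups <- split(seq_len(n), line_trial)
  for (g in names(groups)) {
    idx <- groups[[g]]
    p_g <- if (g == "0" || fst <= 0) p_base else {
      shape <- (1 - fst) / fst
      stats::rbeta(m, p_base * shape, (1 - p_base) * shape)
    }
    # inbred lines: homozygous -1/+1 draws at the trial allele frequency
    draws <- matrix(stats::rbinom(length(idx) * m, 1,
                                  rep(p_g, each = length(idx))),
                    length(idx), m)
    calls[idx, ] <- 2L * draws - 1L
  }
  if (config$het_rate > 0) {
    het <- matrix(stats::runif(n * m) < config$het_rate, n, m)
    calls[het] <- 0L
  }
  if (config$missing_rate > 0) {
    mis <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
    calls[mis] <- NA_integer_
  }
  # enforce polymorphism: flip one call on any monomorphic marker
  for (j in seq_len(m)) {
    obs <- calls[, j][!is.na(calls[, j])]
    if (length(obs) > 0 && length(unique(obs)) == 1L) {
      i <- sample(which(!is.na(calls[, j])), 1L)
      calls[i, j] <- if (obs[1] == 1L) -1L else 1L
    }
  }
  chrom <- rep(seq_len(21L), length.out = m)
  pos <- stats::ave(seq_len(m), chrom, FUN = seq_along) * 1e6
  map <- data.frame(marker_id = colnames(calls), chrom = chrom, pos = pos,
                    stringsAsFactors = FALSE)
  structure(list(calls = calls, map = map, line_trial = line_trial),
            class = "genotype_matrix")
}

#' Simulate additive breeding values (lodging liability)
#'
#' Draws `n_qtl` causal markers with normal effects, builds additive values
#' `u = W beta`, optionally loads one designated marker with a large
#' alien-segment-like effect, and standardises `u` to unit genetic variance
#' so that the residual model in [simulate_plot_lodging()] delivers the
#' configured entry-mean heritability.  With `h2 = 0` all values are exactly
#' zero (no genetic variance).
#'
#' @param G A `genotype_matrix`.
#' @param h2 Target entry-mean heritability in `[0, 1]`.
#' @param n_qtl Number of causal markers.
#' @param major_effect Liability effect of the designated major locus
#'   (0 = no major locus).
#' @param seed Integer seed.
#' @return List of class `breeding_values`: `u` (named liability per line,
#'   variance 1 when `h2 > 0`), `beta` (per-marker true effects on the
#'   standardised scale), `qtl` (marker ids), `major_marker` (id or `NA`),
#'   `sigma2_G`, `h2`.
#' @export
simulate_breeding_values <- function(G, h2, n_qtl, major_effect = 0,
                                     seed = 1L) {
  stopifnot(inherits(G, "genotype_matrix"), h2 >= 0, h2 <= 1, n_qtl >= 1)
  set.seed(stage_seed(seed, "breeding"))
  W <- G$calls
  W[is.na(W)] <- 0L
  m <- ncol(W)
  n_qtl <- min(n_qtl, m)
  qtl <- sort(sample.int(m, n_qtl))
  beta <- numeric(m)
  beta[qtl] <- stats::rnorm(n_qtl)
  major_marker <- NA_character_
  if (major_effect != 0) {
    beta[qtl[1]] <- beta[qtl[1]] + major_effect
    major_marker <- colnames(W)[qtl[1]]
  }
  u <- drop(W %*% beta)
  v <- stats::var(u)
  if (h2 == 0 || v == 0) {
    u <- u * 0
    beta <- beta * 0
    sigma2_G <- 0
  } else {
    u <- (u - mean(u)) / sqrt(v)
    beta <- beta / sqrt(v)
    sigma2_G <- 1
  }
  names(u) <- rownames(W)
  structure(list(u = u, beta = beta, qtl = colnames(W)[qtl],
                 major_marker = major_marker, sigma2_G = sigma2_G, h2 = h2),
            class = "breeding_values")
}

#' Simulate alien/wheat diagnostic tag counts
#'
#' Lines carrying the alien segment draw alien-specific tag counts from
#' `Binomial(depth, p_pos)`; non-carriers from `Binomial(depth, p_neg)`;
#' wheat counts are the complement.
#'
#' @param line_ids Character vector of line names.
#' @param true_2ns Logical vector, carrier status per line.
#' @param depth Total tag depth per line (scalar or per line).
#' @param seed Integer seed.
#' @param p_pos,p_neg Alien-tag probabilities for carriers / non-carriers
#'   (defaults 0.95, 0.02).
#' @return data.frame: `line_id`, `alien_count`, `wheat_count`, `true_2ns`.
#' @export
simulate_tag_counts <- function(line_ids, true_2ns, depth = 100L, seed = 1L,
                                p_pos = 0.95, p_neg = 0.02) {
  stopifnot(length(line_ids) == length(true_2ns), all(depth >= 0))
  set.seed(stage_seed(seed, "tags"))
  depth <- rep_len(as.integer(depth), length(line_ids))
  p <- ifelse(true_2ns, p_pos, p_neg)
  alien <- stats::rbinom(length(line_ids), depth, p)
  data.frame(line_id = line_ids, alien_count = alien,
             wheat_count = depth - alien, true_2ns = as.logical(true_2ns),
             stringsAsFactors = FALSE)
}
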