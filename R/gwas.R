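#' Mixed-model GWAS scan
#'
#' Single-marker association under `y = X beta + Z u + S tau + e` with
#' polygenic background `u ~ N(0, sigma2_u K)`.  Variance components are
#' estimated once under the no-marker null by spectral REML and reused for
#' every marker test (the population-parameters-previously-determined,
#' P3D/EMMAX, approach); `exact = TRUE` re-estimates them per marker.  Fixed
#' effects are an intercept, `n_pc` principal-component covariates from
#' `K`, and any extra covariates (e.g. a year indicator).  Each marker's
#' allele effect `tau` is tested by generalized least squares with a
#' two-sided t-test.
#'
#' @param y Named numeric vector of adjusted means/BLUEs.
#' @param G A `genotype_matrix` or complete -1/0/1 matrix aligned to `y`.
#' @param K Kinship matrix (defaults to [genomic_relationship()] of `G`).
#' @param n_pc Number of structure PCs (default 3).
#' @param covariates Optional numeric matrix of extra fixed covariates.
#' @param exact Re-estimate variance components per marker (slow; default
#'   FALSE).
#' @return data.frame of class `gwas_result`: `marker_id`, `chrom`, `pos`,
#'   `effect`, `se`, `p`, `q`.  Monomorphic markers get `NA` effect and
#'   missing p/q.
#' @export
gwas_scan <- function(y, G, K = NULL, n_pc = 3, covariates = NULL,
                      exact = FALSE) {
  calls <- if (inherits(G, "genotype_matrix")) G$calls else G
  map <- if (inherits(G, "genotype_matrix")) G$map else
    data.frame(marker_id = colnames(calls),
               chrom = NA_integer_, pos = NA_real_)
  if (!is.null(names(y))) {
    common <- intersect(names(y), rownames(calls))
    if (length(common) < length(y)) {
      y <- y[common]
      calls <- calls[common, , drop = FALSE]
      if (!is.null(covariates)) covariates <- covariates[common, , drop = FALSE]
      if (!is.null(K)) K <- K[common, common]
    } else {
      calls <- calls[names(y), , drop = FALSE]
    }
  }
  if (any(is.na(calls))) stop("complete genotypes required; impute first")
  n <- length(y)
  if (is.null(K)) K <- genomic_relationship(calls)
  X <- cbind(`(Intercept)` = rep(1, n), pc_covariates(K, n_pc))
  if (!is.null(covariates)) X <- cbind(X, covariates)

  null_fit <- reml_kinship(y, K = K, X = X)
  eig <- null_fit$eig
  d <- eig$values
  U <- eig$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)

  m <- ncol(calls)
  effect <- se <- pval <- rep(NA_real_, m)
  p_fixed <- ncol(X) + 1L

  test_marker <- function(st, delta) {
    w <- 1 / (d + delta)
    Xa <- cbind(Xt, st)
    XtWX <- crossprod(Xa, Xa * w)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(c(NA_real_, NA_real_, NA_real_))
    XtWy <- crossprod(Xa, yt * w)
    beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
    r <- yt - Xa %*% beta
    s2 <- sum(w * r^2) / (n - p_fixed)
    XtWXinv_last <- chol2inv(ch)[p_fixed, p_fixed]
    tau <- beta[p_fixed]
    se_tau <- sqrt(s2 * XtWXinv_last)
    tstat <- tau / se_tau
    c(tau, se_tau, 2 * stats::pt(-abs(tstat), df = n - p_fixed))
  }

  for (j in seq_len(m)) {
    s <- calls[, j]
    if (length(unique(s)) < 2L) next  # monomorphic
    st <- crossprod(U, s)
    delta <- if (exact) {
      fit_j <- reml_kinship(y, X = cbind(X, s), eig = eig)
      fit_j$delta
    } else null_fit$delta
    res <- test_marker(st, delta)
    effect[j] <- res[1]; se[j] <- res[2]; pval[j] <- res[3]
  }
  q <- rep(NA_real_, m)
  ok <- !is.na(pval)
  if (any(ok)) q[ok] <- qvalue_fdr(pval[ok])$q
  out <- data.frame(marker_id = colnames(calls),
                    chrom = map$chrom[match(colnames(calls), map$marker_id)],
                    pos = map$pos[match(colnames(calls), map$marker_id)],
                    effect = effect, se = se, p = pval, q = q,
                    stringsAsFactors = FALSE)
  attr(out, "null_fit") <- null_fit[c("sigma2_u", "sigma2_e", "delta")]
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Storey q-values
#'
#' Storey's FDR procedure with the null proportion estimated at a fixed
#' tuning point: `pi0 = min(1, #\{p > lambda\} / ((1 - lambda) m))` at
#' `lambda = 0.5`, floored at `1/m`; then
#' `q(i) = min_{j >= rank(i)} pi0 m p(j) / j`, capped at 1.  The q vector is
#' monotone non-decreasing in p by construction.
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @param lambda Null-proportion tuning point (default 0.5).
#' @param fdr_level Reporting threshold returned alongside (default 0.05).
#' @return List: `q` (same order as `p`), `pi0`, `fdr_level`,
#'   `n_significant` at the threshold.
#' @export
qvalue_fdr <- function(p, lambda = 0.5, fdr_level = 0.05) {
  stopifnot(all(is.finite(p)), all(p >= 0), all(p <= 1))
  m <- length(p)
  pi0 <- min(1, sum(p > lambda) / ((1 - lambda) * m))
  pi0 <- max(pi0, 1 / m)
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  list(q = q, pi0 = pi0, fdr_level = fdr_level,
       n_significant = sum(q <= fdr_level))
}

#' Call alien-segment (2NS-type) carrier status from tag counts
#'
#' A line is called positive when its alien-tag fraction
#' `alien / (alien + wheat)` reaches `tau` at sufficient depth, negative
#' below `tau` at sufficient depth, and missing otherwise.
#'
#' @param tags data.frame with `line_id`, `alien_count`, `wheat_count`.
#' @param tau Alien-fraction decision threshold (default 0.5; the original
#'   caller's threshold is unpublished, so it is exposed).
#' @param min_depth Minimum total tag depth for a call (default 10).
#' @return data.frame: `line_id`, `status` ("positive"/"negative"/
#'   "missing"), `alien_fraction`, `depth`.
#' @export
call_2ns <- function(tags, tau = 0.5, min_depth = 10L) {
  stopifnot(all(tags$alien_count >= 0), all(tags$wheat_count >= 0))
  depth <- tags$alien_count + tags$wheat_count
  frac <- ifelse(depth > 0, tags$alien_count / depth, NA_real_)
  status <- ifelse(depth < min_depth, "missing",
                   ifelse(frac >= tau, "positive", "negative"))
  data.frame(line_id = tags$line_id, status = status,
             alien_fraction = frac, depth = depth,
             stringsAsFactors = FALSE)
}
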