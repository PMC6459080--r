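#' REML variance components for the single-trial lodging model
#'
#' Fits `y = mu + G + M + e` with random genotype `G`, random sub-block
#' (nested in replicate) `M`, and residual `e`.  Without a sub-block factor
#' the model reduces to the one-way genotype model.  Balanced one-way
#' designs use the exact ANOVA-REML identity (`sigma2_e = MSE`,
#' `sigma2_G = max(0, (MSB - MSE) / r)`), which is the REML solution there
#' and remains exact on the boundary where iterative fitters struggle; all
#' other designs are fitted by REML via lme4.
#'
#' @param y Numeric response (plot values).
#' @param genotype Factor (or coercible) of entry identities.
#' @param subblock Optional factor of sub-block-in-replicate identities
#'   (use e.g. `interaction(rep, subblock)`); `NULL` fits the one-way model.
#' @return List of class `variance_components`: `sigma2_G`, `sigma2_M`
#'   (`NA` for one-way), `sigma2_e`, `n_reps` (mean replicates per
#'   genotype), `method`, `converged`.
#' @export
reml_variance_components <- function(y, genotype, subblock = NULL) {
  genotype <- droplevels(as.factor(genotype))
  ok <- is.finite(y)
  if (!all(ok)) {
    y <- y[ok]; genotype <- droplevels(genotype[ok])
    if (!is.null(subblock)) subblock <- subblock[ok]
  }
  if (nlevels(genotype) < 2L) {
    stop("singular design: need >= 2 genotypes")
  }
  reps <- table(genotype)
  if (max(reps) < 2L) stop("singular design: need >= 2 reps of some genotype")
  if (any(reps == 0L)) stop("singular design: empty genotype level")

  if (is.null(subblock)) {
    if (length(unique(reps)) == 1L) {
      # balanced one-way: exact ANOVA-REML
      r <- as.integer(reps[1])
      means <- tapply(y, genotype, mean)
      a <- nlevels(genotype)
      msb <- r * stats::var(means)
      mse <- sum((y - means[genotype])^2) / (length(y) - a)
      vc <- list(sigma2_G = max(0, (msb - mse) / r), sigma2_M = NA_real_,
                 sigma2_e = mse, n_reps = r, method = "anova_balanced",
                 converged = TRUE)
      class(vc) <- "variance_components"
      return(vc)
    }
    fit <- lme4::lmer(y ~ (1 | g), data = data.frame(y = y, g = genotype),
                      REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular =
                                                    "ignore"))
    vcd <- as.data.frame(lme4::VarCorr(fit))
    vc <- list(sigma2_G = vcd$vcov[vcd$grp == "g"], sigma2_M = NA_real_,
               sigma2_e = vcd$vcov[vcd$grp == "Residual"],
               n_reps = mean(reps), method = "reml_lme4",
               converged = length(fit@optinfo$conv$lme4$messages) == 0)
  } else {
    subblock <- droplevels(as.factor(subblock))
    dat <- data.frame(y = y, g = genotype, m = subblock)
    fit <- lme4::lmer(y ~ (1 | g) + (1 | m), data = dat, REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular =
                                                    "ignore"))
    vcd <- as.data.frame(lme4::VarCorr(fit))
    vc <- list(sigma2_G = vcd$vcov[vcd$grp == "g"],
               sigma2_M = vcd$vcov[vcd$grp == "m"],
               sigma2_e = vcd$vcov[vcd$grp == "Residual"],
               n_reps = mean(reps), method = "reml_lme4",
               converged = length(fit@optinfo$conv$lme4$messages) == 0)
  }
  class(vc) <- "variance_components"
  vc
}

#' Entry-mean broad-sense heritability
#'
#' `H2 = sigma2_G / (sigma2_G + sigma2_e / r)`: the repeatability of
#' genotype means across `r` replicates.
#'
#' @param vc A `variance_components` object (or list with `sigma2_G`,
#'   `sigma2_e`).
#' @param r Number of replicates entering the entry means.
#' @return List of class `heritability`: `H2` in `[0, 1]` and `r`.
#' @export
entry_mean_heritability <- function(vc, r) {
  stopifnot(r >= 1)
  den <- vc$sigma2_G + vc$sigma2_e / r
  H2 <- if (den <= 0) 0 else vc$sigma2_G / den
  structure(list(H2 = min(1, max(0, H2)), r = r), class = "heritability")
}

#' Per-trial heritability of lodging traits
#'
#' Applies the single-trial model per trial and trait: random genotype and
#' random sub-block nested in replicate, then the entry-mean heritability at
#' the trial's replicate count.
#'
#' @param scores data.frame holding `trial`, `rep`, `subblock`, `entry_id`
#'   and the trait columns.
#' @param traits Character vector of trait column names.
#' @return data.frame: `trial`, `trait`, `sigma2_G`, `sigma2_M`,
#'   `sigma2_e`, `H2`.
#' @export
trial_heritability <- function(scores, traits) {
  out <- list()
  for (tr in sort(unique(scores$trial))) {
    sub <- scores[scores$trial == tr, ]
    r <- length(unique(sub$rep))
    for (trait in traits) {
      y <- sub[[trait]]
      vc <- reml_variance_components(y, sub$entry_id,
                                     interaction(sub$rep, sub$subblock,
                                                 drop = TRUE))
      h <- entry_mean_heritability(vc, r)
      out[[length(out) + 1L]] <- data.frame(
        trial = tr, trait = trait, sigma2_G = vc$sigma2_G,
        sigma2_M = vc$sigma2_M, sigma2_e = vc$sigma2_e, H2 = h$H2,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Spectral REML for y = X beta + u + e with u ~ N(0, sigma2_u K).
# Profiles the restricted likelihood over delta = sigma2_e / sigma2_u using
# the eigendecomposition of K (computed once, reusable via `eig`).
reml_kinship <- function(y, K = NULL, X = NULL, eig = NULL,
                         interval = c(-18, 18)) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  if (sum((y - mean(y))^2) == 0) {
    # constant response: both components are exactly zero
    return(list(sigma2_u = 0, sigma2_e = 0, delta = 1,
                beta = c(mean(y), rep(0, ncol(X) - 1)),
                eig = if (is.null(eig)) eigen(K, symmetric = TRUE) else eig,
                restricted_ll = NA_real_))
  }
  if (is.null(eig)) {
    stopifnot(nrow(K) == n, ncol(K) == n)
    eig <- eigen(K, symmetric = TRUE)
    if (min(eig$values) < -1e-6 * max(abs(eig$values))) {
      stop("kinship matrix is not positive semi-definite")
    }
    eig$values <- pmax(eig$values, 0)
  }
  d <- eig$values
  yt <- crossprod(eig$vectors, y)
  Xt <- crossprod(eig$vectors, X)
  p <- ncol(X)

  neg_restricted_ll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (d + delta)
    XtWX <- crossprod(Xt, Xt * w)
    XtWy <- crossprod(Xt, yt * w)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
    r <- yt - Xt %*% beta
    quad <- sum(w * r^2)
    s2u <- quad / (n - p)
    0.5 * ((n - p) * log(s2u) + sum(log(d + delta)) +
             2 * sum(log(diag(ch))) + (n - p))
  }
  opt <- stats::optimize(neg_restricted_ll, interval = interval, tol = 1e-10)
  delta <- exp(opt$minimum)
  w <- 1 / (d + delta)
  XtWX <- crossprod(Xt, Xt * w)
  XtWy <- crossprod(Xt, yt * w)
  beta <- solve(XtWX, XtWy)
  r <- yt - Xt %*% beta
  sigma2_u <- sum(w * r^2) / (n - p)
  list(sigma2_u = sigma2_u, sigma2_e = sigma2_u * delta, delta = delta,
       beta = drop(beta), eig = eig, restricted_ll = -opt$objective)
}
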