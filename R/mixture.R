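#' Arithmetic mean of differential pixels (DLmean)
#'
#' @param pixels Numeric vector of a plot's differential elevations (m).
#' @return Mean in meters.
#' @export
dl_mean <- function(pixels) {
  if (length(pixels) < 1L) stop("dl_mean needs at least one pixel")
  if (any(!is.finite(pixels))) stop("non-finite pixels")
  mean(pixels)
}

#' Fit a zero-anchored two-component normal mixture by EM
#'
#' Models a plot's differential elevations as
#' `d ~ (1 - lambda2) N(0, sigma1^2) + lambda2 N(mu2, sigma2^2)`:
#' a standing-canopy component anchored at zero and a lodged component with
#' free mean `mu2` (m) and mixing proportion `lambda2`.  The E-step computes
#' lodged-component responsibilities; the M-step sets `lambda2` to the mean
#' responsibility, `mu2`/`sigma2^2` to the responsibility-weighted mean and
#' variance, and `sigma1^2` to the complementary-weighted second moment
#' about zero.  Iteration stops when the log-likelihood improves by less
#' than `tol` or after `max_iter` iterations.
#'
#' Initialisation is deterministic: `lambda2 = 0.5`; `mu2` = mean of pixels
#' above the 75th percentile; `sigma1` = 1.4826 x MAD of pixels below the
#' median; `sigma2` = sd of the upper-quartile pixels.  Variances are
#' floored at `variance_floor`; hitting the floor marks the fit degenerate.
#'
#' @param pixels Numeric vector of differential elevations (>= `min_pixels`
#'   finite values).
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Absolute log-likelihood convergence tolerance (default 1e-8).
#' @param variance_floor Lower bound for both variances in m^2
#'   (default 1e-6).
#' @param min_pixels Minimum pixels for a mixture fit (default 50); below
#'   this the fit is returned degenerate with `lambda2 = NA` and callers
#'   fall back to DLmean-based reporting.
#' @return Object of class `mixture_fit`: `lambda2`, `mu2`, `sigma1`,
#'   `sigma2`, `loglik`, `loglik_trace`, `n_iter`, `n_pixels`, `converged`,
#'   `degenerate`.
#' @export
fit_zero_anchored_mixture <- function(pixels, max_iter = 500L, tol = 1e-8,
                                      variance_floor = 1e-6,
                                      min_pixels = 50L) {
  if (any(!is.finite(pixels))) stop("non-finite pixels rejected")
  n <- length(pixels)
  if (n < min_pixels) {
    return(structure(list(lambda2 = NA_real_, mu2 = NA_real_,
                          sigma1 = NA_real_, sigma2 = NA_real_,
                          loglik = NA_real_, loglik_trace = numeric(0),
                          n_iter = 0L, n_pixels = n, converged = FALSE,
                          degenerate = TRUE),
                     class = "mixture_fit"))
  }
  x <- as.numeric(pixels)
  floor_sd <- sqrt(variance_floor)

  q75 <- stats::quantile(x, 0.75, names = FALSE)
  upper <- x[x > q75]
  if (length(upper) < 2L) upper <- sort(x, decreasing = TRUE)[1:2]
  lower <- x[x < stats::median(x)]
  lambda <- 0.5
  mu2 <- mean(upper)
  s1 <- if (length(lower) < 2L) floor_sd else
    stats::mad(lower, center = 0)
  s2 <- stats::sd(upper)
  if (!is.finite(s1) || s1 < floor_sd) s1 <- floor_sd
  if (!is.finite(s2) || s2 < floor_sd) s2 <- floor_sd

  degenerate <- FALSE
  converged <- FALSE
  trace <- numeric(0)
  ll_old <- -Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    d1 <- (1 - lambda) * stats::dnorm(x, 0, s1)
    d2 <- lambda * stats::dnorm(x, mu2, s2)
    den <- d1 + d2
    # guard against total underflow far in the tails
    den[den < .Machine$double.xmin] <- .Machine$double.xmin
    gam <- d2 / den
    ll <- sum(log(den))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    # M-step
    sg <- sum(gam)
    lambda <- sg / n
    if (sg > 0) {
      mu2 <- sum(gam * x) / sg
      v2 <- sum(gam * (x - mu2)^2) / sg
    } else {
      v2 <- variance_floor
    }
    s1c <- n - sg
    v1 <- if (s1c > 0) sum((1 - gam) * x^2) / s1c else variance_floor
    if (v1 < variance_floor || v2 < variance_floor) degenerate <- TRUE
    s1 <- sqrt(max(v1, variance_floor))
    s2 <- sqrt(max(v2, variance_floor))
  }
  structure(list(lambda2 = lambda, mu2 = mu2, sigma1 = s1, sigma2 = s2,
                 loglik = trace[length(trace)], loglik_trace = trace,
                 n_iter = it, n_pixels = n, converged = converged,
                 degenerate = degenerate),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<mixture_fit> lambda2=%.3f mu2=%.3f sigma1=%.3f sigma2=%.3f (n=%d, %d iter%s%s)\n",
    x$lambda2, x$mu2, x$sigma1, x$sigma2, x$n_pixels, x$n_iter,
    if (x$converged) ", converged" else ", NOT converged",
    if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Mixture lodging index (DLmix)
#'
#' `DLmix = lambda2 x mu2`, the expected canopy drop per plot pixel under
#' the zero-anchored mixture.  A converged negative `mu2` corresponds to
#' apparent growth rather than lodging, so the index is clamped to 0 and the
#' fit flagged degenerate (keeps the index non-negative like the visual
#' scores).  For fits that were degenerate at input (too few pixels) the
#' caller is expected to substitute DLmean.
#'
#' @param fit A `mixture_fit`.
#' @return Index in meters; attribute `degenerate` carries the flag.
#' @export
dl_mix <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (is.na(fit$lambda2)) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  if (fit$mu2 < 0) {
    return(structure(0, degenerate = TRUE))
  }
  structure(fit$lambda2 * fit$mu2, degenerate = fit$degenerate)
}
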