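#' Gaussian kernel on marker distances
#'
#' `K_h = exp(-h D^2 / median(D^2))` with `D^2` the squared Euclidean
#' marker distances and the median taken over off-diagonal pairs, so the
#' bandwidth `h` is scale-free.  As `h -> 0` the kernel tends to all-ones
#' and predictions collapse toward the training mean.
#'
#' @param calls Complete lines x markers matrix coded -1/0/1.
#' @param h Bandwidth (default 1).
#' @return n x n kernel matrix with line names.
#' @export
gaussian_kernel <- function(calls, h = 1) {
  if (inherits(calls, "genotype_matrix")) calls <- calls$calls
  sq <- rowSums(calls^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(calls)
  D2[D2 < 0] <- 0
  med <- stats::median(D2[upper.tri(D2)])
  if (!is.finite(med) || med <= 0) med <- 1
  K <- exp(-h * D2 / med)
  dimnames(K) <- list(rownames(calls), rownames(calls))
  K
}

#' Reproducing-kernel Hilbert space genomic prediction
#'
#' Kernel regression `y = 1 mu + g + e` with `g ~ N(0, sigma2_g K_h)` on
#' the Gaussian marker kernel.  The default fit is a Bayesian Gibbs sampler
#' in the kernel eigenbasis (scaled-inverse-chi-square priors on both
#' variances; default chain 10,000/3,000/3, reduced preset 2,000/500/2);
#' `method = "reml"` is the flagged kernel-ridge variant using the same
#' spectral REML machinery as GBLUP.  Held-out lines are predicted through
#' the cross-kernel rows.
#'
#' @param calls Complete marker matrix over all lines (train and test).
#' @param y_train Named response for the training lines.
#' @param train_ids,test_ids Line names (rownames of `calls`).
#' @param h Kernel bandwidth (default 1).
#' @param iters,burn,thin MCMC settings (defaults 10000, 3000, 3).
#' @param preset `"full"` or `"reduced"` (2000/500/2).
#' @param seed Integer seed.
#' @param method `"bayes"` (default) or `"reml"`.
#' @return List of class `rkhs_fit`: `pred` (named test predictions),
#'   `fitted` (training fit), `mu`, `sigma2_g`, `sigma2_e`, `method`.
#' @export
fit_rkhs <- function(calls, y_train, train_ids, test_ids, h = 1,
                     iters = 10000L, burn = 3000L, thin = 3L,
                     preset = c("full", "reduced"), seed = 1L,
                     method = c("bayes", "reml")) {
  preset <- match.arg(preset)
  method <- match.arg(method)
  if (preset == "reduced") {
    iters <- 2000L; burn <- 500L; thin <- 2L
  }
  if (inherits(calls, "genotype_matrix")) calls <- calls$calls
  K <- gaussian_kernel(calls[c(train_ids, test_ids), , drop = FALSE], h = h)
  tr <- seq_along(train_ids)
  te <- length(train_ids) + seq_along(test_ids)
  y <- as.numeric(y_train[train_ids])

  if (method == "reml") {
    g <- gblup_predict(y, K, tr, te)
    return(structure(list(pred = g$pred, fitted = g$fitted, mu = g$mu,
                          sigma2_g = NA_real_, sigma2_e = NA_real_,
                          method = "reml"),
                     class = "rkhs_fit"))
  }

  K_tt <- K[tr, tr, drop = FALSE]
  eig <- eigen(K_tt, symmetric = TRUE)
  keep <- eig$values > 1e-10 * max(eig$values)
  d <- eig$values[keep]
  U <- eig$vectors[, keep, drop = FALSE]
  n <- length(y)
  vy <- stats::var(y); if (vy == 0) vy <- 1e-8
  nu <- 5
  s_g <- vy * 0.5
  s_e <- vy * 0.5

  set.seed(seed)
  mu <- mean(y)
  a <- numeric(length(d))          # g = U a, prior a_i ~ N(0, sigma2_g d_i)
  sigma2_g <- s_g; sigma2_e <- s_e
  mu_acc <- 0; alpha_acc <- numeric(length(d))
  s2g_acc <- 0; s2e_acc <- 0; n_samp <- 0L
  for (it in seq_len(iters)) {
    yt <- crossprod(U, y - mu)
    prec <- 1 / (sigma2_g * d) + 1 / sigma2_e
    a <- stats::rnorm(length(d), (yt / sigma2_e) / prec, sqrt(1 / prec))
    g <- drop(U %*% a)
    mu <- stats::rnorm(1, mean(y - g), sqrt(sigma2_e / n))
    sigma2_g <- (sum(a^2 / d) + nu * s_g) / stats::rchisq(1, nu + length(d))
    e <- y - mu - g
    sigma2_e <- (sum(e^2) + nu * s_e) / stats::rchisq(1, nu + n)
    if (it > burn && ((it - burn) %% thin == 0L)) {
      n_samp <- n_samp + 1L
      mu_acc <- mu_acc + mu
      alpha_acc <- alpha_acc + a / d   # alpha = K_tt^{-1} g in eigenbasis
      s2g_acc <- s2g_acc + sigma2_g
      s2e_acc <- s2e_acc + sigma2_e
    }
  }
  mu_hat <- mu_acc / n_samp
  alpha_hat <- drop(U %*% (alpha_acc / n_samp))
  pred <- drop(mu_hat + K[te, tr, drop = FALSE] %*% alpha_hat)
  names(pred) <- test_ids
  fitted <- drop(mu_hat + K_tt %*% alpha_hat)
  structure(list(pred = pred, fitted = fitted, mu = mu_hat,
                 sigma2_g = s2g_acc / n_samp, sigma2_e = s2e_acc / n_samp,
                 method = "bayes"),
            class = "rkhs_fit")
}
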