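#' Ridge-regression BLUP of marker effects
#'
#' Fits `y = 1 mu + W beta + e` with `beta ~ N(0, sigma2_b I)`.  The
#' shrinkage ratio `delta = sigma2_e / sigma2_b` is estimated by REML
#' through the spectral decomposition of the marker cross-product
#' `W W'` (so the cost is in the number of lines, not markers), and marker
#' effects are recovered as `beta = W' (W W' + delta I)^{-1} (y - mu)`.
#' Predictions from the marker-effect form are identical to kinship-form
#' GBLUP with `K = W W'`.
#'
#' @param W_train Complete train-set marker matrix coded -1/0/1.
#' @param y_train Numeric response aligned to rows of `W_train`.
#' @return Object of class `rrblup_fit`: `mu`, `beta` (named marker
#'   effects), `sigma2_u`, `sigma2_e`, `delta`, `zero_variance` flag.
#' @export
fit_rrblup <- function(W_train, y_train) {
  stopifnot(nrow(W_train) == length(y_train), !any(is.na(W_train)),
            nrow(W_train) >= 30)
  K <- tcrossprod(W_train)
  fit <- reml_kinship(y_train, K = K)
  mu <- fit$beta[1]
  zero_var <- fit$sigma2_u * max(fit$eig$values) <
    1e-8 * max(fit$sigma2_e, .Machine$double.eps)
  if (zero_var) {
    beta <- stats::setNames(numeric(ncol(W_train)), colnames(W_train))
  } else {
    w <- 1 / (fit$eig$values + fit$delta)
    alpha <- fit$eig$vectors %*% (w * crossprod(fit$eig$vectors,
                                                y_train - mu))
    beta <- stats::setNames(drop(crossprod(W_train, alpha)),
                            colnames(W_train))
  }
  structure(list(mu = mu, beta = beta, sigma2_u = fit$sigma2_u,
                 sigma2_e = fit$sigma2_e, delta = fit$delta,
                 zero_variance = zero_var),
            class = "rrblup_fit")
}

#' Predict genomic values from an RR-BLUP fit
#'
#' @param object An `rrblup_fit`.
#' @param W New lines x markers matrix on the same marker set and coding.
#' @param ... Unused.
#' @return Named numeric vector of GEBVs (`mu + W beta`).
#' @export
predict.rrblup_fit <- function(object, W, ...) {
  stats::setNames(drop(object$mu + W %*% object$beta), rownames(W))
}

#' Kinship-form GBLUP predictions
#'
#' Fits the GBLUP model on training lines and predicts held-out lines
#' through the cross-kinship block:
#' `u_test = K_ts (K_tt + delta I)^{-1} (y - mu)`.
#'
#' @param y_train Response for training lines.
#' @param K Full kinship matrix over training and test lines.
#' @param train_idx,test_idx Row indices (or names) into `K`.
#' @return List: `pred` (named predictions for test lines), `fitted`
#'   (training-line BLUPs plus intercept), `mu`, `delta`.
#' @export
gblup_predict <- function(y_train, K, train_idx, test_idx) {
  K_tt <- K[train_idx, train_idx, drop = FALSE]
  K_st <- K[test_idx, train_idx, drop = FALSE]
  fit <- reml_kinship(y_train, K = K_tt)
  mu <- fit$beta[1]
  w <- 1 / (fit$eig$values + fit$delta)
  alpha <- fit$eig$vectors %*% (w * crossprod(fit$eig$vectors,
                                              y_train - mu))
  pred <- drop(mu + K_st %*% alpha)
  names(pred) <- rownames(K)[test_idx]
  fitted <- drop(mu + K_tt %*% alpha)
  list(pred = pred, fitted = fitted, mu = mu, delta = fit$delta)
}
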