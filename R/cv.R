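#' Leave-one-trial-out cross-validation folds
#'
#' One fold per trial: the fold's test set is that trial's non-check
#' entries, the training set is every other entry plus the checks.  Since
#' trials group related lines (families), this prevents close relatives
#' from straddling the train/test split; checks appear in every trial and
#' are therefore kept in training but never scored in a test set.
#'
#' @param layout A `field_layout` (or any data.frame with `trial`,
#'   `entry_id`, `is_check`).
#' @return Object of class `cv_scheme`: `label`, and `folds` (a list per
#'   trial with `trial`, `test`, `train` entry-id vectors).
#' @export
make_trial_folds <- function(layout) {
  tab <- unique(layout[, c("trial", "entry_id", "is_check")])
  checks <- unique(tab$entry_id[tab$is_check])
  entries <- tab[!tab$is_check, ]
  trials <- sort(unique(layout$trial))
  folds <- lapply(trials, function(t) {
    test <- unique(entries$entry_id[entries$trial == t])
    train <- unique(c(entries$entry_id[entries$trial != t], checks))
    list(trial = t, test = test, train = setdiff(train, test))
  })
  sets <- lapply(folds, `[[`, "test")
  if (any(duplicated(unlist(sets)))) {
    stop("entries assigned to multiple test folds")
  }
  structure(list(label = sprintf("%d-fold leave-one-trial-out",
                                 length(trials)),
                 folds = folds),
            class = "cv_scheme")
}

# Fit the requested model on training lines and predict test lines.
predict_genomic <- function(model, calls, y_train, train_ids, test_ids,
                            seed = 1L, preset = "full", h = 1) {
  W_tr <- calls[train_ids, , drop = FALSE]
  switch(model,
    rrblup = {
      fit <- fit_rrblup(W_tr, y_train[train_ids])
      predict(fit, calls[test_ids, , drop = FALSE])
    },
    bayescpi = {
      fit <- fit_bayes_cpi(W_tr, y_train[train_ids], preset = preset,
                           seed = seed)
      predict(fit, calls[test_ids, , drop = FALSE])
    },
    rkhs = {
      fit <- fit_rkhs(calls, y_train, train_ids, test_ids, h = h,
                      preset = preset, seed = seed)
      fit$pred
    },
    stop("unknown model: ", model))
}

#' Trial-wise cross-validated genomic prediction
#'
#' Fits the chosen whole-genome model on each training fold, predicts the
#' held-out trial, and reports the predictive ability `r_pv` together with
#' the heritability and the prediction accuracy `r_pa = r_pv / sqrt(H2)`.
#'
#' @param model One of `"rrblup"`, `"bayescpi"`, `"rkhs"`.
#' @param G A `genotype_matrix` or complete -1/0/1 matrix with line names.
#' @param y Named numeric vector of entry BLUEs/means.
#' @param scheme A `cv_scheme` from [make_trial_folds()].
#' @param H2 Entry-mean heritability of the trait on the same data slice
#'   (optional; `NA` skips `r_pa`).
#' @param aggregate `"mean"` (default): mean of within-fold Pearson
#'   correlations; `"pooled"`: one correlation over all pooled test
#'   predictions.
#' @param seed Integer seed for the samplers.
#' @param preset MCMC preset for the Bayesian models.
#' @return One-row data.frame of class `cv_result`: `model`, `scheme`,
#'   `r_pv`, `H2`, `r_pa`, `n_folds`; per-fold detail in the
#'   `"fold_r"` attribute, pooled predictions in `"predictions"`.
#' @export
cross_validate <- function(model, G, y, scheme, H2 = NA_real_,
                           aggregate = c("mean", "pooled"), seed = 1L,
                           preset = "full") {
  aggregate <- match.arg(aggregate)
  calls <- if (inherits(G, "genotype_matrix")) G$calls else G
  stopifnot(!is.null(names(y)))
  fold_r <- numeric(0)
  preds <- obs <- numeric(0)
  for (f in scheme$folds) {
    train_ids <- intersect(f$train, intersect(names(y), rownames(calls)))
    test_ids <- intersect(f$test, intersect(names(y), rownames(calls)))
    if (length(intersect(train_ids, test_ids)) > 0) {
      stop("train/test overlap in fold for trial ", f$trial)
    }
    if (length(test_ids) < 3 || length(train_ids) < 30) next
    p <- predict_genomic(model, calls, y, train_ids, test_ids,
                         seed = seed + f$trial, preset = preset)
    fold_r <- c(fold_r, stats::cor(p, y[test_ids]))
    preds <- c(preds, p)
    obs <- c(obs, y[test_ids])
  }
  r_pv <- if (aggregate == "mean") mean(fold_r) else stats::cor(preds, obs)
  out <- data.frame(model = model, scheme = scheme$label, r_pv = r_pv,
                    H2 = H2,
                    r_pa = if (is.na(H2)) NA_real_
                           else prediction_accuracy(r_pv, H2),
                    n_folds = length(fold_r), stringsAsFactors = FALSE)
  attr(out, "fold_r") <- fold_r
  attr(out, "predictions") <- stats::setNames(preds, names(preds))
  class(out) <- c("cv_result", "data.frame")
  out
}

#' Prediction accuracy from predictive ability and heritability
#'
#' `r_pa = r_pv / sqrt(H2)`: the correlation between predictions and
#' observed entry means, rescaled to the true-breeding-value scale by the
#' square root of the entry-mean heritability.
#'
#' @param r_pv Predictive ability (Pearson correlation).
#' @param H2 Entry-mean heritability in `(0, 1]`.
#' @return Accuracy at full precision; round to 2 decimals for reporting.
#' @export
prediction_accuracy <- function(r_pv, H2) {
  stopifnot(all(H2 > 0), all(H2 <= 1))
  r_pv / sqrt(H2)
}

#' Across-environment / across-year genomic prediction
#'
#' Fits the model on one population-trait combination and correlates its
#' predictions with observed values of another (same lines in a second
#' environment, or a disjoint set of lines in another year).
#'
#' @param G A `genotype_matrix` or complete -1/0/1 matrix covering both
#'   sets of lines.
#' @param y_train Named response of the training set.
#' @param y_test Named observed values of the test set.
#' @param model One of `"rrblup"`, `"bayescpi"`, `"rkhs"`.
#' @param seed,preset Sampler controls.
#' @return List: `accuracy` (Pearson r), `predictions` (named), `n_train`,
#'   `n_test`.
#' @export
across_env_predict <- function(G, y_train, y_test,
                               model = "rrblup", seed = 1L,
                               preset = "full") {
  calls <- if (inherits(G, "genotype_matrix")) G$calls else G
  train_ids <- intersect(names(y_train), rownames(calls))
  test_ids <- intersect(names(y_test), rownames(calls))
  p <- predict_genomic(model, calls, y_train, train_ids, test_ids,
                       seed = seed, preset = preset)
  list(accuracy = stats::cor(p, y_test[test_ids]),
       predictions = p, n_train = length(train_ids),
       n_test = length(test_ids))
}

#' Append a row-average column to an accuracy grid
#'
#' @param grid data.frame whose numeric columns are scheme accuracies.
#' @return The grid with an `Average` column (arithmetic mean across the
#'   scheme columns).
#' @export
accuracy_grid_average <- function(grid) {
  num <- vapply(grid, is.numeric, logical(1))
  grid$Average <- rowMeans(grid[, num, drop = FALSE])
  grid
}
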