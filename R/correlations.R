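#' Marker-based genetic correlation between two traits
#'
#' `rg(x, y) = cov_g(x, y) / sqrt(var_g(x) var_g(y))`, with the genetic
#' (co)variances structured by a kinship matrix `K`.  The components are
#' obtained by exact spectral REML on the three univariate traits `x`, `y`
#' and `x + y`, using the polarisation identity
#' `cov_g(x, y) = (var_g(x + y) - var_g(x) - var_g(y)) / 2`; REML scale
#' equivariance makes the self-correlation exactly 1 and the correlation
#' with a negated trait exactly -1.
#'
#' @param x,y Numeric trait vectors on the same genotype set (aligned to the
#'   rows of `K`).
#' @param K Positive semi-definite kinship matrix.
#' @return List of class `genetic_correlation`: `rg` (clipped to
#'   `[-1, 1]`), `cov_g`, `var_gx`, `var_gy`, `boundary` (TRUE when either
#'   genetic variance is effectively zero, making `rg` undefined/NA).
#' @export
genetic_correlation <- function(x, y, K) {
  stopifnot(length(x) == length(y), nrow(K) == length(x))
  eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -1e-6 * max(abs(eig$values))) {
    stop("kinship matrix is not positive semi-definite")
  }
  eig$values <- pmax(eig$values, 0)
  fx <- reml_kinship(x, eig = eig)
  fy <- reml_kinship(y, eig = eig)
  fs <- reml_kinship(x + y, eig = eig)
  var_gx <- fx$sigma2_u
  var_gy <- fy$sigma2_u
  cov_g <- (fs$sigma2_u - var_gx - var_gy) / 2
  scale_floor <- 1e-10 * (stats::var(x) + stats::var(y))
  boundary <- var_gx <= scale_floor || var_gy <= scale_floor
  rg <- if (boundary) NA_real_ else {
    min(1, max(-1, cov_g / sqrt(var_gx * var_gy)))
  }
  structure(list(rg = rg, cov_g = cov_g, var_gx = var_gx, var_gy = var_gy,
                 boundary = boundary),
            class = "genetic_correlation")
}

#' All-pairs Pearson correlations with significance
#'
#' @param df data.frame of numeric score columns (one row per plot or
#'   entry); non-numeric columns are dropped.
#' @return List with matrices `r` (Pearson correlations on pairwise complete
#'   observations; `NA` where undefined, e.g. constant columns), `p`
#'   (two-sided t-test p-values) and `n` (complete pairs).
#' @export
pearson_matrix <- function(df) {
  df <- df[vapply(df, is.numeric, logical(1))]
  k <- ncol(df)
  nm <- names(df)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    for (j in i:k) {
      ok <- is.finite(df[[i]]) & is.finite(df[[j]])
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) >= 3 && stats::sd(df[[i]][ok]) > 0 &&
          stats::sd(df[[j]][ok]) > 0) {
        if (i == j) {
          r[i, j] <- 1; p[i, j] <- 0
        } else {
          ct <- stats::cor.test(df[[i]][ok], df[[j]][ok])
          r[i, j] <- r[j, i] <- unname(ct$estimate)
          p[i, j] <- p[j, i] <- ct$p.value
        }
      }
    }
  }
  list(r = r, p = p, n = n)
}

#' Two-group difference test
#'
#' Welch's two-sample t-test by default (Student's by flag) for e.g. the
#' carrier vs non-carrier contrast of lodging scores.
#'
#' @param values Numeric vector.
#' @param groups Two-level factor/logical splitting `values`.
#' @param var_equal Use Student's pooled-variance test (default FALSE =
#'   Welch).
#' @return List: `t`, `p`, `df`, `mean_diff` (group 2 minus group 1), `n`
#'   per group.  Degenerate groups (fewer than 2 observations) give `NA`
#'   statistics rather than an error.
#' @export
group_difference_test <- function(values, groups, var_equal = FALSE) {
  groups <- as.factor(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) != 2L) stop("need exactly two groups")
  n <- table(groups)
  if (any(n < 2L)) {
    return(list(t = NA_real_, p = NA_real_, df = NA_real_,
                mean_diff = diff(tapply(values, groups, mean)),
                n = as.vector(n), degenerate = TRUE))
  }
  ht <- stats::t.test(values ~ groups, var.equal = var_equal)
  m <- tapply(values, groups, mean)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff = unname(m[2] - m[1]),
       n = as.vector(n), degenerate = FALSE)
}
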