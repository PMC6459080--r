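#' VanRaden genomic relationship matrix
#'
#' `K = W W' / (2 sum_j p_j (1 - p_j))` with `W` the column-centered dosage
#' matrix (dosages 0/1/2 recovered from the -1/0/1 coding).  Symmetric and
#' positive semi-definite up to numerical tolerance; the diagonal averages
#' about 1 for markers near Hardy-Weinberg proportions.
#'
#' @param calls Complete lines x markers matrix coded -1/0/1 (or a
#'   `genotype_matrix`).
#' @return n x n kinship matrix with line names.
#' @export
genomic_relationship <- function(calls) {
  if (inherits(calls, "genotype_matrix")) calls <- calls$calls
  if (any(is.na(calls))) stop("complete genotypes required; impute first")
  dos <- calls + 1  # 0/1/2 dosage of the +1 allele
  p <- colMeans(dos) / 2
  W <- sweep(dos, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic")
  K <- tcrossprod(W) / denom
  (K + t(K)) / 2
}

#' Principal-component population-structure covariates
#'
#' Leading eigenvectors of the kinship matrix, in descending eigenvalue
#' order, with a deterministic sign convention: the largest-magnitude
#' loading of each component is made positive.
#'
#' @param K Kinship matrix.
#' @param n_pc Number of components (0 gives a zero-column matrix, i.e. an
#'   intercept-only design downstream).
#' @return n x n_pc matrix of component scores (unit-norm eigenvectors).
#' @export
pc_covariates <- function(K, n_pc) {
  n <- nrow(K)
  if (n_pc == 0) {
    return(matrix(numeric(0), n, 0, dimnames = list(rownames(K), NULL)))
  }
  eig <- eigen(K, symmetric = TRUE)
  V <- eig$vectors[, seq_len(n_pc), drop = FALSE]
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(rownames(K), paste0("PC", seq_len(n_pc)))
  V
}
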