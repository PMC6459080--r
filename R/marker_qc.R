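#' Marker and line quality-control filters
#'
#' Keeps markers whose missing fraction is strictly below
#' `max_marker_missing` and whose heterozygous fraction is strictly below
#' `max_marker_het`, then drops lines with more than `max_line_missing`
#' missing calls over the retained markers.
#'
#' @param G A `genotype_matrix` or a plain lines x markers matrix coded
#'   -1/0/1 with `NA` missing.
#' @param max_marker_missing Maximum tolerated marker missing fraction,
#'   exclusive bound (default 0.40).
#' @param max_marker_het Maximum tolerated marker heterozygosity, exclusive
#'   bound (default 0.10).
#' @param max_line_missing Line missing fraction above which the line is
#'   removed (default 0.50).
#' @return Same type as `G`, filtered; attribute `qc` records the counts
#'   dropped.
#' @export
filter_markers <- function(G, max_marker_missing = 0.40,
                           max_marker_het = 0.10,
                           max_line_missing = 0.50) {
  stopifnot(max_marker_missing >= 0, max_marker_missing <= 1,
            max_marker_het >= 0, max_marker_het <= 1,
            max_line_missing >= 0, max_line_missing <= 1)
  calls <- if (inherits(G, "genotype_matrix")) G$calls else G
  miss <- colMeans(is.na(calls))
  het <- colMeans(calls == 0L, na.rm = TRUE)
  het[is.nan(het)] <- 0
  keep_m <- miss < max_marker_missing & het < max_marker_het
  calls2 <- calls[, keep_m, drop = FALSE]
  line_miss <- rowMeans(is.na(calls2))
  keep_l <- line_miss <= max_line_missing
  calls2 <- calls2[keep_l, , drop = FALSE]
  qc <- list(markers_dropped = sum(!keep_m), lines_dropped = sum(!keep_l))
  if (inherits(G, "genotype_matrix")) {
    out <- G
    out$calls <- calls2
    out$map <- G$map[G$map$marker_id %in% colnames(calls2), , drop = FALSE]
    out$line_trial <- G$line_trial[rownames(calls2)]
    attr(out, "qc") <- qc
    return(out)
  }
  attr(calls2, "qc") <- qc
  calls2
}

#' Imputation stand-in: het removal plus per-marker mode
#'
#' Heterozygous calls are first set to missing, then every missing call is
#' imputed with the marker's modal homozygous call; ties break
#' deterministically to the allele coded -1.  The output contains no
#' missing and no heterozygous codes, so the filter-then-impute pipeline is
#' idempotent.
#'
#' @param G A `genotype_matrix` or plain matrix (post-QC).
#' @return Same type as `G` with complete -1/+1 calls.
#' @export
impute_and_clean <- function(G) {
  calls <- if (inherits(G, "genotype_matrix")) G$calls else G
  calls[calls == 0L] <- NA_integer_
  for (j in seq_len(ncol(calls))) {
    mis <- is.na(calls[, j])
    if (!any(mis)) next
    obs <- calls[!mis, j]
    n_pos <- sum(obs == 1L)
    n_neg <- sum(obs == -1L)
    mode_call <- if (n_pos > n_neg) 1L else -1L  # tie -> -1
    calls[mis, j] <- mode_call
  }
  if (inherits(G, "genotype_matrix")) {
    G$calls <- calls
    return(G)
  }
  calls
}
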