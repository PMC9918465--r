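#' Counts per million
#'
#' `CPM_ij = K_ij / sum_i(K_ij) * 1e6`. Every sample must have a positive
#' library total.
#'
#' @param counts non-negative integer matrix (features x samples).
#' @return numeric matrix of the same shape.
#' @export
cpm <- function(counts) {
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("sample '", colnames(counts)[totals == 0][1],
         "' has zero total count; CPM undefined")
  }
  sweep(counts, 2, totals, "/") * 1e6
}

#' Filter lowly expressed features by mean CPM
#'
#' Keeps feature i iff `mean_j(CPM_ij) > cpm_threshold` (strictly greater).
#' Row order is preserved; the operation is idempotent.
#'
#' @param counts non-negative integer matrix.
#' @param cpm_threshold mean-CPM cutoff, default 1.
#' @return the surviving rows of `counts`.
#' @export
filter_low_expression <- function(counts, cpm_threshold = 1) {
  keep <- rowMeans(cpm(counts)) > cpm_threshold
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' The reference for feature i is the geometric mean of its counts across
#' samples, computed over features with strictly positive counts in every
#' sample; the size factor of sample j is the median over those features of
#' `K_ij / reference_i`. This is the median-of-ratios estimator used for
#' sequencing-depth and composition correction.
#'
#' @param counts non-negative integer matrix.
#' @return numeric vector of per-sample factors, named by sample.
#' @export
size_factors <- function(counts) {
  all_pos <- rowSums(counts == 0) == 0
  if (!any(all_pos)) {
    stop("no feature has positive counts in all samples; ",
         "filter low-expression features or check the input")
  }
  k <- counts[all_pos, , drop = FALSE]
  # geometric mean via mean of logs; all entries > 0 here
  ref <- exp(rowMeans(log(k)))
  s <- apply(k / ref, 2, stats::median)
  if (any(!is.finite(s)) || any(s <= 0)) stop("degenerate size factors")
  s
}

#' Normalize counts by size factors
#'
#' `value_ij = K_ij / s_j`.
#'
#' @param counts non-negative matrix.
#' @param s size factors named by sample, aligned with `colnames(counts)`.
#' @return numeric matrix of normalized counts.
#' @export
normalize_counts <- function(counts, s) {
  if (!is.null(names(s))) {
    if (!identical(names(s), colnames(counts))) {
      stop("size-factor names do not match count-matrix samples")
    }
  } else if (length(s) != ncol(counts)) {
    stop("size-factor length does not match number of samples")
  }
  sweep(counts, 2, s, "/")
}

#' Shifted-log transform of normalized counts
#'
#' `log2(value + pseudocount)`; monotone and finite for non-negative input.
#' This is the expression scale used for correlation and clustering.
#'
#' @param norm non-negative numeric matrix (normalized counts).
#' @param pseudocount added before the log, default 1.
#' @return numeric matrix in log2 units.
#' @export
transform_log <- function(norm, pseudocount = 1) {
  if (any(norm < 0)) stop("negative values: transform_log expects counts >= 0")
  log2(norm + pseudocount)
}
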