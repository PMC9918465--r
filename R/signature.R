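#' Union of DE feature sets across comparisons
#'
#' @param comparisons list of called `de_comparison` objects.
#' @return character vector of feature ids, first-seen order, no duplicates.
#' @export
de_union <- function(comparisons) {
  if (length(comparisons) < 1) stop("need >= 1 comparison")
  unique(unlist(lapply(comparisons, de_features)))
}

#' Hierarchical clustering of an expression matrix
#'
#' Agglomerative clustering with complete linkage
#' (`D(A,B) = max` pairwise distance) on Euclidean distances, over features
#' (rows) or samples (columns). Ties are broken deterministically by
#' `stats::hclust`'s ordering of the distance matrix.
#'
#' @param mat numeric matrix (features x samples), typically log2 expression.
#' @param axis cluster `"samples"` (columns) or `"features"` (rows).
#' @param method linkage method, default `"complete"`.
#' @param scale_rows z-scale rows before clustering (off by default).
#' @return an object of class `hclust`.
#' @export
hier_cluster <- function(mat, axis = c("samples", "features"),
                         method = "complete", scale_rows = FALSE) {
  axis <- match.arg(axis)
  if (scale_rows) {
    sds <- apply(mat, 1, stats::sd)
    sds[sds == 0] <- 1
    mat <- (mat - rowMeans(mat)) / sds
  }
  x <- if (axis == "samples") t(mat) else mat
  if (nrow(x) < 2) stop("need >= 2 items on the chosen axis")
  stats::hclust(stats::dist(x, method = "euclidean"), method = method)
}

#' Cut a dendrogram into k groups
#'
#' @param linkage an `hclust` object.
#' @param k number of clusters, `1 <= k <= n` leaves.
#' @return integer cluster labels named by leaf.
#' @export
cut_tree <- function(linkage, k) {
  n <- length(linkage$order)
  if (k < 1 || k > n) stop("k must lie in [1, ", n, "]")
  stats::cutree(linkage, k = k)
}

#' Adjusted Rand index between cluster labels and design groups
#'
#' Chance-corrected agreement between a sample clustering and the known
#' group labels; 1 means identical partitions, ~0 chance-level agreement.
#'
#' @param labels cluster labels named by sample.
#' @param design design table with `sample_id`, `group`.
#' @return the adjusted Rand index (scalar).
#' @export
cluster_agreement <- function(labels, design) {
  if (is.null(names(labels))) stop("labels must be named by sample")
  idx <- match(names(labels), design$sample_id)
  if (any(is.na(idx)) || length(labels) != nrow(design)) {
    stop("labels and design must cover the same samples")
  }
  mclust::adjustedRandIndex(labels, design$group[idx])
}

#' Compare lncRNA and mRNA expression levels per sample
#'
#' One-sided Mann-Whitney U test (lncRNA stochastically smaller than mRNA)
#' on log2 expression, per sample, with the median difference.
#'
#' @param lnc_mat log2 expression of the lncRNA features (rows) x samples.
#' @param mrna_mat log2 expression of the mRNA features x the same samples.
#' @return data.frame `(sample_id, median_diff, statistic, pvalue)`.
#' @export
compare_expression_levels <- function(lnc_mat, mrna_mat) {
  if (nrow(lnc_mat) == 0 || nrow(mrna_mat) == 0) {
    stop("both biotype sets must be non-empty")
  }
  if (!identical(colnames(lnc_mat), colnames(mrna_mat))) {
    stop("matrices must share samples (same columns, same order)")
  }
  out <- lapply(seq_len(ncol(lnc_mat)), function(j) {
    wt <- stats::wilcox.test(lnc_mat[, j], mrna_mat[, j],
                             alternative = "less", exact = FALSE)
    data.frame(
      sample_id = colnames(lnc_mat)[j],
      median_diff = stats::median(lnc_mat[, j]) - stats::median(mrna_mat[, j]),
      statistic = unname(wt$statistic),
      pvalue = wt$p.value,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
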