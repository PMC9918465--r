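#' Delta-delta-Ct relative quantification
#'
#' Per replicate, `dCt = Ct_target - mean(Ct over reference genes)` (the
#' arithmetic mean of reference Cts equals the geometric mean of reference
#' expressions); per condition, dCt is averaged over replicates;
#' `ddCt = dCt_condition - dCt_control`; `log2fc = -ddCt`;
#' `fold = 2^(-ddCt)`. Amplification efficiency is taken as 2 (one doubling
#' per cycle).
#'
#' @param ct Ct table `(sample_id, condition, gene_id, ct)`.
#' @param targets character vector of target gene ids.
#' @param references character vector of reference gene ids (non-empty,
#'   measured in every replicate).
#' @param control_label the control condition label.
#' @return data.frame `(gene_id, condition, delta_ct_control, delta_ct,
#'   ddct, log2fc, fold)`, one row per target x non-control condition.
#' @export
delta_delta_ct <- function(ct, targets, references, control_label) {
  if (length(references) == 0) stop("references must be non-empty")
  if (!control_label %in% ct$condition) {
    stop("control condition '", control_label, "' absent from Ct table")
  }
  reps <- unique(ct[, c("condition", "sample_id")])
  # mean reference Ct per (condition, replicate)
  ref_rows <- ct[ct$gene_id %in% references, , drop = FALSE]
  ref_key <- paste(ref_rows$condition, ref_rows$sample_id, sep = "\r")
  rep_key <- paste(reps$condition, reps$sample_id, sep = "\r")
  n_ref <- table(factor(ref_key, levels = rep_key))
  if (any(n_ref < length(references))) {
    bad <- rep_key[n_ref < length(references)][1]
    stop("reference gene(s) missing in replicate '",
         sub("\r", "/", bad), "'")
  }
  ref_mean <- tapply(ref_rows$ct, factor(ref_key, levels = rep_key), mean)

  conditions <- unique(ct$condition)
  treat <- setdiff(conditions, control_label)
  out <- list()
  for (g in targets) {
    rows <- ct[ct$gene_id == g, , drop = FALSE]
    key <- paste(rows$condition, rows$sample_id, sep = "\r")
    dct <- rows$ct - as.numeric(ref_mean[key])
    dct_by_cond <- tapply(dct, rows$condition, mean)
    if (!control_label %in% names(dct_by_cond)) {
      stop("target '", g, "' not measured in the control condition")
    }
    for (cond in treat) {
      if (!cond %in% names(dct_by_cond)) {
        stop("target '", g, "' not measured in condition '", cond, "'")
      }
      ddct <- dct_by_cond[[cond]] - dct_by_cond[[control_label]]
      out[[length(out) + 1]] <- data.frame(
        gene_id = g, condition = cond,
        delta_ct_control = dct_by_cond[[control_label]],
        delta_ct = dct_by_cond[[cond]],
        ddct = ddct, log2fc = -ddct, fold = 2^(-ddct),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-platform comparison of fold-change estimates
#'
#' Pearson correlation (two-tailed p via the t transform with n - 2 df) and
#' the same-trend fraction between two per-gene log2 fold-change vectors,
#' e.g. RT-qPCR versus RNA-seq. A zero on either side counts as a trend
#' disagreement.
#'
#' @param qpcr_lfc named numeric vector of qPCR log2 fold changes.
#' @param rnaseq_lfc named numeric vector of RNA-seq log2 fold changes.
#' @return list `(pearson_r, pvalue, same_trend_fraction, n)`.
#' @export
compare_platforms <- function(qpcr_lfc, rnaseq_lfc) {
  shared <- intersect(names(qpcr_lfc), names(rnaseq_lfc))
  if (length(shared) < 3) stop("need >= 3 shared genes")
  x <- qpcr_lfc[shared]
  y <- rnaseq_lfc[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant fold-change vector: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  trend <- mean(sign(x) == sign(y) & sign(x) != 0)
  list(pearson_r = unname(ct$estimate), pvalue = ct$p.value,
       same_trend_fraction = trend, n = length(shared))
}
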