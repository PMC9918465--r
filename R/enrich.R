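#' Kolmogorov-Smirnov GO-term enrichment
#'
#' Classic per-term scoring: for each GO term of the chosen ontology, the
#' score distribution of annotated genes is compared against all remaining
#' genes with a one-sided two-sample KS test (alternative: annotated scores
#' stochastically smaller — appropriate when the score is a p-value).
#' Each term is tested independently; no graph decorrelation and, by
#' default, no multiple-testing correction (BH available via `adjust`).
#'
#' @param gene_scores named numeric vector (e.g. BH-adjusted DE p-values).
#' @param go_map data.frame `(gene_id, go_term, ontology)`.
#' @param ontology one of `"BP"`, `"CC"`, `"MF"`.
#' @param min_in,min_out minimum genes inside/outside a term (default 2).
#' @param adjust apply BH to the per-term p-values (default `FALSE`).
#' @return data.frame `(term_id, ontology, n_annotated, ks_d, pvalue)`
#'   sorted by p-value.
#' @export
ks_go_enrichment <- function(gene_scores, go_map, ontology,
                             min_in = 2, min_out = 2, adjust = FALSE) {
  stopifnot(ontology %in% c("BP", "CC", "MF"))
  if (nrow(go_map) == 0) stop("GO map is empty")
  if (is.null(names(gene_scores))) stop("gene_scores must be named")
  if (any(!is.finite(gene_scores))) stop("gene scores must be finite")
  gm <- go_map[go_map$ontology == ontology &
                 go_map$gene_id %in% names(gene_scores), , drop = FALSE]
  terms <- unique(gm$go_term)
  n_total <- length(gene_scores)
  rows <- list()
  for (tm in terms) {
    genes_in <- unique(gm$gene_id[gm$go_term == tm])
    n_in <- length(genes_in)
    n_out <- n_total - n_in
    if (n_out == 0) {
      warning("term '", tm, "' annotates every gene; skipped")
      next
    }
    if (n_in < min_in || n_out < min_out) next
    x <- gene_scores[genes_in]
    y <- gene_scores[setdiff(names(gene_scores), genes_in)]
    if (stats::sd(gene_scores) == 0) {
      d <- 0; p <- 1
    } else {
      kt <- suppressWarnings(
        stats::ks.test(x, y, alternative = "greater", exact = FALSE)
      )
      d <- unname(kt$statistic); p <- kt$p.value
    }
    rows[[length(rows) + 1]] <- data.frame(
      term_id = tm, ontology = ontology, n_annotated = n_in,
      ks_d = d, pvalue = p, stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(term_id = character(), ontology = character(),
               n_annotated = integer(), ks_d = numeric(), pvalue = numeric())
  if (adjust && nrow(out) > 0) out$pvalue <- adjust_bh(out$pvalue)
  out <- out[order(out$pvalue, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top enriched terms
#'
#' @param records output of [ks_go_enrichment()] (sorted by p).
#' @param k number of terms to keep.
#' @return the first `min(k, nrow)` records.
#' @export
top_terms <- function(records, k) {
  stopifnot(k >= 0)
  utils::head(records, k)
}
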