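#' Pair-calling thresholds
#'
#' Defaults follow the standard NAT-mRNA screen: antisense overlap of at
#' least 50 bp, squared Pearson correlation of at least 0.6, and a two-fold
#' expression change (|log2FC| >= 1) on both pair members.
#'
#' @param min_overlap minimum antisense overlap, bp (>= 1).
#' @param r2_min minimum squared Pearson correlation in `[0, 1]`.
#' @param lfc_min minimum |log2 fold change| for each member (> 0).
#' @return a list of class `pair_thresholds`.
#' @export
pair_thresholds <- function(min_overlap = 50, r2_min = 0.6, lfc_min = 1) {
  stopifnot(min_overlap >= 1, r2_min >= 0, r2_min <= 1, lfc_min > 0)
  structure(list(min_overlap = min_overlap, r2_min = r2_min,
                 lfc_min = lfc_min), class = "pair_thresholds")
}

#' Find antisense NAT-mRNA overlaps
#'
#' All same-chromosome, opposite-strand (NAT, mRNA) combinations whose
#' overlap length `min(ends) - max(starts) + 1` is at least `min_overlap`.
#' A NAT may pair with several mRNAs and vice versa; each qualifying
#' combination is a distinct candidate.
#'
#' @param nats `feature_set` of NAT loci.
#' @param mrnas `feature_set` of mRNA loci.
#' @param min_overlap minimum overlap in bp, default 50.
#' @return data.frame `(nat_id, mrna_id, overlap_len)`; zero rows if none.
#' @export
find_overlaps <- function(nats, mrnas, min_overlap = 50) {
  validate_feature_set(nats)
  validate_feature_set(mrnas)
  empty <- data.frame(nat_id = character(), mrna_id = character(),
                      overlap_len = integer(), stringsAsFactors = FALSE)
  if (nrow(nats) == 0 || nrow(mrnas) == 0) return(empty)
  gr_n <- as_granges(nats)
  gr_m <- as_granges(mrnas)
  hits <- GenomicRanges::findOverlaps(gr_n, gr_m, minoverlap = min_overlap,
                                      ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  anti <- nats$strand[qi] != mrnas$strand[si]
  qi <- qi[anti]; si <- si[anti]
  if (length(qi) == 0) return(empty)
  ov <- pmin(nats$end[qi], mrnas$end[si]) - pmax(nats$start[qi], mrnas$start[si]) + 1L
  data.frame(nat_id = nats$feature_id[qi], mrna_id = mrnas$feature_id[si],
             overlap_len = as.integer(ov), stringsAsFactors = FALSE)
}

#' Classify antisense overlap topology
#'
#' For overlapping opposite-strand loci: `fully_overlapped` if either
#' interval contains the other; otherwise `head_to_head` if the overlap
#' interval contains both 5' termini (the start of a `+` feature, the end of
#' a `-` feature); otherwise `tail_to_tail`. Exactly one label applies to
#' every antisense overlap.
#'
#' Vectorized: all six coordinate/strand arguments are recycled to a common
#' length.
#'
#' @param nat_start,nat_end,nat_strand NAT coordinates and strand.
#' @param mrna_start,mrna_end,mrna_strand mRNA coordinates and strand.
#' @return character vector of topology labels.
#' @export
classify_topology <- function(nat_start, nat_end, nat_strand,
                              mrna_start, mrna_end, mrna_strand) {
  n <- max(length(nat_start), length(mrna_start))
  s1 <- rep_len(as.integer(nat_start), n); e1 <- rep_len(as.integer(nat_end), n)
  t1 <- rep_len(nat_strand, n)
  s2 <- rep_len(as.integer(mrna_start), n); e2 <- rep_len(as.integer(mrna_end), n)
  t2 <- rep_len(mrna_strand, n)
  if (any(t1 == t2)) stop("topology is defined for opposite-strand pairs only")
  ov_s <- pmax(s1, s2)
  ov_e <- pmin(e1, e2)
  if (any(ov_s > ov_e)) stop("topology is defined for overlapping pairs only")
  contains <- (s1 <= s2 & e1 >= e2) | (s2 <= s1 & e2 >= e1)
  five1 <- ifelse(t1 == "+", s1, e1)
  five2 <- ifelse(t2 == "+", s2, e2)
  h2h <- five1 >= ov_s & five1 <= ov_e & five2 >= ov_s & five2 <= ov_e
  ifelse(contains, "fully_overlapped", ifelse(h2h, "head_to_head", "tail_to_tail"))
}

#' Classify topology for a candidate table
#'
#' Looks pair members up in a feature set and applies [classify_topology()].
#'
#' @param candidates data.frame from [find_overlaps()].
#' @param features `feature_set` containing all pair members.
#' @return `candidates` with a `topology` column added.
#' @export
classify_candidates <- function(candidates, features) {
  ni <- match(candidates$nat_id, features$feature_id)
  mi <- match(candidates$mrna_id, features$feature_id)
  if (any(is.na(ni)) || any(is.na(mi))) {
    stop("candidate pair member missing from feature set")
  }
  candidates$topology <- if (nrow(candidates) == 0) character(0) else
    classify_topology(features$start[ni], features$end[ni], features$strand[ni],
                      features$start[mi], features$end[mi], features$strand[mi])
  candidates
}

#' Pearson correlation of a pair's log expression
#'
#' Standard Pearson r over the named samples on log2-transformed normalized
#' expression. A constant vector makes r undefined; the pair is then flagged
#' (NA) rather than raising an error.
#'
#' @param nat_id,mrna_id pair member ids (rows of `log_expr`).
#' @param log_expr log2 expression matrix.
#' @param samples sample (column) names to use; >= 3.
#' @return list `(r, r2)`; both NA when undefined.
#' @export
pair_correlation <- function(nat_id, mrna_id, log_expr, samples) {
  if (length(samples) < 3) stop("need >= 3 samples for a correlation")
  x <- log_expr[nat_id, samples]
  y <- log_expr[mrna_id, samples]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, r2 = NA_real_))
  }
  r <- stats::cor(x, y)
  list(r = r, r2 = r^2)
}

#' Call concordant/discordant NAT-mRNA pairs
#'
#' Candidates are evaluated only when both the NAT and its cognate mRNA are
#' differentially expressed and both clear the fold-change gate
#' (|log2fc| >= `lfc_min`, i.e. fold >= 2 or <= 0.5 at the default).
#' Retained pairs with `r^2 >= r2_min` are classed `concordant` (same-signed
#' log2 fold changes) or `discordant` (opposite signs); pairs clearing the
#' DE/fold gate but not the correlation gate are reported as `NC`.
#' Exclusion counts (NAT not DE, mRNA not DE, fold gate) are attached as the
#' `"excluded"` attribute.
#'
#' @param candidates data.frame with `nat_id`, `mrna_id`, `overlap_len`,
#'   `topology` (see [classify_candidates()]).
#' @param de_comparison a called `de_comparison` covering both members.
#' @param log_expr log2 expression matrix.
#' @param samples sample names over which to correlate (typically the 8
#'   samples of the pairwise comparison).
#' @param thresholds a [pair_thresholds()].
#' @return data.frame `(nat_id, mrna_id, overlap_len, topology, nat_log2fc,
#'   mrna_log2fc, r, r2, pair_class)`.
#' @export
call_pairs <- function(candidates, de_comparison, log_expr, samples,
                       thresholds = pair_thresholds()) {
  res <- de_comparison$results
  if (is.null(res$called)) stop("run call_de() on the comparison first")
  ni <- match(candidates$nat_id, res$feature_id)
  mi <- match(candidates$mrna_id, res$feature_id)
  if (any(is.na(ni)) || any(is.na(mi))) {
    stop("DE results do not cover all candidate pair members")
  }
  nat_de <- res$called[ni]
  mrna_de <- res$called[mi]
  nat_lfc <- res$log2fc[ni]
  mrna_lfc <- res$log2fc[mi]
  fold_ok <- abs(nat_lfc) >= thresholds$lfc_min &
    abs(mrna_lfc) >= thresholds$lfc_min
  keep <- nat_de & mrna_de & fold_ok
  excluded <- c(nat_not_de = sum(!nat_de),
                mrna_not_de = sum(nat_de & !mrna_de),
                fold_gate = sum(nat_de & mrna_de & !fold_ok))
  out <- candidates[keep, , drop = FALSE]
  out$nat_log2fc <- nat_lfc[keep]
  out$mrna_log2fc <- mrna_lfc[keep]
  cors <- lapply(seq_len(nrow(out)), function(i) {
    pair_correlation(out$nat_id[i], out$mrna_id[i], log_expr, samples)
  })
  out$r <- vapply(cors, `[[`, numeric(1), "r")
  out$r2 <- vapply(cors, `[[`, numeric(1), "r2")
  corr_ok <- !is.na(out$r2) & out$r2 >= thresholds$r2_min
  out$pair_class <- ifelse(!corr_ok, "NC",
                           ifelse(sign(out$nat_log2fc) == sign(out$mrna_log2fc),
                                  "concordant", "discordant"))
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Tally pair calls by class and topology
#'
#' @param calls output of [call_pairs()].
#' @return list with `by_class`, `by_topology` and the cross table
#'   `class_by_topology`; counts in each margin sum to the total.
#' @export
summarize_pairs <- function(calls) {
  classes <- c("concordant", "discordant", "NC")
  topos <- c("head_to_head", "tail_to_tail", "fully_overlapped")
  cl <- factor(calls$pair_class, levels = classes)
  tp <- factor(calls$topology, levels = topos)
  list(
    n_pairs = nrow(calls),
    by_class = table(cl),
    by_topology = table(tp),
    class_by_topology = table(cl, tp)
  )
}
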