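#' Method-of-moments negative-binomial dispersion
#'
#' Per feature, on normalized counts, with group mean differences removed:
#' `alpha_i = max((v_i - m_i) / m_i^2, alpha_min)` where `m_i` is the grand
#' mean and `v_i` the pooled within-group variance. Poisson-like features
#' land at the floor `alpha_min`.
#'
#' @param counts integer count matrix.
#' @param design design table covering `colnames(counts)`.
#' @param s size factors for the samples.
#' @param alpha_min dispersion floor, default 1e-8.
#' @return numeric vector of per-feature dispersions.
#' @export
estimate_dispersion <- function(counts, design, s, alpha_min = 1e-8) {
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  if (any(is.na(design$sample_id))) stop("design does not cover all samples")
  sizes <- table(design$group)
  if (any(sizes < 2)) {
    stop("group '", names(sizes)[sizes < 2][1],
         "' has a single replicate; dispersion needs >= 2")
  }
  x <- normalize_counts(counts, s)
  grp <- factor(design$group)
  n <- ncol(x)
  g <- nlevels(grp)
  # pooled within-group sum of squares, vectorized over features
  ss <- matrix(0, nrow = nrow(x), ncol = 1)
  for (lev in levels(grp)) {
    xg <- x[, grp == lev, drop = FALSE]
    ss <- ss + rowSums((xg - rowMeans(xg))^2)
  }
  v <- as.numeric(ss) / (n - g)
  m <- rowMeans(x)
  alpha <- (v - m) / m^2
  alpha[!is.finite(alpha)] <- alpha_min
  pmax(alpha, alpha_min)
}

#' Two-group negative-binomial Wald test
#'
#' For each feature, the log2 fold change of group B over group A is computed
#' from pseudocount-stabilized means of normalized counts,
#' `log2fc = log2((mu_B + pc) / (mu_A + pc))`, with a delta-method standard
#' error under the NB variance `mu + alpha mu^2`:
#' `Var(log2 mu_G) ~ (1/ln 2)^2 * (1/n_G) * (1/(mu_G + pc) + alpha)`, summed
#' over the two groups. The Wald statistic `z = log2fc / se` is referred,
#' two-sided, to a t distribution with `n_A + n_B - 2` degrees of freedom —
#' a small-sample calibration that keeps the raw false-positive rate at its
#' nominal level with few replicates, where the estimated dispersion is
#' itself noisy. P-values are Benjamini-Hochberg adjusted.
#'
#' @param counts integer count matrix.
#' @param design design table.
#' @param s size factors.
#' @param alpha_disp per-feature dispersions (recycled if scalar).
#' @param group_a reference group label (denominator of the fold change).
#' @param group_b comparison group label (numerator).
#' @param pseudocount stabilizer for means, default 0.5.
#' @param name comparison name; default `"<B>vs<A>"`.
#' @return a `de_comparison`: list with `name`, `group_a`, `group_b` and a
#'   `results` data.frame (feature_id, base_mean, log2fc, se, wald_z, pvalue,
#'   padj).
#' @export
wald_test <- function(counts, design, s, alpha_disp, group_a, group_b,
                      pseudocount = 0.5, name = NULL) {
  for (g in c(group_a, group_b)) {
    if (sum(design$group == g) < 2) {
      stop("group '", g, "' absent or with < 2 replicates")
    }
  }
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  x <- normalize_counts(counts, s)
  a_cols <- design$group == group_a
  b_cols <- design$group == group_b
  n_a <- sum(a_cols)
  n_b <- sum(b_cols)
  mu_a <- rowMeans(x[, a_cols, drop = FALSE])
  mu_b <- rowMeans(x[, b_cols, drop = FALSE])
  alpha <- rep_len(alpha_disp, nrow(x))
  pc <- pseudocount
  log2fc <- log2((mu_b + pc) / (mu_a + pc))
  var_log2 <- (1 / log(2))^2 *
    ((1 / n_a) * (1 / (mu_a + pc) + alpha) +
     (1 / n_b) * (1 / (mu_b + pc) + alpha))
  se <- sqrt(var_log2)
  z <- log2fc / se
  z[!is.finite(z)] <- 0
  p <- 2 * stats::pt(-abs(z), df = n_a + n_b - 2)
  res <- data.frame(
    feature_id = rownames(counts),
    base_mean = rowMeans(x[, a_cols | b_cols, drop = FALSE]),
    log2fc = log2fc,
    se = se,
    wald_z = z,
    pvalue = p,
    padj = adjust_bh(p),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  out <- list(
    name = if (is.null(name)) paste0(group_b, "vs", group_a) else name,
    group_a = group_a, group_b = group_b, results = res
  )
  class(out) <- "de_comparison"
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `padj_(i) = min_{j>=i}(p_(j) * m / j)`, clipped at
#' 1 and mapped back to input order.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
adjust_bh <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed features
#'
#' A feature is called iff `padj < alpha` (strict); direction comes from the
#' sign of the log2 fold change (`up`, `down`, else `ns`).
#'
#' @param comparison a `de_comparison` from [wald_test()].
#' @param alpha significance threshold on adjusted p, default 0.05.
#' @param use_raw_p if `TRUE`, threshold the raw p-value instead.
#' @return the comparison with `called` and `direction` columns added.
#' @export
call_de <- function(comparison, alpha = 0.05, use_raw_p = FALSE) {
  res <- comparison$results
  p <- if (use_raw_p) res$pvalue else res$padj
  res$called <- p < alpha
  res$direction <- ifelse(!res$called, "ns",
                          ifelse(res$log2fc > 0, "up", "down"))
  comparison$results <- res
  comparison
}

#' Extract called feature ids
#'
#' @param comparison a called `de_comparison`.
#' @param direction optionally restrict to `"up"` or `"down"`.
#' @return character vector of feature ids.
#' @export
de_features <- function(comparison, direction = NULL) {
  res <- comparison$results
  if (is.null(res$called)) stop("run call_de() first")
  keep <- res$called
  if (!is.null(direction)) keep <- keep & res$direction == direction
  res$feature_id[keep]
}

#' Summarize up/down calls
#'
#' Counts and integer percentages of up- and down-regulated features among
#' the called set, as reported in up/down pyramid summaries.
#'
#' @param comparison a called `de_comparison`.
#' @return data.frame with `n_called`, `n_up`, `n_down`, `pct_up`, `pct_down`.
#' @export
summarize_de <- function(comparison) {
  res <- comparison$results
  if (is.null(res$called)) stop("run call_de() first")
  n_up <- sum(res$direction == "up")
  n_down <- sum(res$direction == "down")
  n <- n_up + n_down
  data.frame(
    comparison = comparison$name,
    n_called = n,
    n_up = n_up,
    n_down = n_down,
    pct_up = if (n > 0) round(100 * n_up / n) else 0L,
    pct_down = if (n > 0) round(100 * n_down / n) else 0L
  )
}

#' Venn partition of DE sets
#'
#' Counts every region of the Venn partition of two or more named id sets,
#' plus the pairwise shared fraction `|A n B| / |A|`.
#'
#' @param sets named list of character vectors.
#' @return list with `regions` (data.frame: one row per non-empty membership
#'   combination, logical columns per set, `count`) and `shared_fraction`
#'   (matrix, row set A, column set B).
#' @export
intersect_de_sets <- function(sets) {
  if (length(sets) < 2) stop("need >= 2 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be named")
  }
  sets <- lapply(sets, unique)
  all_ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_ids %in% s,
                   logical(length(all_ids)))
  member <- matrix(member, ncol = length(sets),
                   dimnames = list(all_ids, names(sets)))
  key <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  colnames(combos) <- names(sets)
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  ckey <- apply(combos, 1, function(r) paste(as.integer(r), collapse = ""))
  combos$count <- as.integer(table(factor(key, levels = ckey)))
  rownames(combos) <- NULL
  n <- length(sets)
  sf <- matrix(NA_real_, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    sf[i, j] <- if (length(sets[[i]]) > 0) {
      length(intersect(sets[[i]], sets[[j]])) / length(sets[[i]])
    } else 0
  }
  list(regions = combos, shared_fraction = sf)
}
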