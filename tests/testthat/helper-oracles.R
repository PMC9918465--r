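# Independent brute-force oracles used across the suite. These deliberately
# re-derive results from first principles (literal definitions, O(n^3)
# agglomeration, bitmask enumeration) and never call the package code paths
# they check.

# Literal Benjamini-Hochberg step-up rule.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(ps[i:m] * m / (i:m)[seq_len(m - i + 1)])
  }
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Literal terminus-membership topology classifier for one antisense pair.
# Returns NA if the labels are not mutually exclusive/exhaustive, so tests
# can assert the trichotomy directly.
oracle_topology <- function(s1, e1, str1, s2, e2, str2) {
  ov_s <- max(s1, s2); ov_e <- min(e1, e2)
  if (str1 == str2 || ov_s > ov_e) return(NA_character_)
  contains <- (s1 <= s2 && e1 >= e2) || (s2 <= s1 && e2 >= e1)
  if (contains) return("fully_overlapped")
  five1 <- if (str1 == "+") s1 else e1
  five2 <- if (str2 == "+") s2 else e2
  three1 <- if (str1 == "+") e1 else s1
  three2 <- if (str2 == "+") e2 else s2
  in_ov <- function(x) x >= ov_s && x <= ov_e
  h2h <- in_ov(five1) && in_ov(five2)
  t2t <- in_ov(three1) && in_ov(three2)
  if (h2h && !t2t) return("head_to_head")
  if (t2t && !h2h) return("tail_to_tail")
  NA_character_  # ambiguous or unlabeled: a trichotomy violation
}

# Naive O(n^3) complete-linkage agglomerator; returns sorted merge heights.
oracle_complete_linkage_heights <- function(x) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  sort(heights)
}

# Venn region counts by literal membership enumeration.
oracle_venn <- function(sets) {
  ids <- unique(unlist(sets))
  n <- length(sets)
  out <- list()
  for (mask in 1:(2^n - 1)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    cnt <- sum(vapply(ids, function(id) {
      all(vapply(seq_len(n), function(k) {
        (id %in% sets[[k]]) == inset[k]
      }, logical(1)))
    }, logical(1)))
    out[[paste(as.integer(inset), collapse = "")]] <- cnt
  }
  out
}

# Small default pair specification reused by simulation-driven tests.
test_pair_spec <- function(n_con = 10, n_dis = 5, rho = 0.95) {
  data.frame(
    topology = c("head_to_head", "tail_to_tail", "fully_overlapped"),
    class = c("concordant", "concordant", "discordant"),
    rho = c(rho, rho, -rho),
    n = c(ceiling(n_con / 2), floor(n_con / 2), n_dis)
  )
}

# One pass of the count pipeline: filter, size factors, log matrix, DE call.
run_mini_pipeline <- function(dat, group_a, group_b) {
  filt <- filter_low_expression(dat$counts)
  s <- size_factors(filt)
  lg <- transform_log(normalize_counts(filt, s))
  a <- estimate_dispersion(filt, dat$design, s)
  de <- call_de(wald_test(filt, dat$design, s, a, group_a, group_b))
  list(filt = filt, s = s, lg = lg, de = de)
}
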