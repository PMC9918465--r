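two_group_design <- function(n_per = 4) {
  data.frame(
    sample_id = c(paste0("A_", 1:n_per), paste0("B_", 1:n_per)),
    group = rep(c("A", "B"), each = n_per),
    replicate = rep(1:n_per, 2)
  )
}

nb_matrix <- function(mu, alpha, design, lfc_b = 0, seed = 1) {
  set.seed(seed)
  n <- length(mu)
  cols <- lapply(design$group, function(g) {
    m <- if (g == "B") mu * 2^lfc_b else mu
    rnbinom(n, mu = m, size = 1 / alpha)
  })
  k <- do.call(cbind, cols)
  dimnames(k) <- list(paste0("g", seq_len(n)), design$sample_id)
  k
}

test_that("BH adjustment matches the literal step-up rule", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.42), 0.42)
  set.seed(123)
  for (i in 1:100) {
    p <- runif(sample(1:50, 1))
    expect_equal(adjust_bh(p), oracle_bh(p))
  }
  # invariant to permutation, up to reordering
  p <- runif(30)
  o <- sample(30)
  expect_equal(adjust_bh(p)[o], adjust_bh(p[o]))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("moment dispersion floors Poisson-like and constant features", {
  design <- two_group_design(10)
  mu <- rep(100, 1000)
  k <- nb_matrix(mu, alpha = 1e6, design, seed = 2)  # size huge -> Poisson
  k <- matrix(rpois(1000 * 20, 100), 1000, 20,
              dimnames = list(paste0("g", 1:1000), design$sample_id))
  a <- estimate_dispersion(k, design, rep(1, 20))
  expect_lt(median(a), 0.01)
  const <- matrix(5L, 2, 20, dimnames = list(c("c1", "c2"), design$sample_id))
  expect_equal(unname(estimate_dispersion(const, design, rep(1, 20))),
               c(1e-8, 1e-8))
})

test_that("moment dispersion recovers a planted alpha at large n", {
  design <- data.frame(sample_id = paste0("s", 1:200),
                       group = rep(c("A", "B"), each = 100),
                       replicate = rep(1:100, 2))
  set.seed(4)
  k <- matrix(rnbinom(500 * 200, mu = 100, size = 1 / 0.5), 500, 200,
              dimnames = list(paste0("g", 1:500), design$sample_id))
  a <- estimate_dispersion(k, design, rep(1, 200))
  expect_gt(median(a), 0.35)
  expect_lt(median(a), 0.65)
})

test_that("Wald test is symmetric, handles degenerate input and recovers planted effects", {
  design <- two_group_design(4)
  k <- nb_matrix(rep(50, 20), 0.1, design, seed = 5)
  k[1, ] <- rep(c(10L, 20L, 30L, 40L), 2)  # identical across groups
  k[2, ] <- 0L                             # all-zero feature
  s <- rep(1, 8); names(s) <- design$sample_id
  de <- wald_test(k, design, s, 0.1, "A", "B")
  expect_equal(de$results$log2fc[1], 0)
  expect_equal(de$results$pvalue[1], 1)
  expect_equal(de$results$log2fc[2], 0)
  expect_equal(de$results$pvalue[2], 1)

  # swapping groups negates fold changes and keeps p-values
  rev <- wald_test(k, design, s, 0.1, "B", "A")
  expect_equal(rev$results$log2fc, -de$results$log2fc)
  expect_equal(rev$results$pvalue, de$results$pvalue)

  # recovery: planted log2FC = 3 at mean 200, alpha 0.05, 4 vs 4
  med_lfc <- vapply(1:50, function(seed) {
    k2 <- nb_matrix(rep(200, 40), 0.05, design, lfc_b = 3, seed = seed)
    median(wald_test(k2, design, s, 0.05, "A", "B")$results$log2fc)
  }, numeric(1))
  expect_lt(median(abs(med_lfc - 3)), 0.5)

  expect_error(wald_test(k, design, s, 0.1, "A", "C"), "absent")
})

test_that("DE calling applies a strict adjusted-p threshold with signed directions", {
  cmp <- list(name = "BvsA", group_a = "A", group_b = "B",
              results = data.frame(
                feature_id = c("a", "b", "c"),
                base_mean = 10, log2fc = c(2, -2, 1), se = 1,
                wald_z = c(2, -2, 1),
                pvalue = c(0.01, 0.02, 0.5),
                padj = c(0.049, 0.05, 0.9)))
  class(cmp) <- "de_comparison"
  called <- call_de(cmp, 0.05)
  expect_equal(called$results$called, c(TRUE, FALSE, FALSE))
  expect_equal(called$results$direction, c("up", "ns", "ns"))
  raw <- call_de(cmp, 0.05, use_raw_p = TRUE)
  expect_equal(raw$results$called, c(TRUE, TRUE, FALSE))
  expect_equal(raw$results$direction[2], "down")
})

test_that("up/down summaries report rounded percentages", {
  mk <- function(n_up, n_down) {
    res <- data.frame(
      feature_id = paste0("g", seq_len(n_up + n_down + 2)),
      base_mean = 1,
      log2fc = c(rep(1, n_up), rep(-1, n_down), 0, 0),
      se = 1, wald_z = 0, pvalue = 0, padj = 0,
      called = c(rep(TRUE, n_up + n_down), FALSE, FALSE),
      direction = c(rep("up", n_up), rep("down", n_down), "ns", "ns"))
    structure(list(name = "x", group_a = "A", group_b = "B", results = res),
              class = "de_comparison")
  }
  s <- summarize_de(mk(12, 31))  # 12 of 43 up
  expect_equal(s$n_called, 43)
  expect_equal(s$pct_up, 28)
  expect_equal(summarize_de(mk(0, 0))$pct_up, 0)
  s2 <- summarize_de(mk(1, 1))
  expect_equal(c(s2$pct_up, s2$pct_down), c(50, 50))
})

test_that("Venn partitions match bitmask enumeration", {
  sets <- list(TF = c("a", "b", "c"), OF = c("b", "c", "d"), OT = c("c", "e"))
  out <- intersect_de_sets(sets)
  oracle <- oracle_venn(sets)
  for (i in seq_len(nrow(out$regions))) {
    key <- paste(as.integer(out$regions[i, names(sets)]), collapse = "")
    expect_equal(out$regions$count[i], oracle[[key]])
  }
  expect_equal(out$shared_fraction["TF", "OF"], 2 / 3)

  disj <- intersect_de_sets(list(A = c("x"), B = c("y")))
  both <- disj$regions$count[disj$regions$A & disj$regions$B]
  expect_equal(both, 0)
  same <- intersect_de_sets(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(same$regions$count[same$regions$A & same$regions$B], 2)
  expect_equal(sum(same$regions$count), 2)

  set.seed(9)
  for (i in 1:20) {
    rs <- list(A = sample(letters, 8), B = sample(letters, 12),
               C = sample(letters, 5))
    out <- intersect_de_sets(rs)
    oracle <- oracle_venn(rs)
    keys <- apply(out$regions[, names(rs)], 1,
                  function(r) paste(as.integer(r), collapse = ""))
    expect_equal(out$regions$count, unlist(oracle[keys], use.names = FALSE))
  }
})

test_that("null simulations keep false-positive rates near nominal", {
  design <- two_group_design(4)
  s <- rep(1, 8); names(s) <- design$sample_id
  raw_rate <- vapply(1:10, function(seed) {
    k <- nb_matrix(rep(100, 500), 0.1, design, seed = 100 + seed)
    de <- wald_test(k, design, s,
                    estimate_dispersion(k, design, s), "A", "B")
    mean(de$results$pvalue < 0.05)
  }, numeric(1))
  expect_lt(mean(raw_rate), 0.08)
  expect_gt(mean(raw_rate), 0.02)
})
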