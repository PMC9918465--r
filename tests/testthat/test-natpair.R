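fs_pair <- function(nat, mrna) {
  feature_set(c("nat", "mrna"), "chr1",
              c(nat[1], mrna[1]), c(nat[2], mrna[2]),
              c(nat[3], mrna[3]), c("NAT", "mRNA"))
}

test_that("overlap detection applies the >= 50 bp antisense gate inclusively", {
  mk <- function(nat_start) {
    fs <- fs_pair(c(nat_start, 900, "-"), c(100, 500, "+"))
    find_overlaps(features_by_biotype(fs, "NAT"),
                  features_by_biotype(fs, "mRNA"))
  }
  # overlap [451, 500] = 50 bp: retained
  expect_equal(mk(451)$overlap_len, 50L)
  # overlap [460, 500] = 41 bp: excluded
  expect_equal(nrow(mk(460)), 0)
  # 49 and 51 around the boundary
  expect_equal(nrow(mk(452)), 0)   # 49 bp
  expect_equal(mk(450)$overlap_len, 51L)

  # same-strand overlap of any length is never a candidate
  fs <- fs_pair(c(100, 900, "+"), c(100, 500, "+"))
  expect_equal(nrow(find_overlaps(features_by_biotype(fs, "NAT"),
                                  features_by_biotype(fs, "mRNA"))), 0)
})

test_that("overlap scan is symmetric and admits many-to-many pairs", {
  fs <- feature_set(
    c("n1", "n2", "m1", "m2"), "chr1",
    c(100, 300, 150, 350), c(400, 700, 600, 800),
    c("-", "-", "+", "+"), c("NAT", "NAT", "mRNA", "mRNA"))
  nats <- features_by_biotype(fs, "NAT")
  mrnas <- features_by_biotype(fs, "mRNA")
  a <- find_overlaps(nats, mrnas)
  expect_equal(nrow(a), 4)  # every NAT overlaps both mRNAs by >= 50
  # scanning from the mRNA side gives the same pair set
  b <- find_overlaps(
    feature_set(mrnas$feature_id, mrnas$chrom, mrnas$start, mrnas$end,
                mrnas$strand, rep("NAT", 2)),
    feature_set(nats$feature_id, nats$chrom, nats$start, nats$end,
                nats$strand, rep("mRNA", 2)))
  expect_setequal(paste(a$nat_id, a$mrna_id, a$overlap_len),
                  paste(b$mrna_id, b$nat_id, b$overlap_len))
})

test_that("topology classification follows strand-aware termini", {
  # overlap [400,500] holds mRNA 5' (400) and NAT 5' (500): head-to-head
  expect_equal(classify_topology(100, 500, "-", 400, 900, "+"),
               "head_to_head")
  # overlap [400,500] holds both 3' termini: tail-to-tail
  expect_equal(classify_topology(400, 900, "-", 100, 500, "+"),
               "tail_to_tail")
  # containment: fully overlapped
  expect_equal(classify_topology(200, 400, "-", 100, 900, "+"),
               "fully_overlapped")
  expect_equal(classify_topology(100, 900, "-", 200, 400, "+"),
               "fully_overlapped")
  expect_error(classify_topology(1, 10, "+", 5, 20, "+"), "opposite-strand")
  expect_error(classify_topology(1, 10, "+", 50, 60, "-"), "overlapping")
})

test_that("topology labels agree with the literal oracle on random pairs", {
  set.seed(31)
  n_checked <- 0
  while (n_checked < 300) {
    s1 <- sample(1:50, 1); e1 <- s1 + sample(0:30, 1)
    s2 <- sample(1:50, 1); e2 <- s2 + sample(0:30, 1)
    if (max(s1, s2) > min(e1, e2)) next
    str1 <- sample(c("+", "-"), 1); str2 <- if (str1 == "+") "-" else "+"
    expect_equal(classify_topology(s1, e1, str1, s2, e2, str2),
                 oracle_topology(s1, e1, str1, s2, e2, str2))
    n_checked <- n_checked + 1
  }
})

test_that("pair correlation matches the Pearson formula and flags constants", {
  lg <- rbind(x = c(1, 2, 3), y = c(2, 4, 7), z = c(5, 5, 5))
  colnames(lg) <- paste0("s", 1:3)
  pc <- pair_correlation("x", "y", lg, colnames(lg))
  expect_equal(pc$r, 0.9934, tolerance = 1e-4)
  expect_equal(pc$r2, pc$r^2)
  expect_equal(pair_correlation("x", "x", lg, colnames(lg))$r, 1)
  flat <- pair_correlation("x", "z", lg, colnames(lg))
  expect_true(is.na(flat$r))
  expect_error(pair_correlation("x", "y", lg, c("s1", "s2")), ">= 3")
})

test_that("pair calling applies DE, fold and correlation gates in order", {
  samples <- paste0("s", 1:6)
  lg <- rbind(
    n_up = c(1, 2, 3, 4, 5, 6), m_up = c(1.1, 2, 3.2, 4, 5, 6.1),
    n_dn = 6:1, m_flat = c(3, 4, 3, 4, 3, 4))
  colnames(lg) <- samples
  cand <- data.frame(
    nat_id = c("n_up", "n_up", "n_up", "n_dn"),
    mrna_id = c("m_up", "m_up", "m_flat", "m_up"),
    overlap_len = 100L,
    topology = "head_to_head")
  res <- data.frame(
    feature_id = c("n_up", "m_up", "n_dn", "m_flat"),
    base_mean = 10, log2fc = c(2, 3, -2, 0.5), se = 1, wald_z = 2,
    pvalue = 0.001, padj = c(0.001, 0.001, 0.001, 0.9),
    called = c(TRUE, TRUE, TRUE, FALSE),
    direction = c("up", "up", "down", "ns"))
  de <- structure(list(name = "x", group_a = "A", group_b = "B",
                       results = res), class = "de_comparison")
  calls <- call_pairs(cand[c(1, 4), ], de, lg, samples)
  expect_equal(calls$pair_class, c("concordant", "discordant"))
  expect_equal(calls$nat_log2fc, c(2, -2))
  # mRNA not DE (and below the fold gate): candidate dropped, counted
  calls2 <- call_pairs(cand[3, , drop = FALSE], de, lg, samples)
  expect_equal(nrow(calls2), 0)
  expect_equal(unname(attr(calls2, "excluded")["mrna_not_de"]), 1)
  # correlation below the gate: reported NC, not dropped
  lg_nc <- lg
  set.seed(1)
  lg_nc["m_up", ] <- c(4, 1, 5, 2, 4, 3)
  calls3 <- call_pairs(cand[1, , drop = FALSE], de, lg_nc, samples)
  expect_equal(calls3$pair_class, "NC")
})

test_that("pair summaries tally classes and topologies consistently", {
  empty <- data.frame(nat_id = character(), mrna_id = character(),
                      overlap_len = integer(), topology = character(),
                      pair_class = character())
  s0 <- summarize_pairs(empty)
  expect_equal(s0$n_pairs, 0)
  expect_true(all(s0$by_class == 0))

  calls <- data.frame(
    nat_id = paste0("n", 1:3), mrna_id = paste0("m", 1:3),
    overlap_len = 60L,
    topology = c("head_to_head", "tail_to_tail", "fully_overlapped"),
    pair_class = c("concordant", "discordant", "NC"))
  s <- summarize_pairs(calls)
  expect_true(all(s$by_topology == 1))
  expect_equal(sum(s$by_class), s$n_pairs)
  expect_equal(sum(s$class_by_topology), s$n_pairs)

  set.seed(8)
  big <- data.frame(
    nat_id = paste0("n", 1:50), mrna_id = paste0("m", 1:50),
    overlap_len = 60L,
    topology = sample(c("head_to_head", "tail_to_tail", "fully_overlapped"),
                      50, TRUE),
    pair_class = sample(c("concordant", "discordant", "NC"), 50, TRUE))
  s2 <- summarize_pairs(big)
  expect_equal(as.vector(s2$by_topology),
               as.vector(table(factor(big$topology,
                 c("head_to_head", "tail_to_tail", "fully_overlapped")))))
})

test_that("no pair is ever called between non-overlapping features", {
  cfg <- sim_config(n_mrna = 80, n_linc = 20, n_nat = 30, seed = 21,
                    pair_spec = test_pair_spec())
  d <- simulate_dataset(cfg)
  mr <- features_by_biotype(d$annotation, "mRNA")
  nt <- features_by_biotype(d$annotation, "NAT")
  cand <- classify_candidates(find_overlaps(nt, mr), d$annotation)
  pl <- run_mini_pipeline(d, "F", "T")
  cand <- cand[cand$nat_id %in% rownames(pl$lg) &
                 cand$mrna_id %in% rownames(pl$lg), ]
  calls <- call_pairs(cand, pl$de, pl$lg,
                      d$design$sample_id[d$design$group %in% c("F", "T")])
  for (i in seq_len(nrow(calls))) {
    ni <- match(calls$nat_id[i], d$annotation$feature_id)
    mi <- match(calls$mrna_id[i], d$annotation$feature_id)
    ov <- min(d$annotation$end[ni], d$annotation$end[mi]) -
      max(d$annotation$start[ni], d$annotation$start[mi]) + 1
    expect_gte(ov, 50)
    expect_true(d$annotation$strand[ni] != d$annotation$strand[mi])
  }
})
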