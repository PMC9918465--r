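#' Simulation configuration
#'
#' Defines the synthetic experiment the generator emulates: a three-morphotype
#' design with four replicates each, a transcript portfolio of ~10,774 mRNAs,
#' ~1,510 intergenic lncRNAs and ~3,279 antisense lncRNAs (scalable down),
#' lncRNAs systematically lower-expressed than mRNAs (`lnc_mean_scale`),
#' negative-binomial count noise, planted group-specific fold changes, and
#' planted correlated NAT-mRNA pairs.
#'
#' `pair_spec` is a data.frame with columns `topology`
#' (`head_to_head` / `tail_to_tail` / `fully_overlapped`), `class`
#' (`concordant` / `discordant`), `rho` (signed latent correlation: positive
#' for concordant, negative for discordant pairs) and `n` (number of pairs).
#'
#' @param n_mrna,n_linc,n_nat portfolio sizes (`n_nat <= n_mrna`).
#' @param n_groups number of groups (morphotypes), default 3.
#' @param reps_per_group replicates per group, default 4.
#' @param lnc_mean_scale lncRNA baseline-mean multiplier in (0, 1], default 0.25.
#' @param dispersion_range NB dispersion alpha drawn uniformly from this
#'   interval, default `c(0.05, 0.3)`.
#' @param de_fraction fraction of features with a planted effect per
#'   non-reference group, default 0.1.
#' @param planted_lfc_magnitude |log2FC| of planted effects, default 2.
#' @param pair_spec planted-pair specification (see Details); `NULL` for none.
#' @param library_size_range relative library-size factors drawn log-uniformly,
#'   default `c(0.5, 2)`.
#' @param mrna_len_range,nat_ext_range,gap mRNA length range, NAT extension
#'   beyond its mRNA, and intergenic gap (bp) used for the layout.
#' @param min_overlap minimum planted antisense overlap (bp), default 50.
#' @param ct_sigma qPCR Ct measurement noise (cycles), default 0.2.
#' @param ct_baseline baseline cycle offset, default 35.
#' @param seed integer RNG seed (mandatory).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_mrna = 10774, n_linc = 1510, n_nat = 3279,
                       n_groups = 3, reps_per_group = 4,
                       lnc_mean_scale = 0.25,
                       dispersion_range = c(0.05, 0.3),
                       de_fraction = 0.1,
                       planted_lfc_magnitude = 2,
                       pair_spec = NULL,
                       library_size_range = c(0.5, 2),
                       mrna_len_range = c(500, 3000),
                       nat_ext_range = c(100, 1000),
                       gap = 6000,
                       min_overlap = 50,
                       ct_sigma = 0.2,
                       ct_baseline = 35,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_mrna >= 1, n_linc >= 0, n_nat >= 0,
            n_groups >= 1, reps_per_group >= 1,
            lnc_mean_scale > 0, lnc_mean_scale <= 1,
            all(dispersion_range > 0), length(dispersion_range) == 2,
            de_fraction >= 0, de_fraction <= 1,
            planted_lfc_magnitude >= 0,
            all(library_size_range > 0),
            min_overlap >= 1, ct_sigma >= 0)
  if (n_nat > n_mrna) {
    stop("each NAT needs a distinct mRNA partner: n_nat must be <= n_mrna")
  }
  if (!is.null(pair_spec)) {
    needed <- c("topology", "class", "rho", "n")
    if (!all(needed %in% names(pair_spec))) {
      stop("pair_spec needs columns: ", paste(needed, collapse = ", "))
    }
    if (!all(pair_spec$topology %in%
             c("head_to_head", "tail_to_tail", "fully_overlapped"))) {
      stop("unknown pair topology in pair_spec")
    }
    if (!all(pair_spec$class %in% c("concordant", "discordant"))) {
      stop("pair class must be concordant or discordant")
    }
    if (any(abs(pair_spec$rho) >= 1) || any(pair_spec$rho == 0)) {
      stop("latent correlation rho must lie in (-1, 0) or (0, 1)")
    }
    bad <- (pair_spec$class == "concordant" & pair_spec$rho < 0) |
      (pair_spec$class == "discordant" & pair_spec$rho > 0)
    if (any(bad)) {
      stop("impossible pair request: concordant pairs need rho > 0, ",
           "discordant pairs need rho < 0")
    }
    if (sum(pair_spec$n) > n_nat) stop("pair_spec requests more pairs than n_nat")
  }
  cfg <- list(
    n_mrna = n_mrna, n_linc = n_linc, n_nat = n_nat,
    n_groups = n_groups, reps_per_group = reps_per_group,
    lnc_mean_scale = lnc_mean_scale,
    dispersion_range = dispersion_range,
    de_fraction = de_fraction,
    planted_lfc_magnitude = planted_lfc_magnitude,
    pair_spec = pair_spec,
    library_size_range = library_size_range,
    mrna_len_range = mrna_len_range,
    nat_ext_range = nat_ext_range,
    gap = gap, min_overlap = min_overlap,
    ct_sigma = ct_sigma, ct_baseline = ct_baseline,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

sim_group_labels <- function(cfg) {
  if (cfg$n_groups == 3) c("F", "T", "O") else paste0("G", seq_len(cfg$n_groups))
}

#' Generate a synthetic annotation
#'
#' Lays all features on one linear chromosome: mRNAs in non-overlapping
#' slots (random strand), lincRNAs strictly intergenic in the gaps, and each
#' NAT antisense to a distinct mRNA with the requested overlap topology and
#' an overlap of at least `min_overlap` bp. The planted (NAT, mRNA)
#' assignment with its topology, correlation class and latent rho is
#' attached as the `"pairs"` attribute. Deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @return a [feature_set()] with attribute `"pairs"`.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gap <- config$gap
  ext_max <- config$nat_ext_range[2]
  if (gap < 2 * ext_max + 3600) {
    stop("gap too small for the requested NAT extensions; ",
         "increase `gap` (chromosome layout parameter)")
  }
  slot <- config$mrna_len_range[2] + gap
  # --- mRNAs ---
  m_len <- sample(config$mrna_len_range[1]:config$mrna_len_range[2],
                  config$n_mrna, replace = TRUE)
  m_start <- gap + (seq_len(config$n_mrna) - 1L) * slot + 1L
  m_end <- m_start + m_len - 1L
  m_strand <- sample(c("+", "-"), config$n_mrna, replace = TRUE)
  m_id <- sprintf("MRNA%05d", seq_len(config$n_mrna))
  # --- lincRNAs, in the gap after mRNA (cycled), inside a safe window ---
  if (config$n_linc > 0) {
    host <- rep_len(seq_len(config$n_mrna), config$n_linc)
    l_len <- sample(200:2000, config$n_linc, replace = TRUE)
    l_start <- m_end[host] + ext_max + 500L +
      sample(0:99, config$n_linc, replace = TRUE)
    l_end <- l_start + l_len - 1L
    l_strand <- sample(c("+", "-"), config$n_linc, replace = TRUE)
    l_id <- sprintf("LINC%05d", seq_len(config$n_linc))
  } else {
    l_id <- l_strand <- character(0); l_start <- l_end <- integer(0)
  }
  # --- NATs: planted topologies first, then a uniform mix ---
  n_nat <- config$n_nat
  topo <- character(0)
  cls <- character(0)
  rho <- numeric(0)
  if (!is.null(config$pair_spec)) {
    topo <- rep(config$pair_spec$topology, config$pair_spec$n)
    cls <- rep(config$pair_spec$class, config$pair_spec$n)
    rho <- rep(config$pair_spec$rho, config$pair_spec$n)
  }
  n_free <- n_nat - length(topo)
  if (n_free > 0) {
    topo <- c(topo, sample(c("head_to_head", "tail_to_tail", "fully_overlapped"),
                           n_free, replace = TRUE))
    cls <- c(cls, rep("none", n_free))
    rho <- c(rho, rep(NA_real_, n_free))
  }
  if (n_nat > 0) {
    host_m <- seq_len(n_nat)   # distinct partner mRNA per NAT
    hs <- m_start[host_m]; he <- m_end[host_m]
    hlen <- he - hs + 1L
    hstr <- m_strand[host_m]
    ext <- sample(config$nat_ext_range[1]:ext_max, n_nat, replace = TRUE)
    # overlap length: leave >= 1 bp of the mRNA outside for the edge
    # topologies, >= 1 bp margin on both sides for full containment
    max_ov <- ifelse(topo == "fully_overlapped", hlen - 2L, hlen - 1L)
    ov <- config$min_overlap +
      floor(stats::runif(n_nat) * (max_ov - config$min_overlap + 1L))
    n_start <- integer(n_nat); n_end <- integer(n_nat)
    # edge placements depend on which mRNA end carries the relevant termini
    left_edge <- (topo == "head_to_head" & hstr == "+") |
      (topo == "tail_to_tail" & hstr == "-")
    right_edge <- (topo == "head_to_head" & hstr == "-") |
      (topo == "tail_to_tail" & hstr == "+")
    full <- topo == "fully_overlapped"
    n_start[left_edge] <- hs[left_edge] - ext[left_edge]
    n_end[left_edge] <- hs[left_edge] + ov[left_edge] - 1L
    n_start[right_edge] <- he[right_edge] - ov[right_edge] + 1L
    n_end[right_edge] <- he[right_edge] + ext[right_edge]
    if (any(full)) {
      off <- 1L + floor(stats::runif(sum(full)) *
                          (hlen[full] - ov[full] - 1L))
      n_start[full] <- hs[full] + off
      n_end[full] <- n_start[full] + ov[full] - 1L
    }
    n_strand <- ifelse(hstr == "+", "-", "+")
    n_id <- sprintf("NAT%05d", seq_len(n_nat))
    pairs <- data.frame(nat_id = n_id, mrna_id = m_id[host_m],
                        topology = topo, class = cls, rho = rho,
                        stringsAsFactors = FALSE)
  } else {
    n_id <- n_strand <- character(0); n_start <- n_end <- integer(0)
    pairs <- data.frame(nat_id = character(), mrna_id = character(),
                        topology = character(), class = character(),
                        rho = numeric(), stringsAsFactors = FALSE)
  }
  fs <- feature_set(
    feature_id = c(m_id, l_id, n_id),
    chrom = "chr1",
    start = c(m_start, l_start, n_start),
    end = c(m_end, l_end, n_end),
    strand = c(m_strand, l_strand, n_strand),
    biotype = c(rep("mRNA", config$n_mrna),
                rep("lincRNA", config$n_linc),
                rep("NAT", n_nat))
  )
  attr(fs, "pairs") <- pairs
  fs
}

#' Generate synthetic counts with planted truth
#'
#' Counts are drawn `K_ij ~ NB(mean = s_j * mu_i * 2^(lfc_i,g(j)) * L_ij,
#' dispersion alpha_i)`: `s_j` a log-uniform library-size factor, `mu_i` a
#' log-normal baseline (scaled by `lnc_mean_scale` for lncRNA biotypes),
#' `lfc` the planted group effects (the first group is the reference and
#' carries none), and `L_ij` a per-pair latent log-normal multiplier shared
#' between pair members with the same sign (concordant) or inverted sign
#' (discordant). The latent variance is calibrated so that the realized
#' log-expression correlation targets the requested rho; it is a target, not
#' an exact per-draw value. Deterministic given the config seed.
#'
#' @param annotation output of [generate_annotation()] (carries the planted
#'   pair assignment).
#' @param config the same [sim_config()].
#' @return list `(counts, design, truth)`; `truth` is a `truth_table` list
#'   with `features` (feature_id, biotype, mu, alpha, one `lfc_<group>`
#'   column per group), `pairs` (nat_id, mrna_id, topology, class, rho) and
#'   `samples` (sample_id, planted library_factor).
#' @export
generate_counts <- function(annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  pairs <- attr(annotation, "pairs")
  if (is.null(pairs)) stop("annotation lacks the planted-pair attribute; ",
                           "use generate_annotation()")
  set.seed(config$seed + 1L)
  n_feat <- nrow(annotation)
  groups <- sim_group_labels(config)
  reps <- config$reps_per_group
  n_samp <- config$n_groups * reps
  design <- data.frame(
    sample_id = paste0(rep(groups, each = reps), "_", seq_len(reps)),
    group = rep(groups, each = reps),
    replicate = rep(seq_len(reps), times = config$n_groups),
    stringsAsFactors = FALSE
  )
  is_lnc <- annotation$biotype %in% c("lincRNA", "NAT")
  mu <- stats::rlnorm(n_feat, meanlog = log(200), sdlog = 1.2)
  mu[is_lnc] <- mu[is_lnc] * config$lnc_mean_scale
  alpha <- stats::runif(n_feat, config$dispersion_range[1],
                        config$dispersion_range[2])
  # planted correlated pairs are modeled as well-expressed, low-dispersion
  # transcripts: a realized r^2 >= 0.6 across 8 samples is unattainable when
  # per-sample NB noise exceeds the shared signal, and validated
  # sense-antisense pairs are by construction robustly detectable transcripts
  planted_members_nat <- match(pairs$nat_id[pairs$class != "none"],
                               annotation$feature_id)
  planted_members_mrna <- match(pairs$mrna_id[pairs$class != "none"],
                                annotation$feature_id)
  pm <- c(planted_members_nat, planted_members_mrna)
  if (length(pm) > 0) {
    mu[pm] <- stats::rlnorm(length(pm), meanlog = log(1000), sdlog = 0.3)
    mu[pm] <- mu[pm] * ifelse(is_lnc[pm], config$lnc_mean_scale, 1)
    alpha[pm] <- stats::runif(length(pm), 0.005, 0.02)
  }
  # planted group effects (reference group = groups[1], lfc 0)
  lfc <- matrix(0, n_feat, config$n_groups, dimnames = list(NULL, groups))
  mag <- config$planted_lfc_magnitude
  planted <- pairs[pairs$class != "none", , drop = FALSE]
  pair_rows_nat <- match(planted$nat_id, annotation$feature_id)
  pair_rows_mrna <- match(planted$mrna_id, annotation$feature_id)
  if (nrow(planted) > 0 && config$n_groups >= 2) {
    sgn <- sample(c(-1, 1), nrow(planted), replace = TRUE)
    for (g in seq_len(config$n_groups)[-1]) {
      lfc[pair_rows_nat, g] <- sgn * mag
      lfc[pair_rows_mrna, g] <- ifelse(planted$class == "concordant",
                                       sgn, -sgn) * mag
    }
  }
  pair_member <- union(pair_rows_nat, pair_rows_mrna)
  free <- setdiff(seq_len(n_feat), pair_member)
  if (config$de_fraction > 0 && config$n_groups >= 2) {
    n_de <- floor(config$de_fraction * n_feat)
    for (g in seq_len(config$n_groups)[-1]) {
      pick <- sample(free, min(n_de, length(free)))
      lfc[pick, g] <- sample(c(-mag, mag), length(pick), replace = TRUE)
    }
  }
  # library sizes, log-uniform
  lsr <- config$library_size_range
  s <- exp(stats::runif(n_samp, log(lsr[1]), log(lsr[2])))
  names(s) <- design$sample_id
  # latent pair multipliers on the log2 scale
  Lmult <- matrix(1, n_feat, n_samp)
  if (nrow(planted) > 0) {
    # between-group variance already shared by the pair members through their
    # planted fold changes, across a balanced two-group comparison
    b_shared <- if (config$n_groups >= 2) mag^2 / 4 else 0
    for (p in seq_len(nrow(planted))) {
      i_n <- pair_rows_nat[p]; i_m <- pair_rows_mrna[p]
      v_noise <- mean((1 / log(2))^2 *
                        (1 / mu[c(i_n, i_m)] + alpha[c(i_n, i_m)]))
      r <- abs(planted$rho[p])
      sigma2 <- max(0, r / (1 - r) * v_noise - b_shared)
      z <- stats::rnorm(n_samp, 0, sqrt(sigma2))
      Lmult[i_n, ] <- 2^z
      Lmult[i_m, ] <- 2^(sign(planted$rho[p]) * z)
    }
  }
  grp_idx <- match(design$group, groups)
  mean_mat <- (mu * 2^(lfc[, grp_idx, drop = FALSE])) * Lmult
  mean_mat <- sweep(mean_mat, 2, s, "*")
  counts <- matrix(
    stats::rnbinom(n_feat * n_samp, mu = as.numeric(mean_mat),
                   size = rep(1 / alpha, times = n_samp)),
    nrow = n_feat,
    dimnames = list(annotation$feature_id, design$sample_id)
  )
  truth_feat <- data.frame(feature_id = annotation$feature_id,
                           biotype = annotation$biotype,
                           mu = mu, alpha = alpha,
                           stringsAsFactors = FALSE)
  for (g in seq_len(config$n_groups)) {
    truth_feat[[paste0("lfc_", groups[g])]] <- lfc[, g]
  }
  truth <- structure(
    list(features = truth_feat, pairs = pairs,
         samples = data.frame(sample_id = design$sample_id,
                              library_factor = unname(s),
                              stringsAsFactors = FALSE)),
    class = "truth_table")
  list(counts = counts, design = design, truth = truth)
}

#' Generate a synthetic qPCR Ct table
#'
#' Emulates an RT-qPCR assay with amplification efficiency fixed at 2 (one
#' doubling per cycle): per replicate,
#' `Ct = c0_gene - log2(relative expression in condition) + eps`,
#' `eps ~ N(0, ct_sigma^2)`, where the relative expression of a gene in a
#' condition is `2^lfc` from the planted truth and `c0` reflects the gene's
#' baseline abundance. Reference genes must carry no planted effect.
#' Deterministic given the config seed.
#'
#' @param truth a `truth_table` from [generate_counts()].
#' @param config the [sim_config()].
#' @param targets target gene ids.
#' @param references reference gene ids (zero planted effect in all groups).
#' @return a Ct table `(sample_id, condition, gene_id, ct)`; the first group
#'   label is the control condition.
#' @export
generate_ct_table <- function(truth, config, targets, references) {
  stopifnot(inherits(config, "sim_config"))
  tf <- truth$features
  groups <- sim_group_labels(config)
  lfc_cols <- paste0("lfc_", groups)
  idx_ref <- match(references, tf$feature_id)
  if (any(is.na(idx_ref))) stop("unknown reference gene id")
  if (any(tf[idx_ref, lfc_cols] != 0)) {
    stop("reference gene '",
         references[which(rowSums(tf[idx_ref, lfc_cols] != 0) > 0)[1]],
         "' has a planted effect; pick an unaffected gene")
  }
  idx_tar <- match(targets, tf$feature_id)
  if (any(is.na(idx_tar))) stop("unknown target gene id")
  set.seed(config$seed + 2L)
  genes <- c(targets, references)
  gi <- c(idx_tar, idx_ref)
  c0 <- config$ct_baseline - log2(tf$mu[gi])
  rows <- list()
  for (g in seq_along(groups)) {
    lfc_g <- tf[[lfc_cols[g]]][gi]
    for (r in seq_len(config$reps_per_group)) {
      ct <- c0 - lfc_g + stats::rnorm(length(genes), 0, config$ct_sigma)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = paste0(groups[g], "_", r),
        condition = groups[g],
        gene_id = genes,
        ct = ct,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a full dataset
#'
#' Convenience wrapper: [generate_annotation()] then [generate_counts()].
#'
#' @param config a [sim_config()].
#' @return list `(annotation, counts, design, truth)`.
#' @export
simulate_dataset <- function(config) {
  ann <- generate_annotation(config)
  cd <- generate_counts(ann, config)
  c(list(annotation = ann), cd)
}
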