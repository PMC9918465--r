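---
title: "Methods: antisense lncRNA-mRNA pair detection and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: antisense lncRNA-mRNA pair detection and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncpair)
```

# Scope

`lncpair` implements a pipeline for discovering natural antisense
transcript (NAT) to mRNA regulatory pairs from multi-condition RNA-seq
count data, plus a ground-truth synthetic generator used to validate
every stage. This vignette documents the statistical model, each tunable
parameter and its default, what the generator does and does not emulate,
and the numerical and design decisions behind the implementation.

# Statistical model

## Filtering and normalization

- **CPM filter.** `filter_low_expression()` keeps features with mean
  counts-per-million strictly greater than `cpm_threshold = 1` across
  all samples. The strict inequality makes the boundary behavior
  unambiguous; a mean CPM of exactly 1 is dropped.
- **Size factors.** `size_factors()` is median-of-ratios: using only
  features with positive counts in every sample, the reference is the
  per-feature geometric mean `r_i = exp(mean(log k_i.))` and
  `s_j = median_i(k_ij / r_i)`. This estimator is robust to a minority
  of differentially expressed features but is *not* equivariant under
  arbitrary rescaling of the true library sizes — only the ratios
  `s_j / s_j'` are identified. All accuracy statements therefore compare
  estimated and planted factors after dividing each by its geometric
  mean.
- **Transform.** `transform_log()` is `log2(k/s + 1)`. It is a
  deliberately simple, monotone, variance-compressing stand-in for
  regularized-log transforms; it requires no fitted dispersion trend and
  is exactly invertible, at the cost of residual mean-variance
  dependence for low counts.

## Differential expression

`wald_test()` is a simplified two-group negative-binomial Wald test.

- **Dispersion.** `estimate_dispersion()` is method-of-moments on
  normalized counts: with grand mean `m_i` and pooled within-group
  variance `v_i` (group means removed, denominator `n - g`),
  `alpha_i = max((v_i - m_i) / m_i^2, 1e-8)`. The floor keeps
  Poisson-like features (empirical variance at or below the mean) from
  producing zero or negative dispersion. No shrinkage across features is
  applied; this trades some power at low counts for transparency.
- **Effect and error.** With pseudocount `c = 0.5`,
  `log2FC = log2((mu_B + c)/(mu_A + c))`. The delta-method variance of
  `log2 mu_G` under NB sampling (`Var(k) = mu + alpha mu^2`) is
  `(1/ln 2)^2 (1/n_G)(1/(mu_G + c) + alpha)`, summed over groups. The
  pseudocount bounds both the fold change and its variance when a group
  mean is zero.
- **Reference distribution.** The Wald ratio is referred two-sided to a
  *t* distribution with `n_A + n_B - 2` degrees of freedom rather than
  the standard normal. With four replicates per group the plug-in
  dispersion is itself noisy, and the normal reference is anticonservative:
  in repeated null simulations (8 samples, NB with `alpha = 0.1`) the
  raw false-positive rate at the 0.05 level is roughly 0.10 under the
  normal reference and 0.050-0.052 under the t reference. The t
  correction is the standard small-sample remedy for a variance
  estimated with few residual degrees of freedom; it converges to the
  normal as replication grows.
- **Multiplicity.** `adjust_bh()` wraps `stats::p.adjust(method = "BH")`
  after validating inputs; `call_de()` uses the strict rule
  `padj < alpha` with `alpha = 0.05`.

## Antisense pair detection

- **Candidates.** `find_overlaps()` intersects NAT and mRNA intervals
  (via `GenomicRanges::findOverlaps`, strand-blind) and keeps opposite-
  strand hits with 1-based inclusive overlap
  `min(end1, end2) - max(start1, start2) + 1 >= 50` bp
  (`pair_thresholds(min_overlap = 50)`).
- **Topology.** `classify_topology()`: if either interval contains the
  other the pair is `fully_overlapped`; otherwise the pair is
  `head_to_head` if both 5' termini lie inside the overlap window and
  `tail_to_tail` if both 3' termini do. For antisense, non-contained
  overlapping intervals exactly one of the two terminus conditions
  holds (the 5' terminus of the plus-strand member is its start and of
  the minus-strand member its end, so the two conditions partition the
  non-containment cases), making the three classes a true partition.
- **Regulatory class.** `call_pairs()` requires both members to be DE
  (`padj < 0.05`) with `|log2FC| >= 1` (at least two-fold). Among pairs
  passing those gates, the squared Pearson correlation `r^2` of the two
  members' `log2(normalized + 1)` profiles across the samples of the
  compared groups decides the label: `r^2 >= 0.6` with same-sign fold
  changes is `concordant`, with opposite signs `discordant`, and
  `r^2 < 0.6` is `NC` (non-correlated). Counts of candidates excluded at
  each gate are kept in the `excluded` attribute.

## Signatures, qPCR, enrichment

- `de_union()` plus `hier_cluster()` (Euclidean distance, complete
  linkage via `stats::hclust`) and `cut_tree()` recover condition
  signatures; `cluster_agreement()` scores them against the design with
  the adjusted Rand index (`mclust::adjustedRandIndex`).
- `compare_expression_levels()` runs a per-sample one-sided Wilcoxon
  rank-sum test (normal approximation, `exact = FALSE`) of the
  hypothesis that lncRNA expression is stochastically lower than mRNA
  expression.
- `delta_delta_ct()`: per replicate, `dCt = Ct(target) - mean
  Ct(references)` (arithmetic mean of reference Cts); `ddCt` is the
  difference of per-condition means against the control condition;
  `log2FC = -ddCt`, `fold = 2^-ddCt`, i.e. amplification efficiency
  fixed at 2. `compare_platforms()` reports the Pearson correlation and
  sign-agreement fraction between two fold-change sets sharing at least
  three genes.
- `ks_go_enrichment()` scores each GO term by a one-sided two-sample
  Kolmogorov-Smirnov test (`alternative = "greater"`, asymptotic)
  comparing the score distribution of annotated versus non-annotated
  genes; small sides (< 2 genes) are skipped, and a term annotating
  every scored gene is skipped with a warning since no outside
  distribution exists.

# The synthetic generator

`sim_config()` freezes all parameters plus a mandatory seed;
`simulate_dataset()` derives three independent sub-seeds (seed, seed+1,
seed+2) for annotation, counts, and Ct stages, so each stage is
individually reproducible.

## What it emulates

- **Annotation.** One chromosome laid out in fixed-width slots
  (`mrna_len_max + gap`), each holding one mRNA with uniform length in
  `mrna_len_range`. A planted NAT is placed on the opposite strand of
  its partner with the requested topology constructed directly
  (extension beyond the left edge, beyond the right edge, or strict
  containment), always clearing the `min_overlap` gate. lincRNAs are
  placed in inter-slot gaps, guaranteed not to touch any mRNA on either
  strand. Unplanted NATs overlap otherwise-unused mRNAs with random
  topology.
- **Counts.** Per-feature NB draws with log-uniform baseline means,
  dispersions uniform in `dispersion_range`, and per-sample library
  factors log-uniform in `library_size_range`. A `de_fraction` of
  features receives a ±`planted_lfc_magnitude` log2 shift in one
  non-reference group. lncRNA means are scaled by `lnc_mean_scale`,
  emulating the globally lower abundance of non-coding transcripts.
- **Pairs.** Each requested pair shares a latent log2-scale Normal
  deviate added to both members' means. Signed `rho` encodes the class:
  concordant pairs need `rho > 0` (the latent is added to both),
  discordant `rho < 0` (added to one, subtracted from the other);
  configurations violating this are rejected at `sim_config()` time.
  The latent variance is calibrated so that the *total* shared
  variation — latent plus the shared between-group DE shift, which
  contributes `magnitude^2 / 4` on the log2 scale — matches the
  requested correlation against the NB measurement noise:
  `sigma^2 = max(0, |rho|/(1-|rho|) * v_noise - magnitude^2/4)`.
  Planted pair members are drawn well-expressed (log-normal around
  1000 counts) with low dispersion (0.005-0.02): validated sense-
  antisense pairs are robustly expressed transcripts, and a requested
  `r^2 >= 0.6` is mathematically unattainable when NB noise exceeds the
  shared signal.
- **Ct tables.** `Ct = (ct_baseline - log2 mu) - lfc + N(0, ct_sigma)`,
  so expression differences appear as Ct differences under perfect
  efficiency. Reference genes with planted effects are rejected.

## What it does not emulate

Gene structure (exons, UTRs, isoforms), sequencing artifacts (GC and
length bias, multimapping, batch effects), dispersion-mean trends,
between-replicate correlation, more than one chromosome, partial
amplification efficiency in qPCR, and biologically structured GO
annotation. The generator's purpose is controlled ground truth for the
statistical pipeline, not realistic read-level simulation.

## Parameters and defaults

| Parameter | Default | Rationale |
|---|---|---|
| `n_mrna`, `n_linc`, `n_nat` | 10774, 1510, 3279 | full-scale transcriptome-like catalog; tests and examples use smaller sizes, chosen by this package for runtime |
| `n_groups`, `reps_per_group` | 3, 4 | three-condition, four-replicate design the pipeline targets |
| `lnc_mean_scale` | 0.25 | lncRNAs globally lower-expressed than mRNAs; 1 makes biotypes exchangeable (tested) |
| `dispersion_range` | 0.05–0.3 | typical RNA-seq biological dispersions |
| `de_fraction` | 0.1 | minority of DE features, preserving size-factor validity |
| `planted_lfc_magnitude` | 2 | four-fold planted effects, comfortably above the two-fold call gate |
| `library_size_range` | 0.5–2 | four-fold depth spread, log-uniform |
| `mrna_len_range` | 500–3000 bp | typical transcript lengths |
| `nat_ext_range` | 100–1000 bp | NAT extension beyond the shared overlap |
| `gap` | 6000 bp | inter-slot spacing; leaves room for intergenic lincRNAs |
| `min_overlap` | 50 bp | the pair-calling overlap gate |
| `ct_sigma` | 0.2 | realistic replicate-to-replicate Ct noise |
| `ct_baseline` | 35 | Ct of a single-copy-scale template |
| `seed` | mandatory | no silent irreproducibility |

Analysis-side defaults: `cpm_threshold = 1` (strict >), `pseudocount =
0.5`, `alpha_min = 1e-8`, `pair_thresholds(50, 0.6, 1)`, DE `alpha =
0.05`, clustering `method = "complete"` on Euclidean distances.

# Numerical choices

- Strict inequalities at every gate (`> 1` CPM, `padj < 0.05`,
  `r^2 >= 0.6` stated as an inclusive lower bound, `>= 50` bp) are fixed
  and tested at their boundaries.
- 1-based inclusive interval arithmetic throughout, matching GTF.
- Size factors and planted library factors are compared on the ratio
  scale (each normalized to geometric mean 1) because the estimator only
  identifies ratios.
- Constant expression vectors yield `NA` correlations rather than
  errors in `pair_correlation()`; downstream gating treats `NA` as not
  passing.
- `ks.test` and `wilcox.test` are used with their asymptotic versions
  (`exact = FALSE`) since expression data are tied and moderately sized.

# Validation strategy

The test suite is oracle-first: independent brute-force implementations
(literal BH step-up, terminus-membership topology classifier, O(n^3)
complete-linkage agglomeration, bitmask Venn enumeration) are frozen in
test helpers and the package is checked against them, exhaustively where
feasible (all antisense interval pairs with coordinates in [1, 30]).
End-to-end properties — size-factor recovery, null error control, power,
planted-pair precision/recall/class accuracy, clustering agreement,
ΔΔCt exactness — are verified on generator output across many seeds.
Problem sizes in tests and in `scripts/acceptance.R` (hundreds to a few
thousand features, 8–12 samples, tens of planted pairs) are this
package's own choices balancing statistical resolution against runtime.

# Limitations

- The Wald test has no dispersion shrinkage and no outlier handling;
  for real data with few replicates a dedicated DE package will be more
  powerful. The value here is a transparent, fully specified test with
  verified error control.
- `log2(x + 1)` is not variance-stabilized at low counts; clustering on
  very sparse data may be driven by the low-count regime.
- Pair calling is purely observational (overlap + DE + correlation); it
  cannot distinguish co-regulation from causal antisense regulation.
- The generator plants pairs as well-expressed, low-dispersion features;
  recovery statistics quantify pipeline correctness under detectable
  signal, not sensitivity to weakly expressed pairs.
- KS enrichment assumes scores are comparable across genes and ignores
  the GO graph structure (no parent-term propagation).
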