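# lncpair

Detection and classification of antisense lncRNA–mRNA pairs from RNA-seq
count data, with a built-in synthetic data generator for end-to-end
validation.

Long non-coding RNAs transcribed antisense to protein-coding genes
(natural antisense transcripts, NATs) can regulate their sense partner in
*cis*. Given a genome annotation and a count matrix across several
conditions (the motivating design is three diatom morphotypes — fusiform,
triradiate, oval — with four replicates each), `lncpair`:

1. reads/writes the standard interchange formats (GTF-like annotation,
   TSV count matrices, design tables, GO maps, qPCR Ct tables);
2. filters and normalizes counts (CPM filter, median-of-ratios size
   factors, `log2(x + 1)` transform);
3. tests for differential expression with a simplified negative-binomial
   Wald test and Benjamini–Hochberg FDR control;
4. finds antisense lncRNA–mRNA overlaps, classifies their **topology**
   (head-to-head, tail-to-tail, fully overlapped) and their **regulatory
   class** (concordant, discordant, or non-correlated);
5. builds condition signatures (DE-union hierarchical clustering,
   lncRNA-vs-mRNA expression-level comparison);
6. cross-validates fold changes against qPCR via the ΔΔCt method;
7. scores GO term enrichment with a Kolmogorov–Smirnov score test.

A seed-deterministic simulator (`sim_config()` / `simulate_dataset()`)
generates annotation, NB counts with planted library-size factors,
differential expression, correlated antisense pairs of requested topology
and class, and matching Ct tables — so every analysis step is validated
against known ground truth.

## Core model

**Normalization.** Size factors are median-of-ratios: with geometric-mean
reference `r_i = (∏_j k_ij)^(1/n)` over features positive in all samples,
`s_j = median_i(k_ij / r_i)`. Normalized counts are `k_ij / s_j`.

**Differential expression.** For groups A and B with pseudocount
`c = 0.5` and moment dispersion `α_i = max((v_i − m_i)/m_i², 10⁻⁸)`
(pooled within-group variance `v_i`):

```
log2FC_i = log2((μ_iB + c) / (μ_iA + c))
Var_i    = (1/ln 2)² [ (1/n_A)(1/(μ_iA + c) + α_i) + (1/n_B)(1/(μ_iB + c) + α_i) ]
z_i      = log2FC_i / √Var_i ,  p_i = 2·P(t_{n_A+n_B−2} ≤ −|z_i|)
```

with BH adjustment across features. The t reference (rather than normal)
is a small-sample calibration; see the vignette.

**Pair calling.** A NAT–mRNA candidate requires an antisense overlap of
at least 50 bp (1-based inclusive: `min(ends) − max(starts) + 1`).
Topology: if either transcript contains the other, *fully_overlapped*;
otherwise *head_to_head* when both 5′ termini fall inside the overlap,
*tail_to_tail* when both 3′ termini do (for antisense, non-contained
overlaps exactly one of the two holds). A pair is reported when both
members are DE (padj < 0.05) with |log2FC| ≥ 1; it is *concordant* /
*discordant* when the fold changes agree / oppose in sign and the squared
Pearson correlation of the members' `log2(normalized + 1)` profiles is
r² ≥ 0.6, and *NC* (non-correlated) when r² < 0.6.

**qPCR.** Per replicate, ΔCt = Ct(target) − mean Ct(references); ΔΔCt is
the difference of condition means versus the control condition;
`log2FC = −ΔΔCt`, fold = `2^−ΔΔCt` (amplification efficiency 2).

## Worked example

```r
library(lncpair)

# 1. Simulate a three-morphotype experiment with planted antisense pairs
spec <- data.frame(
  topology = c("head_to_head", "tail_to_tail", "fully_overlapped"),
  class    = c("concordant",   "concordant",   "discordant"),
  rho      = c(0.95,           0.95,           -0.95),
  n        = c(8,              8,              6))
cfg <- sim_config(n_mrna = 150, n_linc = 30, n_nat = 60,
                  seed = 42, pair_spec = spec)
dat <- simulate_dataset(cfg)
dim(dat$counts)
#> [1] 240  12

# 2. Filter, normalize, transform
filt <- filter_low_expression(dat$counts)
s    <- size_factors(filt)
round(s, 3)
#>   F_1   F_2   F_3   F_4   T_1   T_2   T_3   T_4   O_1   O_2   O_3   O_4
#> 0.689 1.462 1.288 1.162 0.730 0.613 1.097 1.635 1.026 0.967 1.177 0.833
lg <- transform_log(normalize_counts(filt, s))

# 3. Differential expression, fusiform (F) vs triradiate (T)
disp <- estimate_dispersion(filt, dat$design, s)
de   <- call_de(wald_test(filt, dat$design, s, disp, "F", "T"))
summarize_de(de)
#>   comparison n_called n_up n_down pct_up pct_down
#> 1       TvsF       65   35     30     54       46

# 4. Antisense pair discovery
cand <- classify_candidates(
  find_overlaps(features_by_biotype(dat$annotation, "NAT"),
                features_by_biotype(dat$annotation, "mRNA")),
  dat$annotation)
cand <- cand[cand$nat_id %in% rownames(lg) &
             cand$mrna_id %in% rownames(lg), ]
pairs <- call_pairs(cand, de, lg,
                    dat$design$sample_id[dat$design$group %in% c("F", "T")])
summarize_pairs(pairs)$class_by_topology
#>             tp
#> cl           head_to_head tail_to_tail fully_overlapped
#>   concordant            8            8                0
#>   discordant            0            0                6
#>   NC                    0            0                0
head(pairs[pairs$pair_class != "NC",
           c("nat_id", "mrna_id", "topology", "r2", "pair_class")], 5)
#>     nat_id   mrna_id     topology        r2 pair_class
#> 1 NAT00001 MRNA00001 head_to_head 0.9362544 concordant
#> 2 NAT00002 MRNA00002 head_to_head 0.9695430 concordant
#> 3 NAT00003 MRNA00003 head_to_head 0.9232504 concordant
#> 4 NAT00004 MRNA00004 head_to_head 0.9609702 concordant
#> 5 NAT00005 MRNA00005 head_to_head 0.9533284 concordant

# 5. Morphotype signature: cluster samples on the union of DE features
de_fo <- call_de(wald_test(filt, dat$design, s, disp, "F", "O"))
de_to <- call_de(wald_test(filt, dat$design, s, disp, "T", "O"))
sig   <- de_union(list(de, de_fo, de_to))
length(sig)
#> [1] 80
hc <- hier_cluster(lg[sig, , drop = FALSE], axis = "samples")
cluster_agreement(cut_tree(hc, 3), dat$design)   # adjusted Rand index
#> [1] 1
```

All 22 planted pairs are recovered with the correct topology and class,
and the 12 samples cluster perfectly by morphotype (ARI = 1).

## Documentation

The methods vignette (`vignettes/methods.Rmd`) documents the statistical
model, every tunable parameter and its default, what the synthetic
generator does and does not emulate, and the package's numerical and
design choices.
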