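---
title: "Integrated hypothesis testing for bulk RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated hypothesis testing for bulk RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihtseq)
```

## The analysis model

`ihtseq` implements a differential-expression workflow for multi-group bulk
RNA-seq experiments with a single vehicle control and several treatments —
the canonical use case being a small balanced design (e.g. 8 groups of 4
replicates, 32 samples) profiled at the gene level. The pipeline starts from
a gene-by-sample count matrix (integer or fractional estimated counts) and
proceeds:

1. **Expression filter.** A gene is kept only if its count is *strictly*
   greater than 10 in *every* sample. This is deliberately stringent: with
   32 samples it restricts the analysis universe to robustly expressed
   genes, which also defines the background for enrichment testing.
2. **TMM normalization.** Between-sample scale factors are computed by the
   trimmed mean of M-values: for each sample against a reference column,
   per-gene log2 ratios of library-size-scaled counts (M) and average log2
   abundances (A) are formed over genes positive in both columns; the
   extreme 30% of M and 5% of A are trimmed on each side, and the factor is
   2 to the inverse-delta-method-variance weighted mean of the surviving M
   values, with all factors rescaled to geometric mean 1. The reference is
   the sample whose 75th percentile of library-size-scaled counts is closest
   to the mean of those percentiles — the standard convention when none is
   specified.
3. **log2-CPM.** Expression is `log2(count / (library size x TMM factor) x
   1e6 + 1)`. The pseudocount of 1 keeps zero counts at exactly 0 and every
   value finite; it is configurable. We transform counts-per-million rather
   than normalized counts so that values are comparable across libraries of
   different depth; the choice is exposed through the effective-size
   argument of `log_cpm()`.
4. **Integrated hypothesis testing.** Per gene, two tests of the
   treatment-vs-control contrast on log2 expression:
   - a two-sided Student *t*-test with pooled variance (Welch's form by
     flag). "t-test" alone is ambiguous; the pooled form is the textbook
     default for small balanced groups.
   - a **median-difference test**: the statistic is
     `median(treatment) - median(control)`; its null is built by
     re-splitting the pooled 8 samples into pseudo-groups of 4 in all
     C(8,4) = 70 ways (random splits when enumeration would exceed 10,000)
     and collecting `|median difference|` for every gene and split into one
     **gene-pooled empirical null**. Pooling is essential: a per-gene 4-vs-4
     null has only 70 atoms, far too coarse to resolve the small p-values
     FDR control needs. A per-gene mode is retained by flag. The p-value
     uses add-one smoothing, `p = (1 + #{null >= |obs|}) / (1 + N)`, so it
     is never 0 and ties count conservatively as exceedances.
   - **Stouffer combination.** Each two-sided p maps to a signed z,
     `qnorm(1 - p/2) x sign(effect)` (the log2FC sign for the t component,
     the median-difference sign for the other), and
     `z = (z_t + z_m) / sqrt(2)`. Signing makes discordant directions
     cancel instead of reinforcing, which combining unsigned two-sided
     p-values would wrongly do. Weights are equal.
   - **BH-FDR** over the combined p-values, then a DEG call at
     `q <= 0.05` **and** `|log2FC| >= 0.58` (both inclusive; 0.58 is
     log2 of 1.5-fold). log2FC is the difference of group means of log2
     expression, inheriting the pseudocount.
5. **Enrichment.** One-sided Fisher's exact (hypergeometric upper-tail)
   over-representation of a query (by default the up-regulated DEGs of a
   comparison) against GMT gene sets intersected with the filtered-gene
   universe, BH-adjusted across tested sets, significant at `q < 0.05`
   (strict). For radar charts, `-log10(q)` per pathway and comparison is
   clipped into a caller-chosen `[cap_min, cap_max]` range; the maximum cap
   is mandatory configuration because a sensible display range depends on
   the data.

A small auxiliary, `ddct_fold()`, implements classic delta-delta-Ct qPCR
quantification with efficiency fixed at 2, technical replicates averaged on
the Ct scale, and the calibrator-group *mean* dCt as the anchor (so the
calibrator folds have geometric mean exactly 1).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `filter.threshold` | 10 counts | strict per-sample minimum |
| `tmm.trim_m`, `tmm.trim_a` | 0.30, 0.05 | two-sided trim fractions on M and A |
| `logcpm.pseudocount` | 1 CPM | offset before log2 |
| `fdr_cut` | 0.05 | inclusive FDR gate for DEGs |
| `lfc_cut` | 0.58 | inclusive \|log2FC\| gate (1.5-fold) |
| `n_perm` | 10,000 | random splits when enumeration is infeasible |
| `pooled_null` | TRUE | gene-pooled permutation null |
| `enrich fdr` | 0.05 | strict significance cut for sets |

## What the simulator emulates — and what it does not

`simulate_counts()` draws `count ~ NB(mean = baseline x 2^lfc x size factor,
dispersion phi)` with variance `mu + phi mu^2` (the parameterization is
stated to avoid the size/rate ambiguity). Defaults describe the target
study shape: 8 groups x 4 replicates, ~12,000 expressed genes, log-normal
baselines (meanlog log 250, sdlog 1), constant dispersion 0.1 (biological
CV ~0.32, typical for cell-line bulk RNA-seq), log-normal library scale
factors (sdlog 0.15, geometric mean 1), 10% of genes differentially
expressed per treatment with |log2FC| at least 0.58 (random sign, floor
plus an Exponential(2) excess), DE sets drawn independently per treatment
so they overlap like shared response programs. Ground truth (flags, true
log2FC, size factors, dispersions) is returned for recovery testing.

It does **not** model batch effects, outlier samples, gene-gene
correlation, length/GC bias, or read-level noise. Passing tests therefore
demonstrate correctness of the statistical machinery under the assumed
generative model, not robustness to the full messiness of real libraries.

## Statistical behaviour worth knowing

The two component tests are computed on the same data and are strongly
correlated (measured `cor(z_t, z_m)` around 0.88 under a DE-free
simulation). The equal-weight Stouffer combination divides by `sqrt(2)` as
if they were independent, so the combined p-value is **anti-conservative**:
under a pure null its distribution piles up near 0 and 1 (Kolmogorov-
Smirnov distance from uniform around 0.17 at 5,000 genes) even though each
component p is accurately uniform (KS around 0.01). Consequently the
realized false-discovery proportion among called DEGs can exceed the
nominal 5% when true effects are present, and borderline calls should be
read with that in mind. Two features keep the practical false-positive
yield low on null data: BH acts on the whole gene set, and the
|log2FC| >= 0.58 gate removes small-effect flukes — in 20 DE-free
simulations at 2,000 genes the called fraction stays well under 1%. Users
wanting calibrated combined p-values can permute the combined statistic
instead; that is outside the present scope.

Other numerical choices: degenerate zero-variance genes get t = 0, p = 1
when means agree and the smallest representable p when they differ;
permutation p-values are add-one smoothed so `qnorm` never receives 0 or
1; combined p-values are clipped into the machine-representable (0, 1];
BH is the standard step-up (`p.adjust`); fewer than 10 genes surviving the
TMM trim triggers a warning and an untrimmed weighted mean; all writers
serialize doubles at 17 significant digits so round-trips are exact and
re-runs byte-identical.

## Design choices on genuinely open points

- **Pooled vs per-gene permutation null**: pooled by default (see above);
  per-gene retained by `pooled_null = FALSE`.
- **Student vs Welch**: Student by default, Welch by flag.
- **CPM vs normalized counts** before log2: CPM, configurable via the
  effective sizes passed to `log_cpm()`.
- **log2FC on log-space group means** (not on the count scale), matching
  the scale on which both tests operate.
- **Enrichment correction**: BH over the supplied GMT collection — fully
  self-contained, no annotation service, no network.
- **Enrichment query direction**: up-regulated DEGs by default (down- and
  all-DEG queries by flag), reflecting the common situation where the
  down-regulated set is too small to enrich.
- **Radar caps**: `cap_min = 0` by default; `cap_max` must be supplied.
- **ddCt anchor**: the calibrator-group mean dCt rather than a single
  designated sample.

## Problem sizes used by the test suite

The shipped tests validate: oracle equality of BH against a quadratic
brute-force step-up (100 vectors, m <= 200); exhaustive 70-split
enumeration on 4-vs-4 toys; hypergeometric tails against direct
enumeration at N <= 50 (to 1e-12); TMM against the independent edgeR
implementation (to 1e-6, 200 x 6 matrices); null false-positive control
over 20 seeded DE-free replicates at 2,000 genes x 32 samples; and
power/bias recovery of 10% spikes at |log2FC| = 2 (recall >= 80%,
orientation-corrected bias < 0.1). These sizes were chosen as the smallest
at which the Monte-Carlo error bands in the assertions are meaningful.

## Known limitations

- No moderated (empirical-Bayes) variance: with n = 4 per group the
  per-gene t-test is noisier than limma/DESeq2-style shrinkage estimators.
- No covariates, batch terms, or multi-factor designs.
- The combined p-value is anti-conservative under dependence, as discussed.
- The pseudocount mildly attenuates log2FC for weakly expressed genes
  (negligible above ~50 CPM).
- Gene identifiers are opaque strings; no symbol/Ensembl mapping.
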