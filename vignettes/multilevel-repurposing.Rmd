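---
title: "Multilevel expression changes and signature-reversal repurposing: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel expression changes and signature-reversal repurposing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigreverse)
```

This vignette is the package's account of its statistical machinery: the
models each stage assumes, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

## The pipeline at a glance

Starting from an integer gene-by-sample read-count matrix with a binary
group label (reference "normal" versus contrast "cancer"), the stages
are:

1. **Sample QC** — PCA screen before differential expression; dendrogram
   screen per group before network construction.
2. **Differential expression** — negative-binomial Wald tests with
   median-of-ratios normalisation; two threshold tiers.
3. **Coexpression modules** — soft-thresholded correlation network,
   topological overlap, average-linkage clustering, eigengene merging;
   run independently per group and cross-tabulated.
4. **Differential correlation** — Fisher-z tests for between-group change
   of pairwise correlations on a selected gene subset; per-group edge
   lists.
5. **Enrichment** — hypergeometric over-representation of gene lists
   against a GMT collection.
6. **Drug reversal** — direction-reversed Fisher exact matching of a drug
   signature library against the disease signature, with a coverage
   filter.

Every stage is a plain function over plain containers (a `count_matrix`,
matrices, data frames), so stages can be run, inspected and re-run
independently; `run_pipeline()` chains them and records a manifest.

## Differential expression

Counts are modelled as `K_gj ~ NB(mean = s_j * mu_gj, dispersion =
alpha_g)`. The pieces:

* **Size factors** (`size_factors()`): the median-of-ratios estimator.
  For sample `j`, `s_j = exp(median_g(log(K_gj) - log(geomean_g)))` over
  genes whose geometric mean across samples is positive. The median is
  taken on the log scale; this matters only when the two middle ratios
  are averaged, and matches the convention of the standard NB DE tools.
  Factors are deliberately not renormalised — only their ratios matter to
  the GLM, which absorbs any common scale into the intercept.
* **Dispersion** (`estimate_dispersions()`, internal): per gene a
  method-of-moments estimate on normalised counts,
  `alpha_hat = max((v - xim * m) / m^2, 0)` with `m` the mean of
  normalised counts, `v` the pooled within-group variance and
  `xim = mean(1/s_j)`; then a least-squares trend `alpha(mu) = a0 +
  a1/mu` fitted over well-estimated genes (`m > 1`, `alpha_hat` in
  `(1e-6, 10)`), and a final per-gene value at the midpoint of the
  gene-wise and trend estimates, floored at `1e-8`. The midpoint is a
  deliberately simple shrinkage: with the generator's trend-true
  dispersions it is nearly unbiased, and the package's calibration tests
  (type-I error in `[0.03, 0.07]` at `n = 20 + 20`) are the check that it
  is adequate.
* **Testing** (`de_test()`): per gene, a log-link NB GLM with design
  `~ group` and offset `log(s_j)`, fitted by IRLS with the dispersion
  held fixed; the Wald `z` on the group coefficient gives a two-sided
  normal p-value, BH-adjusted over all tested genes. Genes that are zero
  in every sample are removed first; non-convergent fits are reported
  with missing statistics and excluded from the BH count. Positive
  `log2FoldChange` means higher in the contrast group.
* **Tiers** (`apply_thresholds()`): loose = `padj < 0.05`, split by
  fold-change sign; strict additionally requires `padj <= 0.001`,
  `baseMean >= 100` and `|log2FC| >= 1`. The strict tier is nested in
  the loose tier by construction. The disease signature used for drug
  matching defaults to the loose tier (the tier a practitioner would
  feed a reversal screen, keeping the signature large); the strict tier
  is selectable via `pipeline_config(disease_tier = "strict")`.

What is intentionally *not* implemented: outlier-count refitting (Cook's
distance), independent filtering, and fold-change shrinkage. Those are
robustness refinements of the reference implementations; the package's
scope is the core estimator, and its tests measure parameter recovery on
NB data rather than bit-agreement with any particular tool.

## Sample QC

Two screens, used at the two places they matter:

* **PCA screen** (`pca_outliers()`), before DE. Samples are projected on
  the first `n_pcs` principal components of log2-normalised expression
  (`log2(K/s + 1)`); each component is centred at its median and scaled
  by its MAD; a sample is removed iff its Euclidean distance in this
  standardised space exceeds `median(d) + mad_k * MAD(d)`. Two defaults
  deserve comment. First, `n_pcs = min(10, n - 1)` rather than 2: in
  data with real group and module structure the top two components carry
  that structure, and an aberrant sample typically *owns* a minor
  component instead — a plain top-2 distance misses it (on generator
  defaults, in roughly half of seeds). Second, the per-component MAD
  standardisation makes the rule scale-free; on this standardised scale
  the null spread of distances is narrow, and `mad_k = 8` sits far
  outside it while remaining an order of magnitude below a genuinely
  aberrant profile's distance (measured over 30 generator seeds: 29
  exact recoveries, no false flags).
* **Dendrogram screen** (`dendrogram_outliers()`), per group before
  network construction: average-linkage clustering on Euclidean
  distances of log2-normalised profiles, a cut at `cut_height`, and
  removal of everything outside the largest cluster — the standard
  recipe for trimming stray samples before coexpression analysis. The
  largest-cluster rule (rather than removing singletons) means two
  identical aberrant samples are still removed together. Absolute cut
  heights do not transfer across datasets, so when no height is given
  the 99th percentile of the tree's merge heights is used; for
  publication-grade use the height should be chosen by inspecting the
  dendrogram.

## Coexpression modules

The network is unsigned by default, `a_ij = |r_ij|^beta`, with
`beta = 6`; a signed variant `((1 + r)/2)^beta` is available.
`pick_soft_threshold()` reports, per candidate power, the mean
connectivity and the scale-free topology fit (r² of `log10 p(k)` versus
`log10 k` over connectivity bins) — it is a diagnostic table, not an
automatic selector; the pipeline keeps the fixed working power.

Topological overlap (`tom_similarity()`) follows the standard unsigned
definition, and `1 - TOM` feeds average-linkage clustering. Module
detection then needs a tree cut, and here the design was genuinely open:

* The hybrid dynamic tree-cut algorithm used by the reference WGCNA
  workflow is a separate method with many shape-based heuristics; this
  package deliberately uses a fully specified *static* cut.
* A static cut at a fixed extreme quantile of merge heights fails
  structurally: with average linkage on `1 - TOM`, the merges that join
  distinct modules to each other sit *below* the highest merges of the
  diffuse background gene cloud, so any cut high enough to keep the top
  percentile intact leaves all modules fused in one cluster.
* The default is therefore the midpoint of the **largest gap** between
  consecutive merge heights in the upper half of the tree. Tight
  within-module merges and loose background merges are separated by a
  pronounced height gap whenever module structure exists at all; cutting
  inside that gap isolates each module while the background shatters
  into fragments below the minimum module size (which become `grey`).
  When no structure exists the gap is tiny and the cut lands among
  noise merges, leaving essentially everything `grey` — the correct
  degenerate behaviour. A numeric `tree_cut_quantile` restores a plain
  quantile cut for users who want to reproduce that convention.

Clusters under `min_module_size = 30` genes become `grey`. Module
eigengenes are the first principal component of the module's
row-standardised expression, unit-norm and sign-aligned so they correlate
non-negatively with mean module expression; modules whose eigengenes
correlate above 0.75 are merged iteratively (highest-correlation pair
first), and final labels `M1, M2, ...` are assigned in decreasing size
order, which makes the partition invariant to gene order. Under these
defaults the package recovers five planted 100-gene modules at
within-module `r = 0.6` from 50 samples with adjusted Rand index ≥ 0.98
in ten seeds out of ten, and leaves independent genes entirely grey.

`module_overlap_table()` cross-tabulates two group-specific assignments
over their common genes and attaches a hypergeometric overlap p-value per
module pair — the quantitative version of asking which normal-tissue
modules persist, dissolve, or fragment in the cancer network.

## Differential correlation

`diffcorr()` computes, for every pair in a gene subset: Pearson `r` per
group, a within-group two-sided t-test of `rho = 0`
(`t = r * sqrt((n-2)/(1-r^2))`), and the between-group Fisher-z
difference `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`
against a standard normal. The two tests intentionally differ: the
within-group t-test governs whether an edge exists in a group's network
(`|r| > 0.3` *and* `p < 0.05`, both strict, per `export_group_networks()`),
while the Fisher-z statistic measures whether the correlation *changed*
between groups. No multiple-testing correction is applied to the
difference p-values by default — the edge filter is a per-pair screen,
not an inference procedure — but `adjust = TRUE` appends BH-adjusted
values. The pipeline applies `diffcorr()` to a selected subset (by
default the largest normal-group module, capped at 200 genes) because the
all-pairs computation is quadratic; a full-transcriptome run is allowed
and warns.

Numerical details: correlations of exactly ±1 are clamped by `1e-12`
before `atanh`; genes constant within a group yield missing statistics
for their pairs rather than errors; group sizes must exceed 3 for the
variance of the z-difference to exist.

## Enrichment

`ora()` is a one-sided hypergeometric upper-tail test per gene set,
identical to the one-sided Fisher exact test on the same 2×2 table (a
cross-consistency the test suite asserts against the drug-reversal
module and against an exact enumeration oracle). The default universe is
the set of genes that survived the all-zero filter — the background that
was actually tested. Significance is flagged at raw `p < 0.001` with
BH-adjusted values reported alongside, since collection-level error
control is a judgement the analyst should make explicitly.
`ora_modules()` batches the test over every non-grey module of an
assignment.

## Drug reversal

A drug counts only its *reversed* overlaps: disease-up genes in the
drug's down set and disease-down genes in the drug's up set. Concordant
overlaps are ignored entirely — a candidate must push the disease state
back, and a drug that moves disease genes further in the disease
direction earns nothing from them. The two directions are pooled into a
single test per drug (one p-value, one coverage; per-direction counts are
still reported), on the 2×2 table of total reversed overlap against the
combined disease and drug signature sizes within the analysis universe.

`coverage = o_total / drug_sig_size` uses the drug signature restricted
to the analysis universe as denominator, so a drug is never penalised for
perturbing genes the experiment could not measure
(`restrict_coverage = FALSE` restores the unrestricted denominator).
Passing requires `fisher_p < 1e-5` and `coverage > 0.95`, both strict
inequalities; ranking is by coverage descending, ties broken by smaller
p, then lexicographic drug id, so the ordering is total and
deterministic. Drugs whose signatures are empty after universe
restriction are scored with missing coverage, warned about, and excluded
from the passing set.

## The synthetic-data generator

`simulate_counts()` plants, under a single seed, every structure the
stages are supposed to find, so the pipeline's tests are
parameter-recovery experiments with known truth:

* **Counts** are negative binomial (gamma-Poisson) with per-gene
  dispersion following the trend `alpha(mu) = a0 + a1/mu`
  (defaults `a0 = 0.01`, `a1 = 1.5`) around log-normal base means
  (log2 means drawn `N(5, 2)`), scaled by per-sample library-size
  factors drawn log-uniformly from a 4-fold range.
* **DE genes**: a `de_fraction` of genes (default 10% of 2,000 — 100 up
  and 100 down) get a group effect of ±2 on the log2 scale.
* **Modules** enter as one latent factor per module on the log2-mean
  scale. The loading solves `r = lambda^2 / (lambda^2 + sigma^2)` where
  `sigma^2 = (1/mu + alpha)/ln(2)^2` is the NB-induced log2-scale noise
  variance, so the realised within-module Pearson correlation of
  normalised log2 expression lands on the target (±0.1 at 50 samples per
  group). Because this calibration is a continuous approximation, module
  genes' base means are floored at 50 counts — at very low counts the
  discreteness of `log2(K + 1)` breaks it. Disrupted modules have their
  loading zeroed in the cancer group only, so the coexpression exists in
  normal samples and dissolves in cancer, which is what the module
  cross-tab and the differential-correlation stage are built to detect.
* **Outliers** get a per-gene log2 shift drawn `N(2, 1)` plus a doubled
  library size. The per-gene draw matters: a *uniform* shift of every
  gene is exactly a library-size change, which median-of-ratios
  normalisation removes without trace — an "outlier" defined that way
  would be invisible to any screen operating on normalised data. The
  gene-specific component survives normalisation and is what both QC
  screens detect.
* **The drug library** (`simulate_drug_library()`) draws random
  disjoint up/down sets from the gene universe and, when requested,
  appends one drug whose up set is the planted down-regulated disease
  genes and vice versa — the exact sign flip of the disease signature.

What the generator does **not** emulate: batch effects, disease
subtypes, gene-length or GC biases, realistic gene identifiers, count
sparsity beyond what NB sampling produces, overlap between DE genes and
module genes (the planted blocks are disjoint, so each structure can be
scored cleanly), or correlated drug signatures. Consequently, passing
tests demonstrate that each stage recovers the structure it models from
data satisfying its assumptions — they do not demonstrate robustness to
the confounders real cohort data carry, which is exactly the caveat any
user should keep for real applications.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in a few minutes: 2,000-gene universes with 50 + 50
(pipeline) or 20 + 20 (calibration) samples, 1,000-gene module-recovery
runs at 50 samples, ~11,000 gene pairs for correlation calibration, and a
201-drug library. Exact-test agreement is checked exhaustively on all
2×2 tables with universe up to 60 and on 1,000 random larger tables.

All randomness flows through explicit integer seeds
(`simulation_config(seed = )`; the drug-library draw uses `seed + 1` so
counts and library are independently reproducible). The analysis stages
themselves contain no randomness: clustering, merging and ranking all
have deterministic tie-breaks, and `run_pipeline()`'s manifest contains
no timestamps, so identical inputs give byte-identical outputs.

## Known limitations

* The Wald test with moment-based, midpoint-shrunk dispersions is
  slightly liberal at very small sample sizes; the calibration tests
  bound this at `n = 20 + 20` but two or three samples per group should
  not be trusted.
* The static gap cut assumes modules are tighter than the background by
  a clear margin; weak, overlapping or nested modules will not split the
  way the hybrid dynamic algorithm might split them.
* Exact string matching of gene identifiers is a contract, not a
  convenience: no symbol/alias mapping is attempted, so disease and drug
  signatures must already live in one identifier space.
* The reversal test treats gene sets as unordered; rank-weighted
  connectivity scores are out of scope.
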