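---
title: "Methods: multi-region brain-aging expression analysis and IHC tile quantification"
author: "neuroAging package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-region brain-aging expression analysis and IHC tile quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroAging)
```

# Overview

`neuroAging` implements the two analysis arms of a multi-region study of the
aging human brain:

1. **Expression arm.** Post-mortem cohorts sample up to ten brain regions per
   individual (frontal, temporal and occipital cortex, white matter,
   cerebellum, substantia nigra, putamen, thalamus, hippocampus, medulla).
   Samples are assigned to three age groups — young 16–44, middle 45–74, old
   ≥ 75 years — and per-region differential expression across the groups is
   combined with a regional-breadth taxonomy, cell-type specificity scoring,
   sample classification, and a stepwise age-associative regression.
2. **Imaging arm.** High-resolution immunohistochemistry sections
   (brown chromogen marking a cell population of interest, blue hematoxylin
   counterstain marking all nuclei) are processed as fixed-size tiles:
   entropy-based quality control, channel-based segmentation, cell-size
   binning, density-class tile selection, and shuffled-label permutation
   statistics on per-tile counts.

Because the original cohorts and slide scans are restricted or impractically
large, a first-class synthetic-data module generates expression cohorts,
cell-type reference profiles, and stained tiles with known ground truth.
Every statistical guarantee this package advertises is stated — and tested —
with respect to those generated conditions.

# The synthetic cohort generator

`generateExpressionStudy()` emulates the structure of a multi-region brain
expression cohort:

* One column per (individual, region) pair; samples are dropped completely at
  random at `missing_region_rate` (default 0.08), mirroring cohorts in which
  not every individual contributes every region. Every individual keeps at
  least one sample and every region at least two.
* Ages are drawn **uniformly** over `age_range` (default 16–106 years), so the
  three age groups have unequal sizes, as in real brain banks. We deliberately
  do not model bank-specific age pyramids.
* Signals are log2-scale: a grand mean (default 8), block-wise per-region
  offsets (20 gene blocks, SD 0.3 by default) that give each region a
  transcriptional identity, and i.i.d. Gaussian noise (`noise_sd`, default
  0.5 log2 units — a typical residual SD for expression arrays after
  normalization).
* A planted aging effect shifts a gene's group means monotonically: young
  + 0, middle + Δ/2, old + Δ (signed by direction). The midpoint convention
  is the simplest monotone trend consistent with three ordered groups.

What the generator does **not** emulate: probe-level effects and
normalization artifacts, batch/bank structure, correlated gene modules,
age-dependent cell-composition drift, and non-Gaussian heavy tails. Passing
recovery tests on this generator therefore demonstrates the correctness and
calibration of the pipeline's inference machinery, not robustness to every
pathology of real microarray data.

`generateCellTypeReference()` builds linear-scale mean profiles for seven CNS
cell types (neurons, astrocytes, OPCs, newly formed and myelinating
oligodendrocytes, microglia, endothelial cells). Baseline means are lognormal
(median 50, log-SD 0.6, broadly matching the spread of real mean expression);
a planted marker's home-type mean is set to `marker_fold` (default 20) times
its maximum over the other types **before** multiplicative lognormal noise
(`noise_cv`, default 0.1), so with noise disabled the specificity score of a
marker equals `marker_fold` exactly as the pseudocount vanishes.

`generateTile()` renders disk-shaped cells — flat DAB-brown or
hematoxylin-blue fill plus Gaussian RGB noise (SD 3 by default) on a pale
background. Disks are placed by rejection sampling; when overlap is
disallowed, boundaries must clear each other by 2 pixels, because exactly
tangent disks rasterize into adjacent pixels and would merge under any
connected-component labeling. No histology texture or lighting gradients are
simulated: the tiles exercise thresholding, morphology, labeling and
counting, not color normalization.

# Differential expression and regional breadth

Within each region, each gene is tested by one-way fixed-effects ANOVA of
log2 signal on the three age groups (no covariates at this stage; sexes are
pooled). Age groups with fewer than two samples are dropped; genes with
fewer than two usable groups are flagged untestable and excluded from that
region's multiple-testing family. The per-gene F statistics are computed by
a vectorized rowwise ANOVA (cross-checked against `stats::oneway.test` in the
test suite) so that hundreds of null simulations stay cheap.

P-values are adjusted per region with Benjamini–Hochberg (`stats::p.adjust`);
"significant" means q < 1e-3, the stringent threshold used to isolate global
signals. BH is applied per region across genes; no cross-region joint
correction is attempted, since the breadth taxonomy itself aggregates across
regions.

Breadth of a gene = the number of regions in which it is significant:
region-specific (exactly 1), region-selective (2–7), multi-regional (8–9),
cross-regional (all 10). The taxonomy is defined for ten regions; other
totals require explicit rescaled thresholds, which the classifier refuses to
guess. Direction is the sign of the old-minus-young mean difference, with an
exact tie reported as "none" and never counted as up or down.

Enrichment of gene sets in breadth categories (and the generic
over-representation interface) is the one-sided hypergeometric tail,
verified against brute-force enumeration in the tests.

# Cell-type specificity

The specificity score of gene *g* in type *t* is

$$ s(g,t) = \frac{\mu_{g,t} + \varepsilon}{\max_{u \neq t}\ \mu_{g,u} + \varepsilon} $$

with linear-scale means and pseudocount ε = 1. Ratio-to-max is the strictest
of the common specificity definitions: a threshold above 1 makes per-type
marker lists automatically disjoint. The default marker threshold is 5,
chosen so that markers at typical enrichment folds (≥ 10–20) are recovered
while flat genes (score ≈ 1) are firmly excluded; both ε and the threshold
are exposed. Consensus lists (`consensusLists()`) intersect the
reference-derived lists with an independently supplied list per shared type.
Orthology mapping between species is out of scope: reference and study must
share a gene namespace.

# Classification and discrimination

Sample–sample similarity uses Spearman correlation on a stated gene subset
(invariant to monotone transforms of the signal). Hierarchical clustering
uses Euclidean distance with complete linkage (the usual default for
expression heatmaps; configurable). Two-dimensional embeddings use t-SNE
(perplexity 30, 1,000 iterations, seed 0 by default, all logged in the
result). Heatmap standardization is the per-row z-score with the n−1 SD
convention, clipped to ±3.

"Successful age-group discrimination" is operationalized as: cut the sample
dendrogram into three clusters, map clusters to age groups by the
best of the 3! assignments, and count an individual correct when the
majority of its samples fall in its own group's cluster. Under random
clusters this scores ≈ 1/3 after the best-of-six correction (verified by
simulation); it is invariant to cluster relabeling by construction.

# Stepwise age model

The age-associative model is forward–backward stepwise OLS of age in years
on candidate gene signals, with brain bank and cause of death forced in as
dummy-coded covariates (never removable). The stepwise criterion is the
partial-F p-value — entry 0.05, removal 0.10 by default, an AIC mode as an
alternative — with two safeguards: a term removed in one step may not
re-enter on the next (no add/remove cycles), and a hard cap on steps and on
selected terms (`max_terms`, default 10). Interactions are restricted to
pairwise products of already-selected genes, keeping the search space linear
in the candidate count. R² is non-decreasing along a forward pass and the
final R² never falls below the covariate-only R². Models per cell type are
ranked by R², ties broken by fewer selected terms. Whether to pool regions
or fit per region is left to the caller; the default pools all supplied
samples.

# IHC tile quantification

* **Entropy QC.** Shannon entropy (bits) of the 256-bin histogram of integer
  Rec.601 luma; range [0, 8]. Tiles at or below 5 bits are flagged for
  exclusion — blank glass and coverslip edges fall well under this; the bin
  count and channel convention are fixed and documented since several
  conventions circulate.
* **Segmentation.** Foreground by Otsu thresholding of the grayscale
  (fixed-threshold mode available), per-pixel stain class by channel
  comparison — chromogen where red exceeds blue by `stain_delta` (default
  20 intensity units), counterstain otherwise — morphological opening
  (disc radius 2 px), 8-connected component labeling (EBImage's 4-connected
  labeling plus an exact diagonal-merge pass), components below `min_area`
  discarded (50 px in the small-tile dialect, 500 px in the large-tile
  dialect), object class by majority pixel vote.
* **Size bins.** Areas ≥ 500 px partition into small [500, 3000), medium
  [3000, 6000), large [6000, 9000], very large (> 9000). The upper-inclusive
  large bin is forced by "very large" being defined as strictly above 9,000
  pixels.
* **Density classes.** Tiles are split by pooled terciles of total nucleus
  count (low/mid/high, proxying white vs gray matter); within each extreme
  class the k = 50 most extreme tiles per case are selected, deterministically
  (ties broken by tile id). A global top-k selection
  (`rankTilesByDensity()`) serves the highest-density workflow.

# Permutation statistics

Group comparisons on per-tile counts use the pooled-variance two-sample t
statistic, signed young-minus-old so a positive value means a higher count
in young samples. Null distributions come from shuffling tile labels:
`n_iterations` rounds (optionally subsampling tiles per round) of
`n_permutations` shuffles each, pooled; the observed statistic is the mean
true-label t over rounds. Scheme presets mirror the three workflows used in
practice (100 × 500 with subsampling; 10,000; 100,000 single-round
shuffles). P-values use the add-one convention
p = (1 + #{t_null ≥ t_obs}) / (1 + N), so p is never zero and the minimum
attainable is 1/(N+1); the two-sided p doubles the smaller tail (capped at
1). Tiles — not cases — are the permutation units, following the workflow
this mirrors; with six cases the case-level exchangeability caveat applies
and is the main inferential limitation of the imaging arm.

# Numerical and design notes

* Degenerate ANOVA cells: zero within-group variance yields F = 0, p = 1
  when group means agree, and an unbounded F with p below the machine floor
  when they separate.
* The vectorized permutation t handles zero pooled variance the same way
  (t = 0 on equal means, ±∞ otherwise).
* All generators are bit-reproducible given a seed, and seeded code paths
  never disturb the caller's RNG state.
* Ages below 16 are rejected everywhere: the age-group taxonomy starts at 16.
* Problem sizes in the shipped verification suites — e.g. 200 null cohorts of
  5,000 genes × 10 regions for the calibration suite, 100 planted cohorts for
  breadth recovery, 50 + 6 tiles for segmentation, 1,000 × 1,000 shuffles for
  permutation calibration, 100 seeds for the age model — were chosen to make
  Monte-Carlo error small relative to each acceptance band while remaining
  desk-scale; the acceptance script uses moderately smaller replicate counts
  for the same quantities.

# Known limitations

* The specificity-score formula and marker threshold are this package's
  interpretive choices; published marker lists derived with other scores
  will differ gene-by-gene even when the biology agrees.
* The imaging pipeline assumes pre-extracted RGB tiles; whole-slide formats,
  stitching, and nuclear/cytoplasmic signal separation are out of scope.
* Permutation inference treats tiles as exchangeable units; case-level
  random effects are not modeled.
* The stepwise search is greedy; it reports one good model, not the set of
  equivalent models under collinearity.
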