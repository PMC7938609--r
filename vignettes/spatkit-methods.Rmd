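---
title: "Statistical methods in spatkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods in spatkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatkit)
```

spatkit analyzes spatially resolved expression data: a genes x cells count
matrix plus a 2D (or 3D) centroid per cell. This vignette documents the
models and statistics behind each analysis, the tunable parameters and
their defaults, the numerical conventions, and what the synthetic
benchmarks do and do not demonstrate.

## The container and preprocessing

All functions operate on a `spat_state`: raw counts, derived `normalized`
and `scaled` layers, cell/gene metadata, spatial networks and grids, and
result tables. Preprocessing follows the standard single-cell recipe:

* `filter_dataset()` removes low-quality cells **first** (fewer than
  `min_detected_genes_per_cell` genes at the detection threshold, default
  1 count) and lowly detected genes **second**. The cells-then-genes order
  makes the result independent of gene ordering.
* `normalize_default()` computes
  `log_b(count / libsize * scale_factor + offset)` with base 2, offset 1
  and `scale_factor = 6000` by default. The scale factor is an arbitrary
  target library size; any positive value works and it is recorded in the
  state's parameter log. Optional rescaling adds a gene-wise z-score layer;
  zero-variance genes become all-zero rows by convention. A second,
  cell-wise standardization pass is deliberately not applied.
* `adjust_for_covariates()` regresses the normalized layer on technical
  covariates (one-hot categorical encoding, reference level dropped) and
  keeps residual + gene mean, so per-gene means are preserved to 1e-9.
* `find_hvg()` selects highly variable genes either by within-bin z-scores
  of the coefficient of variation (20 equal-size mean-expression bins,
  z > 1.5) or by a local polynomial (loess) trend of CoV versus mean with
  span 0.3, flagging genes above the fitted trend. The CoV is computed on
  the log-normalized layer with the sample (n−1) standard deviation; the
  raw-versus-log choice is a convention of this package, documented here
  because either is defensible.

## Spatial structures

`create_delaunay_network()` connects cells through Delaunay triangulation
edges (2D; computed by the deldir package). Co-circular degeneracies are
resolved by the triangulation's deterministic tie-breaking — for exactly
co-circular points (e.g. a perfect square) the diagonal choice is
platform-stable but arbitrary. Duplicate or collinear centroids are
rejected with pointers to the kNN alternative. 3D data use
`create_knn_network()` (k nearest neighbors, default k = 4, symmetrized to
an undirected graph); a `max_dist` cutoff can prune long edges while
`min_k` guarantees every cell keeps its nearest neighbors regardless of
distance. Edge weights are binary by default or `1/(1+d)`.

`create_spatial_grid()` tiles the bounding box with boxes anchored at the
per-axis minimum. Boxes are half-open on the high side except the last
box, which is closed, so every cell maps to exactly one box; per-box
expression is the member-cell mean.

## Gini marker genes

For gene *i* and cluster *j*, let `X(i,j)` be the mean log-normalized
expression and `Y(i,j)` the detection fraction (normalized value > 0). The
Gini coefficient

$$G(x) = \frac{\sum_i \sum_j |x_i - x_j|}{2 n^2 \bar{x}}$$

of the row `X(i,·)` (resp. `Y(i,·)`) measures how concentrated expression
(detection) is across clusters: 0 for a constant row, approaching 1 when
one cluster carries everything. It is computed by the O(n log n) sorted
identity, which equals the double sum exactly, and is scale- and
permutation-invariant. Clusters are then ranked per gene (rank 1 =
highest; ties averaged) and the rank r over K clusters is rescaled
linearly to `0.1 + 0.9·(K−r)/(K−1)`, so the top cluster scores 1 and the
bottom 0.1. The aggregated score
`G_final = G_expr · G_det · R_expr · R_det` is therefore large only for
genes that are specific to, and well detected in, exactly one cluster.
Ranks are computed before the `min_expr`/`min_det` floors are applied to a
gene's top cluster. `markers_one_vs_all()` repeats the computation on each
{cluster, rest} dichotomy.

## Spot-level cell-type enrichment

Lower-resolution platforms measure spots containing several cells. All
scorers start from per-spot fold changes
`fc[g,s] = (x[g,s] + 0.1) / (mean_s x[g,·] + 0.1)`. The fold change is the
plain ratio: we verified on scrambled data that the normal null PAGE fits
(below) is well calibrated on ratio fold changes, whereas set means of
*log* fold changes are left-skewed and make the fitted upper-tail p-values
conservative. The rank-based scorer is unaffected by this choice because
ranks are invariant under monotone transforms; the calibration itself is
re-measured by the test suite and the acceptance script.

**PAGE.** For a signature of m marker genes with mean fold change `S_m`,
and spot-wise mean μ and sample standard deviation δ over all genes,
`ES = (S_m − μ)·√m / δ`. The null draws `n_perm = 1000` random same-size
gene sets (shared across spots by default; a flag redraws them per spot)
and fits a normal distribution per (spot, type); p-values are its upper
tail, Benjamini–Hochberg-adjusted over all (spot, type) pairs. Spots with
zero fold-change variance are excluded with a warning.

**RANK.** A reference single-cell dataset provides, per cell type, the
fold-change rank `R1_g` of every gene (`make_signature_rank_matrix()`,
pseudo-count 0.1); the spatial data provide the spot-specificity rank
`R2_g`. The mutual rank `R_g = √(R1_g · R2_g)` becomes a rank-biased
precision score `RBP_g = (1−p)·p^(R_g−1)` with persistence p = 0.99, and
`ES = Σ` of the top 100 RBP values, so `ES ≤ 1 − 0.99^100 ≈ 0.634`. The
null shuffles the reference ranking 1000 times and fits a gamma
distribution (maximum likelihood via fitdistrplus, method-of-moments
start; empirical p-values with the (1+k)/(1+N) estimator if the fit
degenerates). Because a shuffled `R1` is a uniform random permutation and
every spot's `R2` is itself a permutation of 1..G, the null ES
distribution is identical across spots, so one null sample per cell type
suffices — an exact symmetry, not an approximation (average-rank ties
perturb it negligibly).

**Hypergeometric.** Spot-specific genes are the top 5% by expression (ties
broken by gene index); the marker/non-marker x specific/non-specific 2x2
table is tested with the hypergeometric upper tail and
`ES = −log10(p)`.

**Spearman.** A comparison scorer: correlation between the spot profile
and each type's mean reference profile, no null fit.

`enrichment_auc()` evaluates any scorer against known spot composition via
the Mann–Whitney AUC with average-rank tie handling.

## BinSpect: spatially coherent genes

Each gene is binarized across cells: 1D k-means with k = 2 (10
deterministic restarts initialized from quantile pairs; the larger-center
cluster is "high"), or a rank threshold labeling the top 30% high (ties by
cell index). Constant genes binarize to all zeros with a warning. The
undirected spatial-network edges are then tallied into a 2x2 table of
endpoint combinations — concordant edges on the diagonal, discordant edges
split evenly between the two off-diagonal cells — and Fisher's exact test
gives an odds ratio (conditional MLE; Haldane-corrected sample odds ratio
when a table cell is zero) and p-value, BH-adjusted across genes.

Two conventions were open. (1) Counting each edge once versus counting
both orientations: doubling every cell of a 2x2 table roughly squares the
evidence, so the doubled table is anti-conservative under the null; we
compared both on position-scrambled data, kept single counting, and the
suite and acceptance script re-measure its calibration. (2) The even
discordant split keeps the two-sided p exactly invariant to edge
orientation and to swapping the high/low labels (the swapped table is a
transpose plus 180° rotation of the original, both of which Fisher's test
is invariant to). Hub cells are high cells with at least 2 high neighbors
(configurable). `rank_spatial_genes()` orders by ascending p, then
descending odds ratio.

## Spatial co-expression modules

`smooth_expression_spatial()` replaces each cell's value by the mean of
itself and up to k (default 5) of its nearest spatial-network neighbors,
or by its grid-box mean; the focal cell is included. Mean aggregation
never increases per-gene variance. `spatial_gene_correlation()` computes
gene–gene Pearson (or Spearman) correlation on the smoothed matrix and,
separately, on the original single-cell matrix: genes sharing a spatial
pattern but expressed in different cells correlate spatially yet not
intrinsically, which is the signature of genuinely spatial co-expression.
Zero-variance genes get zero off-diagonal correlation and a flag. Modules
come from average-linkage hierarchical clustering of `1 − r` distances,
cut to a module count or height; metagenes average the gene-wise z-scored
expression of module members so modules with different absolute levels
are comparable.

## Cell neighborhoods

**Proximity enrichment.** Network edges are labeled homo- or heterotypic;
observed per-pair counts are compared with 1000 label permutations over
the nodes (network fixed). The report gives the observed/expected ratio
and one-sided empirical p-values with the (1+k)/(1+N) estimator, which
never returns exactly zero. Pair counts always sum to the edge total, in
every permutation.

**Ligand–receptor communication.** For ligand L, receptor R and types A,
B: `S = mean(L over interacting A-cells) + mean(R over interacting
B-cells)`, interacting meaning "with at least one network neighbor of the
other type". The null shuffles cell positions within each focal type
(equivalently: draws random same-size subsets within type), keeping other
types untouched; p-values are two-sided empirical (with a relative 1e-9
tie tolerance so exactly invariant scores yield p = 1), BH-adjusted over
all rows; pairs with fewer than 4 interacting cells on either side are
dropped. `expression_lr_communication()` is the spatially unaware analog:
all A- and B-cells, null subsets drawn from all cells. The activity score
multiplies log2(S/perm-mean) by −log10(adjusted p); the literal product
with the adjusted p itself is available behind `literal = TRUE`, but as a
default it would shrink the most significant pairs toward zero and invert
the intended ranking. `compare_communication_rankings()` asks, per type
pair, how early the expression-only ranking recovers the spatially
top-ranked pair (AUC; 1 = immediately, 0 = last).

**Interaction-changed genes.** Per source type A and neighbor type B, the
A-cells split into those with/without a B neighbor, and each gene is
tested between subgroups (Welch t, Wilcoxon, or a membership-permutation
test), BH-adjusted within the (A, B) block; blocks with a subgroup below
2 cells are skipped. Because the normalized layer is log2-scale, the
reported `log2fc` is the difference of subgroup means of log2-normalized
expression. `filter_icg()` applies cell-count, FDR, fold-change and
expression floors.

## Synthetic data and benchmarks

`simulate_layered_tissue()` emulates laminar tissue: cells uniform in a
rectangle (default 2000 cells in 2000x2000 length units, so the default
500-unit coarse-graining step gives a 4x4 spot grid), types assigned by
horizontal band (or block, or at random for null experiments), negative
binomial counts (dispersion 0.5, gene baselines log-normal with median
~1.6 counts) and 20 markers per type elevated 5-fold. It captures
count noise, detection dropout and spatial organization; it does **not**
capture segmentation errors, spatially varying capture efficiency,
cell-shape effects or real marker redundancy, so passing benchmarks shows
the statistics behave as designed, not that any biological dataset will
reach the same accuracy.

`plant_icg_effect()` and `plant_lr_effect()` add contact-induced effects:
affected genes are **re-drawn** from a negative binomial at the baseline
(mean 4) or fold-elevated rate, as a transcriptional induction would do —
multiplying realized counts would leave dropout zeros in place and
understate the detection shift.

`run_pattern_simulation()` implements the planted-pattern protocol: per
gene, the cells are ordered by expression; group G (as many top expressers
as pattern positions) receives weight Pr and the rest weight 1 − Pr, and
the pattern positions are filled by weighted sampling without replacement
(via the exponential-race scheme, seed-controlled), expression values
untouched. Pr = 1 places exactly the top expressers; Pr = 0.5 is uniform.
Defaults (100 genes, Pr ∈ {0.5, 0.65, 0.8, 0.9, 0.95, 0.99, 1}, 6
repetitions) give 4200 instances per pattern.
`benchmark_spatial_gene_methods()` scores BinSpect's p-value ranking of
planted versus position-scrambled genes (4 scrambled copies per planted
gene) as an AUC per probability level; since BinSpect tests genes
marginally against the fixed network, each gene's assignment is applied
independently, letting one BinSpect run per (Pr, rep) evaluate all genes.

`coarse_grain_spots()` grids the tissue (default step 500 length units)
and **sums** the normalized single-cell expression per box — the summing
convention conserves per-gene totals exactly and is the default; box-mean
aggregation is available by flag. Per-spot cell-type fractions are
recorded as ground truth for the enrichment AUC benchmarks.

## Calibration experiments and their design

The test suite checks every permutation or fitted null on data where the
null hypothesis holds exactly: marker folds set to 1 (so signatures are
exchangeable with random gene sets — with genuinely elevated markers even
position scrambling leaves their fold-change variance atypical), positions
or labels scrambled, ~1000 spots or 2000 cells, fixed seeds. Scaled-down
problem sizes (e.g. 3 repetitions per probability level in the pattern
benchmark, 400–1000 permutations) were chosen so the full suite runs in a
few minutes while keeping Monte-Carlo error well below the tested margins.
Two adjacent probability levels near chance (0.5, 0.65) have true AUCs
within ~0.02 of each other; the monotonicity check therefore averages over
repetitions to keep the ordering stable.

## Known limitations

* Delaunay networks are 2D; 3D tissues use kNN networks.
* The per-spot fold-change pseudo-count (0.1) matters for near-zero genes;
  it is configurable on every scorer.
* Empirical p-values are bounded below by 1/(n_perm + 1).
* A 4-fold planted induction yields a measured log2 fold change of at most
  ~2 (library-size dilution and the log transform's damping pull it
  slightly below); filters demanding |log2FC| > 2 will sit exactly at that
  boundary and recover roughly half of such genes, as the acceptance run
  reports. Stronger effects clear the threshold comfortably.
* Community detection (Louvain/Leiden), loess smoothing, hierarchical
  clustering, Fisher's exact test and the gamma fit are delegated to
  igraph, stats and fitdistrplus; this package contributes the spatial
  statistics built on top of them.
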