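# spatkit

An R toolkit for the statistical analysis of spatial transcriptomic (and
proteomic) data at single-cell or spot resolution. Given a gene-by-cell
expression matrix and cell centroid coordinates, spatkit builds the spatial
structures and runs the spatial statistics that turn "where each cell sits"
into biology:

* **Preprocessing** — filtering, library-size log-normalization, per-cell and
  per-gene statistics, covariate adjustment, highly variable gene selection,
  expression-space kNN/sNN graphs and community clustering with
  correlation-based cluster merging.
* **Spatial structures** — Delaunay and k-nearest-neighbor spatial networks
  over cell centroids, and spatial grids with per-box expression averaging.
* **Gini marker detection** — cluster markers scored by
  `G_final(i,j) = G_expr(i) x G_det(i) x R_expr(i,j) x R_det(i,j)`, where
  `G_expr`/`G_det` are Gini coefficients of a gene's per-cluster mean
  expression and detection fraction (`G(x) = Σ_i Σ_j |x_i − x_j| / (2 n² x̄)`)
  and `R` are cluster ranks rescaled to [0.1, 1].
* **Spot enrichment** — for multi-cell spots (Visium/Slide-seq resolution),
  cell-type enrichment by PAGE (`ES = (S_m − μ)·√m / δ` on per-spot fold
  changes, normal-fitted random-set null), RANK (mutual rank
  `R_g = √(R1_g·R2_g)` converted to rank-biased precision
  `RBP_g = (1−p)·p^(R_g−1)`, `ES = Σ top-100 RBP`, gamma-fitted shuffle null),
  hypergeometric overlap tests, and a Spearman profile scorer, plus AUC
  evaluation against known spot composition.
* **BinSpect** — spatially coherent gene detection: binarize each gene
  (k-means or rank threshold), tally high/low combinations over spatial
  network edges into a 2x2 table, Fisher exact test, plus hub-cell counts.
* **Spatial co-expression** — neighbor smoothing, spatial vs cell-intrinsic
  gene-gene correlation, average-linkage module clustering, and metagenes.
* **Cell neighborhoods** — cell-type proximity enrichment
  (observed/expected homo- and hetero-typic edges under label permutation),
  spatially informed ligand-receptor communication
  (`S = mean L over interacting A-cells + mean R over interacting B-cells`
  with a within-type shuffle null) and its expression-only counterpart,
  their ranking comparison, and interaction-changed genes (ICG) with
  t/Wilcoxon/permutation tests and threshold filtering.
* **Simulation benchmarks** — a layered-tissue generator with planted
  markers, ICG and ligand-receptor effects; the planted-pattern protocol
  (assign cells to a fixed pattern with probability Pr ∈ {0.5 … 1}, 100
  genes x 7 levels x 6 reps = 4200 instances per pattern); and
  coarse-graining of single-cell data into spots with known composition.

## Worked example

```r
library(spatkit)

# a 2000-cell, 4-type layered tissue with 20 planted markers per type
ts <- simulate_layered_tissue(seed = 2)
ts <- normalize_default(ts)
ts <- create_delaunay_network(ts)
labels <- ts$results$simulation_truth$labels

# which cell types sit next to each other?
prox <- proximity_enrichment(ts$networks$delaunay, labels, seed = 2)
head(prox[order(-prox$ratio), c("type_a", "type_b", "observed_edges",
                                "expected_edges", "ratio")], 3)
#>    type_a type_b observed_edges expected_edges    ratio
#> 1   type1  type1           1384        344.823 4.013653
#> 10  type4  type4           1426        369.897 3.855127
#> 3   type2  type2           1380        371.655 3.713121
```

Homotypic edge ratios near 4 say each type's cells neighbor their own kind
~4x more often than in label-permuted tissue — the layered structure.

```r
# coarse-grain to spots and score cell-type enrichment with PAGE
cg <- coarse_grain_spots(ts, step = 500)
spot <- normalize_default(cg$state)
page <- page_enrichment(spot, ts$results$simulation_truth$markers, seed = 2)
enrichment_auc(page, cg$composition > 0.1)
#> type1 type2 type3 type4
#>     1     1     1     1
```

AUC 1 per type: the enrichment score ranks every spot that truly contains a
type above every spot that does not.

A command-line entry point wrapping the same functions is installed at
`system.file("cli", "spatkit", package = "spatkit")`; it operates on a state
directory of TSV files plus a JSON manifest (see `write_state()`).

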