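#' Simulate a layered synthetic tissue
#'
#' Places cells uniformly at random in a rectangle and assigns each a cell
#' type by horizontal band (`"layers"`, emulating laminar tissue such as
#' cortex), by rectangular spatial block (`"blocks"`), or at random
#' (`"random"`, the spatial null). Counts are drawn from a negative
#' binomial with gene-specific baseline means (log-normal across genes) and
#' each type's marker genes elevated `marker_fold`-fold in that type.
#' Ground truth (labels, marker map, layout) is stored under
#' `results$simulation_truth`.
#'
#' @param n_cells Number of cells.
#' @param n_types Number of cell types.
#' @param n_genes Number of genes.
#' @param n_markers_per_type Marker genes per type
#'   (`n_markers_per_type * n_types` must not exceed `n_genes`).
#' @param marker_fold Fold elevation of a marker in its own type.
#' @param layout `"layers"`, `"blocks"` or `"random"`.
#' @param seed Integer seed (default 0).
#' @param dispersion Negative binomial dispersion (default 0.5; variance =
#'   mu + dispersion * mu^2).
#' @param width,height Tissue extent in length units (default 2000, sized
#'   so the default 500-unit coarse-graining step yields a 4x4 spot grid).
#' @return A `spat_state` with a `cell_type` annotation and simulation
#'   ground truth in `results$simulation_truth`.
#' @export
simulate_layered_tissue <- function(n_cells = 2000, n_types = 4,
                                    n_genes = 500, n_markers_per_type = 20,
                                    marker_fold = 5,
                                    layout = c("layers", "blocks", "random"),
                                    seed = 0, dispersion = 0.5,
                                    width = 2000, height = 2000) {
  layout <- match.arg(layout)
  stopifnot(n_cells > 0, n_types > 0, n_genes > 0, marker_fold > 0)
  if (n_markers_per_type * n_types > n_genes)
    stop("n_markers_per_type * n_types exceeds n_genes")
  set.seed(seed)
  x <- stats::runif(n_cells, 0, width)
  y <- stats::runif(n_cells, 0, height)
  types <- paste0("type", seq_len(n_types))
  type_id <- switch(layout,
    layers = pmin(floor(y / height * n_types) + 1L, n_types),
    blocks = {
      nbx <- ceiling(sqrt(n_types))
      bx <- pmin(floor(x / width * nbx) + 1L, nbx)
      by <- pmin(floor(y / height * ceiling(n_types / nbx)) + 1L,
                 ceiling(n_types / nbx))
      pmin((by - 1L) * nbx + bx, n_types)
    },
    random = sample.int(n_types, n_cells, replace = TRUE))
  labels <- types[type_id]

  gene_ids <- sprintf("gene%03d", seq_len(n_genes))
  base_mu <- stats::rlnorm(n_genes, meanlog = 0.5, sdlog = 1)
  markers <- lapply(seq_len(n_types), function(t)
    gene_ids[(t - 1) * n_markers_per_type + seq_len(n_markers_per_type)])
  names(markers) <- types

  mu <- matrix(base_mu, n_genes, n_cells)
  for (t in seq_len(n_types)) {
    rows <- (t - 1) * n_markers_per_type + seq_len(n_markers_per_type)
    mu[rows, type_id == t] <- mu[rows, type_id == t] * marker_fold
  }
  counts <- matrix(stats::rnbinom(n_genes * n_cells, mu = mu,
                                  size = 1 / dispersion),
                   n_genes, n_cells,
                   dimnames = list(gene_ids,
                                   sprintf("cell%04d", seq_len(n_cells))))
  state <- create_spat_state(counts, cbind(x = x, y = y),
                             annotations = data.frame(cell_type = labels))
  state$results$simulation_truth <- list(
    labels = stats::setNames(labels, colnames(counts)),
    markers = markers, layout = layout,
    parameters = list(n_cells = n_cells, n_types = n_types,
                      n_genes = n_genes, marker_fold = marker_fold,
                      dispersion = dispersion, seed = seed))
  .log_call(state, "simulate_layered_tissue",
            list(layout = layout, seed = seed))
}

#' Planted spatial-pattern simulation
#'
#' For each selected gene, cells are ordered by expression and split into
#' group G (the top expressers, as many as there are pattern positions) and
#' group R (the rest). For each probability level Pr and repetition, the
#' pattern positions are filled by weighted sampling without replacement,
#' giving weight Pr to G members and 1 - Pr to R members; the remaining
#' cells fill the non-pattern positions in random order. Expression values
#' are untouched - only the assignment of cells to positions changes - so
#' at Pr = 1 the pattern cells are exactly the top expressers and at
#' Pr = 0.5 the assignment is uniformly random. With the defaults
#' (100 genes, 7 probability levels, 6 repetitions) each pattern yields
#' 4200 simulation instances.
#'
#' @param state A `spat_state`.
#' @param pattern_cells Cell ids (or indices) forming the fixed spatial
#'   pattern; fewer than the number of cells.
#' @param gene_ids Genes to simulate (default: 100 genes sampled from the
#'   dataset, or all genes when fewer).
#' @param prob_levels Probability levels Pr, each in (0, 1]; default
#'   `c(0.5, 0.65, 0.8, 0.9, 0.95, 0.99, 1)`.
#' @param reps Repetitions per (gene, Pr) (default 6).
#' @param seed Integer seed (default 0).
#' @return Object of class `pattern_simulation`: a list with `instances`
#'   (data.frame gene/pr/rep), `assignment` (list of integer vectors, one
#'   per instance, mapping each position/original cell index to the cell
#'   whose expression now sits there), `pattern_positions` (integer
#'   positions of the pattern), and the generating parameters.
#' @export
run_pattern_simulation <- function(state, pattern_cells, gene_ids = NULL,
                                   prob_levels = c(0.5, 0.65, 0.8, 0.9,
                                                   0.95, 0.99, 1),
                                   reps = 6, seed = 0) {
  stopifnot(inherits(state, "spat_state"))
  if (any(prob_levels <= 0 | prob_levels > 1))
    stop("probability levels must lie in (0, 1]")
  expr <- .expr_or_raw(state)
  n <- ncol(expr)
  if (is.character(pattern_cells))
    pattern_cells <- match(pattern_cells, state$cells$cell_id)
  pattern_cells <- as.integer(pattern_cells)
  if (anyNA(pattern_cells) || length(pattern_cells) >= n)
    stop("pattern_cells must name fewer than all cells")
  P <- length(pattern_cells)
  set.seed(seed)
  if (is.null(gene_ids))
    gene_ids <- rownames(expr)[sample.int(nrow(expr),
                                          min(100L, nrow(expr)))]
  if (!all(gene_ids %in% rownames(expr))) stop("unknown gene ids")

  instances <- expand.grid(rep = seq_len(reps), pr = prob_levels,
                           gene = gene_ids, stringsAsFactors = FALSE,
                           KEEP.OUT.ATTRS = FALSE)[, c("gene", "pr", "rep")]
  assignment <- vector("list", nrow(instances))
  non_pattern <- setdiff(seq_len(n), pattern_cells)
  for (g in gene_ids) {
    ord <- order(-expr[g, ], seq_len(n))
    inG <- logical(n)
    inG[ord[seq_len(P)]] <- TRUE
    rows <- which(instances$gene == g)
    for (r in rows) {
      pr <- instances$pr[r]
      w <- ifelse(inG, pr, 1 - pr)
      # weighted sampling without replacement via the exponential race
      u <- stats::rexp(n) / w
      sel <- order(u)[seq_len(P)]
      perm <- integer(n)
      perm[pattern_cells] <- sel
      perm[non_pattern] <- sample(setdiff(seq_len(n), sel))
      assignment[[r]] <- perm
    }
  }
  structure(list(instances = instances, assignment = assignment,
                 pattern_positions = pattern_cells,
                 parameters = list(prob_levels = prob_levels, reps = reps,
                                   seed = seed, n_genes = length(gene_ids))),
            class = "pattern_simulation")
}

#' @export
print.pattern_simulation <- function(x, ...) {
  cat("pattern_simulation:", nrow(x$instances), "instances (",
      x$parameters$n_genes, "genes x", length(x$parameters$prob_levels),
      "probability levels x", x$parameters$reps, "reps )\n")
  invisible(x)
}

#' Coarse-grain single-cell spatial data into spots
#'
#' Grids the tissue into square boxes of the given step and aggregates the
#' normalized single-cell expression within each box into one spot, by
#' summation (default) or averaging. Spots without cells are dropped. When
#' a cell type annotation is present the per-spot type composition is
#' recorded, giving ground truth for evaluating spot-level enrichment
#' methods.
#'
#' @param state A `spat_state` with a normalized layer and 2D coordinates.
#' @param step Box side length (default 500 length units).
#' @param aggregation `"sum"` or `"mean"`.
#' @param annotation Cell annotation column holding cell types (default
#'   `"cell_type"`; ignored when absent).
#' @return List with `state` (spot-level `spat_state`, raw layer = the
#'   aggregated values, spot coordinates = box centers), `composition`
#'   (spots x types fraction matrix or NULL), and `cells_per_spot`.
#' @export
coarse_grain_spots <- function(state, step = 500,
                               aggregation = c("sum", "mean"),
                               annotation = "cell_type") {
  aggregation <- match.arg(aggregation)
  if (step <= 0) stop("step must be positive")
  norm <- get_expression(state, "normalized")
  co <- spat_coords(state)
  if (ncol(co) != 2) stop("coarse-graining requires 2D coordinates")
  tmp <- create_spatial_grid(state, step_x = step, step_y = step,
                             values = "normalized", name = ".cg")
  grid <- tmp$grids[[".cg"]]
  occupied <- which(grid$counts > 0)
  agg <- grid$aggregated[, occupied, drop = FALSE]
  if (aggregation == "sum")
    agg <- sweep(agg, 2, grid$counts[occupied], "*")
  spot_ids <- sprintf("spot%03d", seq_along(occupied))
  colnames(agg) <- spot_ids

  # box centers as spot coordinates
  dims <- grid$dims
  bx <- (occupied - 1L) %% dims[1] + 1L
  by <- (occupied - 1L) %/% dims[1] + 1L
  ctr <- cbind(x = (grid$breaks[[1]][bx] + grid$breaks[[1]][bx + 1]) / 2,
               y = (grid$breaks[[2]][by] + grid$breaks[[2]][by + 1]) / 2)

  composition <- NULL
  if (annotation %in% names(state$cells)) {
    f <- factor(state$cells[[annotation]])
    tab <- table(factor(grid$box_id, levels = occupied), f)
    composition <- as.matrix(tab / pmax(rowSums(tab), 1))
    dimnames(composition) <- list(spot_ids, levels(f))
  }
  spot_state <- create_spat_state(agg, ctr)
  list(state = spot_state, composition = composition,
       cells_per_spot = stats::setNames(grid$counts[occupied], spot_ids))
}

#' Benchmark spatial-gene methods on planted-pattern simulations
#'
#' For each (Pr, rep) of a pattern simulation, builds a dataset holding the
#' planted arrangement of every simulated gene alongside
#' `null_per_gene` position-scrambled copies, runs BinSpect, and computes
#' the AUC of the p-value ranking at separating planted from scrambled
#' genes. Since BinSpect tests genes marginally against the fixed network,
#' each gene's own position assignment is applied independently.
#'
#' @param state The `spat_state` the simulation was generated from.
#' @param sims A `pattern_simulation`.
#' @param method `"binspect_kmeans"` or `"binspect_rank"`.
#' @param network Optional `spat_network` (default: kNN network, k = 4).
#' @param null_per_gene Scrambled control copies per planted gene
#'   (default 4).
#' @param seed Integer seed for the scrambled controls (default 0).
#' @return List with `per_run` (data.frame pr/rep/auc) and `by_pr`
#'   (mean AUC per probability level).
#' @export
benchmark_spatial_gene_methods <- function(state, sims,
                                           method = c("binspect_kmeans",
                                                      "binspect_rank"),
                                           network = NULL,
                                           null_per_gene = 4, seed = 0) {
  method <- match.arg(method)
  bin_method <- sub("binspect_", "", method)
  expr <- .expr_or_raw(state)
  n <- ncol(expr)
  if (is.null(network)) {
    tmp <- create_knn_network(state, k = 4)
    network <- tmp$networks[["knn"]]
  }
  set.seed(seed)
  inst <- sims$instances
  runs <- unique(inst[, c("pr", "rep")])
  genes <- unique(inst$gene)
  per_run <- do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
    sel <- inst$pr == runs$pr[i] & inst$rep == runs$rep[i]
    rows_p <- lapply(which(sel), function(r)
      expr[inst$gene[r], sims$assignment[[r]]])
    planted <- do.call(rbind, rows_p)
    rownames(planted) <- paste0(inst$gene[sel], "_planted")
    null_rows <- do.call(rbind, lapply(seq_len(null_per_gene), function(j) {
      m <- t(vapply(genes, function(g) expr[g, sample.int(n)], numeric(n)))
      rownames(m) <- paste0(genes, "_null", j)
      m
    }))
    mat <- rbind(planted, null_rows)
    colnames(mat) <- state$cells$cell_id
    tmp_state <- create_spat_state(mat, spat_coords(state))
    tab <- binspect(tmp_state, network, method = bin_method)
    score <- -log10(pmax(tab$p_value, 1e-300))
    score[is.na(score)] <- 0
    data.frame(pr = runs$pr[i], rep = runs$rep[i],
               auc = .auc(score, grepl("_planted$", tab$gene)))
  }))
  by_pr <- tapply(per_run$auc, per_run$pr, mean)
  list(per_run = per_run, by_pr = by_pr)
}

#' Plant an interaction effect into a synthetic tissue
#'
#' Multiplies the raw counts of the given genes by `fold` in the source-type
#' cells that have at least one spatial-network neighbor of the neighbor
#' type, emulating genes induced by cell-cell contact (the ground truth for
#' interaction-changed-gene analyses). Optionally the affected genes' raw
#' counts are first re-drawn at a fixed moderate baseline mean so the
#' planted effect size is comparable across genes. Derived layers are
#' dropped; re-run normalization afterwards.
#'
#' @param state A `spat_state` (counts in the raw layer).
#' @param network A `spat_network` defining adjacency.
#' @param source_type,neighbor_type Cell type labels (annotation
#'   `cell_type`).
#' @param genes Gene ids to perturb.
#' @param fold Fold change applied in the interacting subgroup (default 4).
#' @param baseline_mean If not NULL (default 4), re-draw the affected
#'   genes' counts from a negative binomial with this mean (dispersion 0.5)
#'   before applying the fold.
#' @param seed Integer seed (default 0).
#' @return The state with modified raw counts and the planted truth
#'   appended to `results$simulation_truth$icg`.
#' @export
plant_icg_effect <- function(state, network, source_type, neighbor_type,
                             genes, fold = 4, baseline_mean = 4, seed = 0) {
  stopifnot(inherits(state, "spat_state"), all(genes %in% state$genes$gene_id))
  labels <- state$cells$cell_type
  if (is.null(labels)) stop("state needs a cell_type annotation")
  set.seed(seed)
  nbr <- .adjacency_list(network, ncol(state$expr$raw))
  A <- which(labels == source_type)
  hasB <- vapply(nbr[A], function(v) any(labels[v] == neighbor_type),
                 logical(1))
  target <- A[hasB]
  if (length(target) == 0) stop("no interacting source cells")
  raw <- state$expr$raw
  if (!is.null(baseline_mean)) {
    # induction re-draws counts at the baseline / elevated rate (so
    # detection rises too), rather than multiplying realized counts,
    # which would leave zeros at zero
    raw[genes, ] <- matrix(stats::rnbinom(length(genes) * ncol(raw),
                                          mu = baseline_mean, size = 2),
                           length(genes), ncol(raw))
    raw[genes, target] <- stats::rnbinom(length(genes) * length(target),
                                         mu = fold * baseline_mean, size = 2)
  } else {
    raw[genes, target] <- raw[genes, target] * fold
  }
  state$expr$raw <- raw
  state$expr$normalized <- NULL
  state$expr$scaled <- NULL
  state$results$simulation_truth$icg <-
    list(genes = genes, source_type = source_type,
         neighbor_type = neighbor_type, fold = fold,
         interacting_cells = state$cells$cell_id[target])
  .log_call(state, "plant_icg_effect",
            list(source_type = source_type, neighbor_type = neighbor_type,
                 fold = fold, n_genes = length(genes)))
}

#' Plant a spatially restricted ligand-receptor interaction
#'
#' Elevates the ligand gene's counts in source-type cells adjacent to the
#' neighbor type and the receptor gene's counts in neighbor-type cells
#' adjacent to the source type, emulating communication confined to
#' physically interacting cells. Non-adjacent cells of the two types keep
#' baseline expression, so a spatially informed analysis should detect the
#' pair while an expression-only analysis sees a diluted effect.
#'
#' @inheritParams plant_icg_effect
#' @param ligand,receptor Gene ids for the pair.
#' @param fold Fold elevation in the interacting subsets (default 8).
#' @return The state with modified raw counts and the planted truth under
#'   `results$simulation_truth$lr`.
#' @export
plant_lr_effect <- function(state, network, source_type, neighbor_type,
                            ligand, receptor, fold = 8, baseline_mean = 4,
                            seed = 0) {
  stopifnot(inherits(state, "spat_state"),
            all(c(ligand, receptor) %in% state$genes$gene_id))
  labels <- state$cells$cell_type
  if (is.null(labels)) stop("state needs a cell_type annotation")
  set.seed(seed)
  nbr <- .adjacency_list(network, ncol(state$expr$raw))
  intA <- .interacting_cells(nbr, labels, source_type, neighbor_type)
  intB <- .interacting_cells(nbr, labels, neighbor_type, source_type)
  if (length(intA) == 0 || length(intB) == 0)
    stop("the two types are never adjacent")
  raw <- state$expr$raw
  if (!is.null(baseline_mean))
    raw[c(ligand, receptor), ] <-
      matrix(stats::rnbinom(2 * ncol(raw), mu = baseline_mean, size = 2),
             2, ncol(raw))
  raw[ligand, intA] <- raw[ligand, intA] * fold
  raw[receptor, intB] <- raw[receptor, intB] * fold
  state$expr$raw <- raw
  state$expr$normalized <- NULL
  state$expr$scaled <- NULL
  state$results$simulation_truth$lr <-
    list(ligand = ligand, receptor = receptor, source_type = source_type,
         neighbor_type = neighbor_type, fold = fold)
  .log_call(state, "plant_lr_effect",
            list(source_type = source_type, neighbor_type = neighbor_type,
                 fold = fold))
}
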