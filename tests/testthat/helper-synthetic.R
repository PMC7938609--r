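# Small in-code fixtures shared across test files.

# a tiny deterministic state: `raw` genes x cells with ids, coords on a grid
tiny_state <- function(raw, coords = NULL, annotations = NULL) {
  ng <- nrow(raw); nc <- ncol(raw)
  if (is.null(rownames(raw))) rownames(raw) <- paste0("g", seq_len(ng))
  if (is.null(colnames(raw))) colnames(raw) <- paste0("c", seq_len(nc))
  if (is.null(coords))
    coords <- cbind(x = seq_len(nc), y = rep(0.5, nc))
  create_spat_state(raw, coords, annotations = annotations)
}

# random NB state with uniform coordinates
random_state <- function(n_genes = 50, n_cells = 100, seed = 1,
                         width = 100) {
  set.seed(seed)
  raw <- matrix(rnbinom(n_genes * n_cells, mu = 4, size = 2),
                n_genes, n_cells,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("c%03d", seq_len(n_cells))))
  co <- cbind(x = runif(n_cells, 0, width), y = runif(n_cells, 0, width))
  create_spat_state(raw, co)
}

# hand-built spatial network over cells 1..n from an index edge list
manual_network <- function(state, a, b) {
  co <- spat_coords(state)
  d <- sqrt(rowSums((co[a, , drop = FALSE] - co[b, , drop = FALSE])^2))
  structure(list(
    edges = data.frame(cell_a = state$cells$cell_id[pmin(a, b)],
                       cell_b = state$cells$cell_id[pmax(a, b)],
                       idx_a = pmin(a, b), idx_b = pmax(a, b),
                       distance = d, weight = 1,
                       stringsAsFactors = FALSE),
    parameters = list(method = "manual")), class = "spat_network")
}

# brute-force O(n^2) Gini oracle: the printed double-sum definition
gini_oracle <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# Mann-Whitney AUC oracle via wilcox.test statistic
auc_oracle <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  unname(suppressWarnings(
    wilcox.test(score[positive], score[!positive])$statistic) / (n1 * n0))
}
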