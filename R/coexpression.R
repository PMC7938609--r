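#' Spatially smooth expression over neighboring cells
#'
#' `mode = "network_knn"` replaces each cell's value by the mean of itself
#' and its (up to) k nearest spatial-network neighbors; `k = 0` returns the
#' input unchanged. `mode = "grid"` replaces each cell's value by the mean
#' of its grid box.
#'
#' @param state A `spat_state` with a normalized layer.
#' @param mode `"network_knn"` or `"grid"`.
#' @param k Number of network neighbors to average over (default 5).
#' @param network A `spat_network` (required for network_knn with k > 0).
#' @param grid A `spat_grid` (required for grid mode).
#' @return Genes x cells matrix of smoothed values.
#' @export
smooth_expression_spatial <- function(state, mode = c("network_knn", "grid"),
                                      k = 5, network = NULL, grid = NULL) {
  mode <- match.arg(mode)
  expr <- get_expression(state, "normalized")
  n <- ncol(expr)
  if (mode == "grid") {
    if (is.null(grid)) stop("grid required for grid mode")
    sm <- grid$aggregated[rownames(expr), grid$box_id, drop = FALSE]
    dimnames(sm) <- dimnames(expr)
    return(sm)
  }
  if (k < 0) stop("k must be non-negative")
  if (k == 0) return(expr)
  if (is.null(network)) stop("network required for network_knn mode")
  e <- network$edges
  # per cell: itself plus its k nearest network neighbors, weights 1/(1+used)
  idx <- c(e$idx_a, e$idx_b)
  other <- c(e$idx_b, e$idx_a)
  d <- c(e$distance, e$distance)
  o <- order(idx, d)
  idx <- idx[o]; other <- other[o]
  keep <- stats::ave(seq_along(idx), idx, FUN = seq_along) <= k
  idx <- idx[keep]; other <- other[keep]
  deg <- tabulate(idx, nbins = n)
  W <- Matrix::sparseMatrix(i = c(seq_len(n), idx), j = c(seq_len(n), other),
                            x = 1, dims = c(n, n))
  W <- Matrix::Diagonal(x = 1 / (deg + 1)) %*% W
  sm <- as.matrix(Matrix::tcrossprod(expr, W))
  dimnames(sm) <- dimnames(expr)
  sm
}

#' Spatial versus cell-intrinsic gene-gene correlation
#'
#' Correlates genes on spatially smoothed values (spatial correlation) and
#' on the original single-cell values (intrinsic correlation). A gene pair
#' that shares a spatial pattern but is expressed in different cells shows
#' high spatial but low intrinsic correlation, which is what distinguishes
#' genuinely spatial co-expression.
#'
#' @param smoothed Genes x cells matrix from [smooth_expression_spatial()].
#' @param original Genes x cells matrix of unsmoothed normalized expression.
#' @param method `"pearson"` or `"spearman"`.
#' @return List of class `coexpression_result` with `spatial_correlation`,
#'   `intrinsic_correlation` (both genes x genes, unit diagonal; rows for
#'   zero-variance genes are 0 off-diagonal and flagged in `zero_variance`).
#' @export
spatial_gene_correlation <- function(smoothed, original,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!identical(rownames(smoothed), rownames(original)))
    stop("smoothed and original matrices must share the same genes")
  if (nrow(smoothed) < 2) stop("need at least 2 genes")
  corr_of <- function(m) {
    zv <- apply(m, 1, stats::sd) == 0
    cm <- suppressWarnings(stats::cor(t(m), method = method))
    cm[is.na(cm)] <- 0
    diag(cm) <- 1
    list(cor = cm, zv = zv)
  }
  sp <- corr_of(smoothed)
  intr <- corr_of(original)
  structure(list(spatial_correlation = sp$cor,
                 intrinsic_correlation = intr$cor,
                 zero_variance = sp$zv | intr$zv,
                 method = method),
            class = "coexpression_result")
}

#' Cluster the spatial co-expression network into modules
#'
#' Average-linkage hierarchical clustering on the distance
#' `1 - correlation`, cut either into `n_modules` groups or at
#' `cut_height`.
#'
#' @param spatial_correlation Genes x genes correlation matrix (or a
#'   `coexpression_result`).
#' @param n_modules Number of modules (mutually exclusive with
#'   `cut_height`).
#' @param cut_height Dendrogram cut height on the 1 - r scale.
#' @return Integer module id per gene, named by gene id.
#' @export
cluster_coexpression_modules <- function(spatial_correlation,
                                         n_modules = NULL,
                                         cut_height = NULL) {
  if (inherits(spatial_correlation, "coexpression_result"))
    spatial_correlation <- spatial_correlation$spatial_correlation
  G <- nrow(spatial_correlation)
  if (G < 2) stop("need at least 2 genes")
  if (!is.null(n_modules) && n_modules > G)
    stop("n_modules (", n_modules, ") exceeds the number of genes (", G, ")")
  hc <- stats::hclust(stats::as.dist(1 - spatial_correlation),
                      method = "average")
  if (!is.null(n_modules)) stats::cutree(hc, k = n_modules)
  else if (!is.null(cut_height)) stats::cutree(hc, h = cut_height)
  else stop("provide n_modules or cut_height")
}

#' Metagene scores per co-expression module
#'
#' Per module, the metagene of a cell is the mean over the module's member
#' genes of gene-wise z-scored normalized expression, so modules with
#' different absolute expression levels are comparable.
#'
#' @param state A `spat_state` with a normalized layer.
#' @param module_assignment Module id per gene, named by gene id.
#' @return Cells x modules numeric matrix.
#' @export
metagene_scores <- function(state, module_assignment) {
  norm <- get_expression(state, "normalized")
  genes <- names(module_assignment)
  if (is.null(genes) || !all(genes %in% rownames(norm)))
    stop("module assignment must be named by dataset gene ids")
  z <- .rowwise_zscore(norm[genes, , drop = FALSE])
  mods <- sort(unique(module_assignment))
  out <- vapply(mods, function(m) {
    members <- genes[module_assignment == m]
    if (length(members) == 0) stop("empty module: ", m)
    colMeans(z[members, , drop = FALSE])
  }, numeric(ncol(norm)))
  colnames(out) <- paste0("module_", mods)
  rownames(out) <- colnames(norm)
  out
}
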