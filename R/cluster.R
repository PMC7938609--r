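#' Nearest-neighbor graph in expression space
#'
#' Builds a kNN (or shared-NN) graph over cells by Euclidean distance in
#' either normalized expression space or a PCA projection of it. For the sNN
#' variant the edge weight is the number of shared k-nearest neighbors and
#' edges sharing none are dropped; for plain kNN the weight is 1.
#'
#' @param state A `spat_state` with a normalized layer.
#' @param space `"normalized"` or `"pca"`.
#' @param k Number of nearest neighbors (clamped to #cells - 1 with a
#'   warning).
#' @param shared Build the shared-nearest-neighbor variant.
#' @param n_pcs Number of principal components when `space = "pca"`.
#' @return An `igraph` undirected graph whose vertices are cell ids.
#' @export
build_expression_neighbor_graph <- function(state,
                                            space = c("normalized", "pca"),
                                            k = 10, shared = FALSE,
                                            n_pcs = 25) {
  space <- match.arg(space)
  norm <- get_expression(state, "normalized")
  n <- ncol(norm)
  if (k >= n) {
    warning("k clamped to #cells - 1 = ", n - 1L)
    k <- n - 1L
  }
  feat <- t(norm)
  if (space == "pca") {
    n_pcs <- min(n_pcs, nrow(feat) - 1L, ncol(feat))
    feat <- stats::prcomp(feat, center = TRUE, scale. = FALSE,
                          rank. = n_pcs)$x
  }
  nn <- .knn_indices(feat, k)
  from <- rep(seq_len(n), each = k)
  to <- as.vector(t(nn))
  if (shared) {
    # shared neighbor count between each kNN pair
    nbr <- lapply(seq_len(n), function(i) nn[i, ])
    w <- mapply(function(a, b) length(intersect(nbr[[a]], nbr[[b]])), from, to)
    keep <- w > 0
    from <- from[keep]; to <- to[keep]; w <- w[keep]
  } else {
    w <- rep(1, length(from))
  }
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b)
  first <- !duplicated(key)
  g <- igraph::graph_from_data_frame(
    data.frame(from = state$cells$cell_id[a[first]],
               to = state$cells$cell_id[b[first]],
               weight = w[first]),
    directed = FALSE,
    vertices = state$cells$cell_id)
  g
}

# k nearest neighbor indices (self excluded); exact distances, deterministic
# tie-break by lowest index.
.knn_indices <- function(feat, k) {
  n <- nrow(feat)
  if (n <= 2000) {
    d <- as.matrix(stats::dist(feat))
    t(vapply(seq_len(n), function(i) {
      o <- order(d[i, ], seq_len(n))   # ties broken by lowest index
      o[o != i][seq_len(k)]
    }, integer(k)))
  } else {
    RANN::nn2(feat, k = k + 1L)$nn.idx[, -1, drop = FALSE]
  }
}

#' Cluster cells into communities
#'
#' Community detection itself is delegated to published algorithms: Leiden
#' and Louvain run on a neighbor graph (igraph implementations), k-means and
#' hierarchical clustering run on normalized expression profiles.
#'
#' @param state A `spat_state`.
#' @param graph Neighbor graph from [build_expression_neighbor_graph()]
#'   (required for leiden/louvain).
#' @param method One of `"leiden"`, `"louvain"`, `"kmeans"`, `"hclust"`.
#' @param resolution_or_k Resolution parameter (leiden/louvain) or number of
#'   clusters (kmeans/hclust).
#' @param seed Integer seed for the randomized methods (default 0).
#' @return Character vector of cluster labels named by cell id.
#' @export
cluster_communities <- function(state, graph = NULL,
                                method = c("leiden", "louvain", "kmeans",
                                           "hclust"),
                                resolution_or_k = 1, seed = 0) {
  method <- match.arg(method)
  ids <- state$cells$cell_id
  if (method %in% c("leiden", "louvain")) {
    if (is.null(graph)) stop("graph required for ", method)
    set.seed(seed)
    comm <- if (method == "louvain") igraph::cluster_louvain(
      graph, resolution = resolution_or_k)
    else igraph::cluster_leiden(graph, objective_function = "modularity",
                                resolution = resolution_or_k)
    labels <- as.character(igraph::membership(comm))
    names(labels) <- igraph::V(graph)$name
    labels <- labels[ids]
  } else {
    feat <- t(get_expression(state, "normalized"))
    if (method == "kmeans") {
      set.seed(seed)
      labels <- as.character(stats::kmeans(feat, centers = resolution_or_k,
                                           nstart = 10)$cluster)
    } else {
      hc <- stats::hclust(stats::dist(feat), method = "ward.D2")
      labels <- as.character(stats::cutree(hc, k = resolution_or_k))
    }
    names(labels) <- ids
  }
  labels
}

#' Merge transcriptionally similar clusters
#'
#' Computes Pearson correlations between cluster mean expression profiles and
#' iteratively merges the most correlated pair while that correlation exceeds
#' `cor_threshold`, or while any cluster is smaller than `min_size` (an
#' undersized cluster is merged into its most correlated partner).
#'
#' @param state A `spat_state` with a normalized layer.
#' @param labels Cluster labels named by cell id (or in cell order).
#' @param cor_threshold Correlation above which clusters merge; must lie in
#'   (-1, 1).
#' @param min_size Minimum cluster size (default 1 = no size-forced merges).
#' @return Updated label vector named by cell id.
#' @export
merge_similar_clusters <- function(state, labels, cor_threshold,
                                   min_size = 1) {
  if (cor_threshold <= -1 || cor_threshold >= 1)
    stop("cor_threshold must lie strictly inside (-1, 1)")
  norm <- get_expression(state, "normalized")
  labels <- .align_labels(labels, state$cells$cell_id)
  repeat {
    sizes <- table(labels)
    if (length(sizes) < 2) break
    prof <- vapply(names(sizes),
                   function(cl) rowMeans(norm[, labels == cl, drop = FALSE]),
                   numeric(nrow(norm)))
    cm <- suppressWarnings(stats::cor(prof))
    cm[is.na(cm)] <- 0
    diag(cm) <- -Inf
    top <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    small <- names(sizes)[sizes < min_size]
    if (max(cm) > cor_threshold) {
      from <- colnames(cm)[top[2]]; to <- rownames(cm)[top[1]]
    } else if (length(small)) {
      from <- small[1]
      to <- names(which.max(cm[, from]))
    } else break
    labels[labels == from] <- to
  }
  labels
}

# accept labels as named vector or positional vector; return named, aligned
.align_labels <- function(labels, cell_ids) {
  if (!is.null(names(labels))) {
    if (!all(cell_ids %in% names(labels)))
      stop("labels missing for some cells")
    labels <- labels[cell_ids]
  } else {
    if (length(labels) != length(cell_ids))
      stop("labels must have one entry per cell")
    names(labels) <- cell_ids
  }
  as.character(labels) -> out
  names(out) <- cell_ids
  out
}
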