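#' Gini coefficient of a non-negative vector
#'
#' Computes `G(x) = sum_i sum_j |x_i - x_j| / (2 n^2 mean(x))`, the mean
#' absolute difference between all ordered pairs normalized by twice the
#' mean. G is 0 for a constant vector, approaches 1 when a single entry
#' carries all the mass, and is invariant to positive rescaling and to
#' permutation of the entries. Implemented in O(n log n) via the sorted-value
#' identity, which equals the quadratic double sum exactly.
#'
#' @param x Numeric vector of non-negative values with positive mean.
#' @return The Gini coefficient, in [0, 1).
#' @examples
#' gini(c(0, 1))        # 0.5
#' gini(c(0, 0, 0, 1))  # 0.75
#' gini(rep(3, 10))     # 0
#' @export
gini <- function(x) {
  if (length(x) < 1 || anyNA(x)) stop("x must be a non-empty numeric vector")
  if (any(x < 0)) stop("x must be non-negative")
  m <- mean(x)
  if (m <= 0) stop("Gini coefficient undefined for a zero-mean vector")
  n <- length(x)
  s <- sort(x)
  # sum_{i,j} |x_i - x_j| = 2 * sum_i (2i - n - 1) * x_(i)
  sum((2 * seq_len(n) - n - 1) * s) / (n^2 * m)
}

#' Gini-coefficient marker gene scores per cluster
#'
#' For each gene, `X(i, j)` is the mean log-normalized expression in cluster
#' j and `Y(i, j)` the detection fraction (normalized expression > 0).
#' `G_expr(i)` and `G_det(i)` are the Gini coefficients of the X and Y rows:
#' large when expression or detection concentrates in few clusters. Clusters
#' are ranked per gene by X and by Y (rank 1 = highest, ties averaged) and
#' the ranks rescaled linearly to [0.1, 1] with the top cluster at 1. The
#' aggregated score is
#' `G_final(i, j) = G_expr(i) * G_det(i) * R_expr(i, j) * R_det(i, j)`,
#' rewarding genes that are both specific to and well detected in exactly
#' one cluster.
#'
#' @param state A `spat_state` with a normalized layer.
#' @param labels Cluster labels (named by cell id, or in cell order); at
#'   least two clusters.
#' @param min_expr Minimum mean expression in a gene's top cluster
#'   (default 0.1).
#' @param min_det Minimum detection fraction in a gene's top cluster
#'   (default 0.1).
#' @return data.frame with one row per (gene, cluster): columns `gene`,
#'   `cluster`, `G_expr`, `G_det`, `R_expr`, `R_det`, `G_final`,
#'   `mean_expr`, `detection`; sorted per cluster by descending `G_final`.
#' @export
compute_gini_markers <- function(state, labels, min_expr = 0.1,
                                 min_det = 0.1) {
  norm <- get_expression(state, "normalized")
  labels <- .align_labels(labels, state$cells$cell_id)
  cl <- sort(unique(labels))
  K <- length(cl)
  if (K < 2) stop("at least two clusters required")
  sizes <- table(labels)
  if (any(sizes < 2))
    warning("cluster(s) with fewer than 2 cells: ",
            paste(names(sizes)[sizes < 2], collapse = ", "))

  X <- vapply(cl, function(c) rowMeans(norm[, labels == c, drop = FALSE]),
              numeric(nrow(norm)))
  Y <- vapply(cl, function(c) rowMeans(norm[, labels == c, drop = FALSE] > 0),
              numeric(nrow(norm)))
  if (!is.matrix(X)) {   # single-gene dataset
    X <- matrix(X, 1, K, dimnames = list(rownames(norm), cl))
    Y <- matrix(Y, 1, K, dimnames = list(rownames(norm), cl))
  }
  G_expr <- apply(X, 1, function(r) if (mean(r) > 0) gini(r) else 0)
  G_det <- apply(Y, 1, function(r) if (mean(r) > 0) gini(r) else 0)
  rescale <- function(r) 0.1 + 0.9 * (K - r) / (K - 1)
  R_expr <- t(apply(X, 1, function(r)
    rescale(rank(-r, ties.method = "average"))))
  R_det <- t(apply(Y, 1, function(r)
    rescale(rank(-r, ties.method = "average"))))
  G_final <- G_expr * G_det * R_expr * R_det

  out <- data.frame(
    gene = rep(rownames(norm), times = K),
    cluster = rep(cl, each = nrow(norm)),
    G_expr = rep(G_expr, times = K),
    G_det = rep(G_det, times = K),
    R_expr = as.vector(R_expr),
    R_det = as.vector(R_det),
    G_final = as.vector(G_final),
    mean_expr = as.vector(X),
    detection = as.vector(Y),
    stringsAsFactors = FALSE)

  # drop genes whose TOP cluster fails the expression/detection floors
  top_expr <- apply(X, 1, max)
  top_det <- apply(Y, 1, max)
  ok_gene <- rownames(norm)[top_expr >= min_expr & top_det >= min_det]
  out <- out[out$gene %in% ok_gene, , drop = FALSE]
  out <- out[order(out$cluster, -out$G_final), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-vs-all Gini marker detection
#'
#' For each cluster c, recomputes the Gini marker table on the two-group
#' labeling {c, rest} and reports the rows for c, giving a combined marker
#' table across clusters.
#'
#' @inheritParams compute_gini_markers
#' @param method Marker method; only `"gini"` is implemented.
#' @param top_n Keep at most this many markers per cluster (default Inf).
#' @return data.frame as [compute_gini_markers()], with `cluster` the
#'   originating cluster, sorted by cluster then descending `G_final`.
#' @export
markers_one_vs_all <- function(state, labels, method = "gini",
                               min_expr = 0.1, min_det = 0.1, top_n = Inf) {
  method <- match.arg(method, "gini")
  labels <- .align_labels(labels, state$cells$cell_id)
  cl <- sort(unique(labels))
  if (length(cl) < 2) stop("at least two clusters required")
  res <- lapply(cl, function(c) {
    two <- ifelse(labels == c, c, ".rest")
    tab <- compute_gini_markers(state, two, min_expr = min_expr,
                                min_det = min_det)
    tab <- tab[tab$cluster == c, , drop = FALSE]
    utils::head(tab[order(-tab$G_final), , drop = FALSE], top_n)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
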