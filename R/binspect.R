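#' Binarize a per-cell expression vector
#'
#' `method = "kmeans"` partitions the values into two 1D clusters (10
#' deterministic restarts initialized from quantile pairs; the cluster with
#' the larger center is labeled high). `method = "rank"` labels the top
#' `ceiling(rank_fraction * n)` values high, breaking ties by cell index.
#'
#' @param x Numeric vector (length >= 2).
#' @param method `"kmeans"` or `"rank"`.
#' @param rank_fraction Fraction labeled high under the rank method
#'   (default 0.30).
#' @param seed Unused for the deterministic initializations; kept for
#'   interface stability.
#' @return Integer 0/1 vector; a constant vector yields all zeros with a
#'   warning.
#' @export
binarize_expression <- function(x, method = c("kmeans", "rank"),
                                rank_fraction = 0.30, seed = 0) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 2) stop("need at least 2 values")
  if (max(x) == min(x)) {
    warning("constant vector; binarized to all zeros")
    return(integer(n))
  }
  if (method == "rank") {
    k <- ceiling(rank_fraction * n)
    out <- integer(n)
    out[order(-x, seq_len(n))[seq_len(k)]] <- 1L
    return(out)
  }
  # 1D k-means, 10 restarts seeded from quantile pairs of the data
  qs <- stats::quantile(x, probs = seq(0.05, 0.95, length.out = 20))
  best <- NULL; best_ss <- Inf
  for (i in 1:10) {
    centers <- c(qs[i], qs[21 - i])
    if (centers[1] == centers[2]) next
    km <- suppressWarnings(stats::kmeans(x, centers = matrix(centers)))
    if (km$tot.withinss < best_ss) { best <- km; best_ss <- km$tot.withinss }
  }
  if (is.null(best)) {   # heavily tied values; fall back to a median split
    return(as.integer(x > stats::median(x)))
  }
  as.integer(best$cluster == which.max(best$centers))
}

#' BinSpect: spatially coherent gene detection
#'
#' For each gene, expression is binarized across cells and the undirected
#' network edges are tallied into a 2x2 contingency table of high/low
#' endpoint combinations: concordant edges fill the diagonal and discordant
#' edges are split evenly between the two off-diagonal cells (each edge
#' counted once; the even split makes the two-sided test exactly invariant
#' to the arbitrary edge orientation and to swapping the high/low labels).
#' Fisher's exact test on the table yields an odds ratio and p-value: a
#' gene whose high cells are preferentially adjacent scores an odds ratio
#' above 1. Hub cells are high cells with at least `hub_min_neighbors`
#' high network neighbors.
#'
#' @param state A `spat_state` with a normalized layer.
#' @param network A `spat_network` over the dataset cells (with >= 1 edge).
#' @param method Binarization method, `"kmeans"` or `"rank"`.
#' @param rank_fraction Fraction labeled high under the rank method.
#' @param hub_min_neighbors Minimum high neighbors for a hub cell
#'   (default 2).
#' @param seed Passed to [binarize_expression()].
#' @return data.frame with one row per gene: `gene`, `odds_ratio`,
#'   `p_value`, `adjusted_p`, `avg_expression`, `n_high_cells`,
#'   `n_hub_cells`, `degenerate` (TRUE when binarization produced a single
#'   class and the test was skipped), plus the method parameters as
#'   attributes. Odds ratios are the conditional MLE from the exact test,
#'   or the Haldane-corrected sample odds ratio when a table cell is zero.
#' @export
binspect <- function(state, network, method = c("kmeans", "rank"),
                     rank_fraction = 0.30, hub_min_neighbors = 2, seed = 0) {
  method <- match.arg(method)
  expr <- .expr_or_raw(state)
  e <- network$edges
  if (is.null(e) || nrow(e) == 0) stop("empty spatial network")
  ia <- e$idx_a; ib <- e$idx_b
  G <- nrow(expr)
  B <- matrix(0L, G, ncol(expr), dimnames = dimnames(expr))
  for (g in seq_len(G))
    B[g, ] <- suppressWarnings(
      binarize_expression(expr[g, ], method = method,
                          rank_fraction = rank_fraction, seed = seed))

  Ba <- B[, ia, drop = FALSE]; Bb <- B[, ib, drop = FALSE]
  hh <- rowSums(Ba * Bb)                       # concordant high-high edges
  ll <- rowSums((1 - Ba) * (1 - Bb))           # concordant low-low edges
  hl <- nrow(e) - hh - ll                      # discordant edges
  n_high <- rowSums(B)
  # hub cells: high cells with >= hub_min_neighbors high neighbors.
  # Ma/Mb are edge x cell incidence matrices for the two endpoints, so
  # (Bb %*% Ma)[g, c] counts high neighbors of c reached via its idx_a edges.
  Ma <- Matrix::sparseMatrix(i = seq_along(ia), j = ia, x = 1,
                             dims = c(nrow(e), ncol(B)))
  Mb <- Matrix::sparseMatrix(i = seq_along(ib), j = ib, x = 1,
                             dims = c(nrow(e), ncol(B)))
  high_nbrs <- as.matrix(Bb %*% Ma + Ba %*% Mb)
  n_hub <- rowSums(B * (high_nbrs >= hub_min_neighbors))

  or <- p <- rep(NA_real_, G)
  degenerate <- n_high == 0 | n_high == ncol(B)
  for (g in which(!degenerate)) {
    d1 <- floor(hl[g] / 2); d2 <- hl[g] - d1
    tab <- matrix(c(hh[g], d1, d2, ll[g]), 2)
    ft <- stats::fisher.test(tab)
    p[g] <- ft$p.value
    if (any(tab == 0)) {   # Haldane-corrected sample odds ratio
      or[g] <- ((hh[g] + 0.5) * (ll[g] + 0.5)) / ((d1 + 0.5) * (d2 + 0.5))
    } else {
      or[g] <- unname(ft$estimate)
    }
  }
  out <- data.frame(
    gene = rownames(expr),
    odds_ratio = or,
    p_value = p,
    adjusted_p = NA_real_,
    avg_expression = rowMeans(expr),
    n_high_cells = n_high,
    n_hub_cells = n_hub,
    degenerate = degenerate,
    stringsAsFactors = FALSE)
  out$adjusted_p[!degenerate] <- stats::p.adjust(p[!degenerate], method = "BH")
  attr(out, "method") <- method
  attr(out, "rank_fraction") <- rank_fraction
  attr(out, "hub_min_neighbors") <- hub_min_neighbors
  rownames(out) <- NULL
  out
}

#' Rank spatially coherent genes
#'
#' Orders the BinSpect table by ascending p-value, breaking ties by
#' descending odds ratio, and returns the top `top_k` gene ids.
#'
#' @param table Result of [binspect()].
#' @param top_k Number of genes to return (a larger `top_k` than the table
#'   returns all genes with a warning).
#' @return Character vector of gene ids.
#' @export
rank_spatial_genes <- function(table, top_k) {
  if (nrow(table) == 0) stop("empty table")
  tab <- table[!table$degenerate, , drop = FALSE]
  if (top_k > nrow(tab)) {
    warning("top_k (", top_k, ") exceeds table size (", nrow(tab),
            "); returning all genes")
    top_k <- nrow(tab)
  }
  tab$gene[order(tab$p_value, -tab$odds_ratio)][seq_len(top_k)]
}
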