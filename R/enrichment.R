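# Cell-type enrichment scoring for multi-cell spots.
#
# PAGE and RANK work on per-spot fold changes of expression against the mean
# over spots, computed as a plain ratio with a pseudo-count:
#   fc[g, s] = (expr[g, s] + offset) / (mean_s expr[g, .] + offset)
# The ratio (rather than its log) keeps the distribution of random-set means
# close to the normal null PAGE fits; RANK only uses the ranks of fc, which
# are invariant to any monotone transform.

.spot_foldchange <- function(expr, offset = 0.1) {
  (expr + offset) / (rowMeans(expr) + offset)
}

.col_sds <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  sqrt(pmax(colSums(m^2) - n * mu^2, 0) / (n - 1))
}

# PAGE enrichment scores from a fold-change matrix (genes x spots) and a
# marker gene index set: ES = (S_m - mu) * sqrt(m) / delta per spot.
# Invariant to adding a constant to, or positively rescaling, a spot's fold
# changes.
.page_es <- function(fc, sig_idx) {
  m <- length(sig_idx)
  mu <- colMeans(fc)
  delta <- .col_sds(fc)
  S_m <- colMeans(fc[sig_idx, , drop = FALSE])
  (S_m - mu) * sqrt(m) / delta
}

#' Build a cell-type specificity rank matrix from reference single-cell data
#'
#' For each cell type, the fold change of every gene is the ratio of its mean
#' expression within the type to its mean over all cells (a pseudo-count is
#' added to numerator and denominator), and `R1_g` is the descending rank of
#' that fold change (rank 1 = most type-specific; ties averaged).
#'
#' @param sc_expression Genes x cells matrix of (normalized) reference
#'   single-cell expression.
#' @param sc_labels Cell type label per reference cell.
#' @param offset Pseudo-count (default 0.1).
#' @return Matrix genes x cell types of ranks `R1_g`.
#' @export
make_signature_rank_matrix <- function(sc_expression, sc_labels,
                                       offset = 0.1) {
  sc_expression <- as.matrix(sc_expression)
  sc_labels <- as.character(sc_labels)
  if (length(sc_labels) != ncol(sc_expression))
    stop("one label per reference cell required")
  types <- sort(unique(sc_labels))
  if (length(types) < 2) stop("at least two cell types required")
  overall <- rowMeans(sc_expression)
  R1 <- vapply(types, function(t) {
    sel <- sc_labels == t
    if (!any(sel)) stop("cell type with zero cells: ", t)
    fc <- (rowMeans(sc_expression[, sel, drop = FALSE]) + offset) /
      (overall + offset)
    rank(-fc, ties.method = "average")
  }, numeric(nrow(sc_expression)))
  rownames(R1) <- rownames(sc_expression)
  R1
}

#' PAGE cell-type enrichment of spots
#'
#' Parametric Analysis of Gene Set Enrichment applied per spot: with `S_m`
#' the mean fold change of the m marker genes of a cell type, and mu, delta
#' the mean and sample standard deviation of all genes' fold changes in that
#' spot, the enrichment score is `ES = (S_m - mu) * sqrt(m) / delta`. The
#' null distribution is estimated from `n_perm` random same-size gene sets
#' and fitted by a normal distribution per (spot, type); p-values are its
#' upper tail, adjusted by Benjamini-Hochberg across all (spot, type) pairs.
#'
#' @param state A `spat_state` of spot-level data with a normalized layer.
#' @param signatures Named list mapping cell type to marker gene ids; each
#'   must intersect at least 2 dataset genes.
#' @param n_perm Number of random gene sets (default 1000).
#' @param seed Integer seed (default 0).
#' @param offset Fold-change pseudo-count (default 0.1).
#' @param share_null_sets Reuse the same random gene sets across spots
#'   (default TRUE; set FALSE to redraw per spot).
#' @return data.frame with columns `spot`, `cell_type`, `ES`, `S_m`, `mu`,
#'   `delta`, `p_value`, `adjusted_p`. Spots with zero fold-change variance
#'   are excluded with a warning.
#' @export
page_enrichment <- function(state, signatures, n_perm = 1000, seed = 0,
                            offset = 0.1, share_null_sets = TRUE) {
  expr <- get_expression(state, "normalized")
  fc <- .spot_foldchange(expr, offset)
  G <- nrow(fc)
  mu <- colMeans(fc)
  delta <- .col_sds(fc)
  bad <- delta == 0
  if (any(bad)) {
    warning(sum(bad), " spot(s) with zero fold-change variance excluded")
    fc <- fc[, !bad, drop = FALSE]
    mu <- mu[!bad]; delta <- delta[!bad]
  }
  spots <- colnames(fc)
  set.seed(seed)
  res <- lapply(names(signatures), function(type) {
    sig <- intersect(signatures[[type]], rownames(fc))
    m <- length(sig)
    if (m < 2) stop("signature '", type, "' intersects fewer than 2 genes")
    S_m <- colMeans(fc[sig, , drop = FALSE])
    ES <- .page_es(fc, match(sig, rownames(fc)))
    # null: mean fold change of n_perm random m-gene sets
    draw_sets <- function(cols) {
      idx <- replicate(n_perm, sample.int(G, m))
      ind <- Matrix::sparseMatrix(i = rep(seq_len(n_perm), each = m),
                                  j = as.vector(idx), x = 1 / m,
                                  dims = c(n_perm, G))
      as.matrix(ind %*% fc[, cols, drop = FALSE])  # n_perm x spots null S_m
    }
    Sm_perm <- if (share_null_sets) draw_sets(seq_along(spots))
    else vapply(seq_along(spots), function(s) draw_sets(s)[, 1],
                numeric(n_perm))
    ES_perm <- sweep(sweep(Sm_perm, 2, mu, "-") * sqrt(m), 2, delta, "/")
    null_mu <- colMeans(ES_perm)
    null_sd <- .col_sds(ES_perm)
    p <- stats::pnorm(ES, mean = null_mu, sd = pmax(null_sd, 1e-12),
                      lower.tail = FALSE)
    data.frame(spot = spots, cell_type = type, ES = unname(ES),
               S_m = unname(S_m), mu = unname(mu), delta = unname(delta),
               p_value = unname(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' RANK (rank-biased precision) cell-type enrichment of spots
#'
#' Combines two specificity ranks per gene: `R1_g`, the cell-type fold-change
#' rank from reference single-cell data ([make_signature_rank_matrix()]),
#' and `R2_g`, the spot fold-change rank from the spatial data. The mutual
#' rank `R_g = sqrt(R1_g * R2_g)` is converted to a rank-biased precision
#' score `RBP_g = (1 - p) * p^(R_g - 1)` with persistence p, and the spot's
#' enrichment score is the sum of the `top_n` largest RBP values. The null
#' shuffles the reference gene ranking `n_perm` times per cell type,
#' recomputes ES, and fits a gamma distribution (maximum likelihood,
#' method-of-moments start); p-values are its upper tail, BH-adjusted
#' across all (spot, type) pairs. Because a shuffled `R1` is a uniformly
#' random permutation, the null ES distribution is the same for every spot,
#' so one null sample per type is fitted.
#'
#' @param state A `spat_state` of spot-level data with a normalized layer.
#' @param rank_matrix Genes x cell-types rank matrix; its genes are
#'   intersected with the dataset.
#' @param persistence RBP persistence parameter p (default 0.99).
#' @param top_n Number of top RBP genes summed into ES (default 100).
#' @param n_perm Ranking shuffles for the null (default 1000).
#' @param seed Integer seed (default 0).
#' @param offset Fold-change pseudo-count (default 0.1).
#' @return data.frame with columns `spot`, `cell_type`, `ES`, `p_value`,
#'   `adjusted_p`.
#' @export
rank_enrichment <- function(state, rank_matrix, persistence = 0.99,
                            top_n = 100, n_perm = 1000, seed = 0,
                            offset = 0.1) {
  expr <- get_expression(state, "normalized")
  genes <- intersect(rownames(rank_matrix), rownames(expr))
  if (length(genes) < 2) stop("rank matrix shares fewer than 2 genes with data")
  expr <- expr[genes, , drop = FALSE]
  G <- length(genes)
  if (top_n > G) stop("top_n (", top_n, ") exceeds the number of genes (", G, ")")
  # re-rank the reference matrix within the intersected gene set
  R1 <- apply(rank_matrix[genes, , drop = FALSE], 2,
              function(r) rank(r, ties.method = "average"))
  fc <- .spot_foldchange(expr, offset)
  R2 <- apply(fc, 2, function(v) rank(-v, ties.method = "average"))
  p <- persistence
  top_sum <- function(v) sum(sort(v, decreasing = TRUE)[seq_len(top_n)])

  set.seed(seed)
  res <- lapply(colnames(R1), function(type) {
    RBP <- (1 - p) * p^(sqrt(R1[, type] * R2) - 1)
    ES <- apply(RBP, 2, top_sum)
    # null: shuffled reference ranking against a reference spot ranking 1..G
    null_ES <- vapply(seq_len(n_perm), function(i) {
      top_sum((1 - p) * p^(sqrt(sample.int(G) * seq_len(G)) - 1))
    }, numeric(1))
    pv <- .gamma_upper_tail(ES, null_ES)
    data.frame(spot = colnames(expr), cell_type = type, ES = unname(ES),
               p_value = unname(pv), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

# upper-tail p-values from a gamma fit to the null sample; falls back to the
# empirical (1+k)/(1+N) estimator when the fit is degenerate
.gamma_upper_tail <- function(obs, null_sample) {
  fit <- tryCatch({
    m <- mean(null_sample); v <- stats::var(null_sample)
    if (v <= 0 || any(null_sample <= 0)) stop("degenerate null")
    f <- suppressWarnings(
      fitdistrplus::fitdist(null_sample, "gamma", method = "mle",
                            start = list(shape = m^2 / v, rate = m / v)))
    f$estimate
  }, error = function(e) NULL)
  if (is.null(fit)) {
    warning("gamma fit failed; using empirical p-values")
    return(vapply(obs, function(x)
      (1 + sum(null_sample >= x)) / (1 + length(null_sample)), numeric(1)))
  }
  stats::pgamma(obs, shape = fit["shape"], rate = fit["rate"],
                lower.tail = FALSE)
}

#' Hypergeometric cell-type enrichment of spots
#'
#' Per spot, the top `top_fraction` of genes by expression (ties broken by
#' gene index) are called spot-specific; a 2x2 table over
#' marker/non-marker x spot-specific/not is tested with the hypergeometric
#' upper tail, and `ES = -log10(p)`.
#'
#' @param state A `spat_state` of spot-level data with a normalized layer.
#' @param signatures Named list mapping cell type to marker gene ids.
#' @param top_fraction Fraction of genes called spot-specific (default 0.05).
#' @return data.frame with columns `spot`, `cell_type`, `overlap`,
#'   `n_markers`, `n_top`, `ES`, `p_value`, `adjusted_p`.
#' @export
hypergeometric_enrichment <- function(state, signatures,
                                      top_fraction = 0.05) {
  expr <- get_expression(state, "normalized")
  G <- nrow(expr)
  k <- ceiling(top_fraction * G)
  top_sets <- apply(expr, 2, function(v)
    rownames(expr)[order(-v, seq_len(G))[seq_len(k)]])
  res <- lapply(names(signatures), function(type) {
    sig <- intersect(signatures[[type]], rownames(expr))
    m <- length(sig)
    if (m == 0) stop("signature '", type, "' has no genes in the dataset")
    x <- colSums(matrix(top_sets %in% sig, nrow = k))
    pv <- stats::phyper(x - 1, m, G - m, k, lower.tail = FALSE)
    data.frame(spot = colnames(expr), cell_type = type,
               overlap = x, n_markers = m, n_top = k,
               ES = -log10(pv), p_value = pv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Spearman-correlation cell-type enrichment of spots
#'
#' Simple comparison scorer: the ES of a (spot, type) pair is the Spearman
#' correlation between the spot's expression profile and the cell type's
#' mean reference profile. No null distribution is fitted.
#'
#' @param state A `spat_state` of spot-level data with a normalized layer.
#' @param profiles Genes x cell-types matrix of mean reference expression.
#' @return data.frame with columns `spot`, `cell_type`, `ES`.
#' @export
spearman_enrichment <- function(state, profiles) {
  expr <- get_expression(state, "normalized")
  genes <- intersect(rownames(profiles), rownames(expr))
  if (length(genes) < 3) stop("too few shared genes")
  cm <- stats::cor(expr[genes, , drop = FALSE], profiles[genes, , drop = FALSE],
                   method = "spearman")
  data.frame(spot = rep(rownames(cm), times = ncol(cm)),
             cell_type = rep(colnames(cm), each = nrow(cm)),
             ES = as.vector(cm), stringsAsFactors = FALSE)
}

#' AUC of enrichment scores against known spot composition
#'
#' For each cell type, computes the area under the ROC curve of the
#' enrichment score as a ranking predictor of the type's presence in each
#' spot (Mann-Whitney formulation, ties counted half).
#'
#' @param result Enrichment result with columns `spot`, `cell_type`, `ES`.
#' @param truth Logical matrix spots x cell types (or data.frame) of
#'   presence; dimnames must cover the result's spots and types.
#' @return Named numeric vector of per-type AUCs; types with all-positive or
#'   all-negative truth are NA.
#' @export
enrichment_auc <- function(result, truth) {
  truth <- as.matrix(truth)
  types <- intersect(unique(result$cell_type), colnames(truth))
  if (length(types) == 0) stop("no shared cell types between result and truth")
  vapply(stats::setNames(types, types), function(type) {
    sub <- result[result$cell_type == type, ]
    keep <- sub$spot %in% rownames(truth)
    sub <- sub[keep, ]
    y <- truth[sub$spot, type]
    .auc(sub$ES, y)
  }, numeric(1))
}

# Mann-Whitney AUC with average-rank tie handling
.auc <- function(score, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
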