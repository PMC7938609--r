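#' Cell-type proximity enrichment on a spatial network
#'
#' Counts network edges between each unordered pair of cell types (homo- and
#' hetero-typic) and compares them to a null obtained by permuting cell type
#' labels over the network nodes with the network fixed (default 1000
#' permutations). The reported ratio is observed over the permutation mean,
#' and one-sided empirical p-values use the (1+k)/(1+N) estimator so they
#' are never exactly zero.
#'
#' @param network A `spat_network`.
#' @param labels Cell type labels named by cell id, covering all network
#'   nodes.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed (default 0).
#' @return data.frame with one row per unordered type pair: `type_a`,
#'   `type_b`, `pair_type` ("homo"/"hetero"), `observed_edges`,
#'   `expected_edges`, `ratio`, `p_higher`, `p_lower`.
#' @export
proximity_enrichment <- function(network, labels, n_perm = 1000, seed = 0) {
  e <- network$edges
  if (is.null(names(labels))) stop("labels must be named by cell id")
  nodes <- unique(c(e$cell_a, e$cell_b))
  if (!all(nodes %in% names(labels))) stop("labels must cover all network nodes")
  f <- factor(labels)
  types <- levels(f)
  K <- length(types)
  if (K < 2)
    warning("single cell type; proximity enrichment is trivial")
  code <- as.integer(f)                       # unnamed, positional
  pos_a <- match(e$cell_a, names(labels))
  pos_b <- match(e$cell_b, names(labels))

  pair_index <- function(ca, cb) {
    lo <- pmin(ca, cb); hi <- pmax(ca, cb)
    (hi - 1L) * K + lo          # unique per unordered pair since lo <= hi
  }
  nb <- K * K
  obs <- tabulate(pair_index(code[pos_a], code[pos_b]), nbins = nb)

  set.seed(seed)
  perm_counts <- matrix(0L, n_perm, nb)
  for (r in seq_len(n_perm)) {
    pl <- sample(code)
    perm_counts[r, ] <- tabulate(pair_index(pl[pos_a], pl[pos_b]),
                                 nbins = nb)
  }
  keep <- which(obs > 0 | colSums(perm_counts) > 0)
  lo <- (keep - 1L) %% K + 1L
  hi <- (keep - 1L) %/% K + 1L
  expected <- colMeans(perm_counts)[keep]
  p_higher <- (1 + colSums(perm_counts[, keep, drop = FALSE] >=
                             rep(obs[keep], each = n_perm))) / (n_perm + 1)
  p_lower <- (1 + colSums(perm_counts[, keep, drop = FALSE] <=
                            rep(obs[keep], each = n_perm))) / (n_perm + 1)
  out <- data.frame(
    type_a = types[lo], type_b = types[hi],
    pair_type = ifelse(lo == hi, "homo", "hetero"),
    observed_edges = obs[keep],
    expected_edges = expected,
    ratio = obs[keep] / pmax(expected, .Machine$double.eps),
    p_higher = p_higher, p_lower = p_lower,
    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- n_perm
  rownames(out) <- NULL
  out
}

# interacting-cell index sets for one ordered type pair on a network
.interacting_cells <- function(nbr, code, a, b) {
  A <- which(code == a)
  hasB <- vapply(nbr[A], function(v) any(code[v] == b), logical(1))
  A[hasB]
}

# core communication scorer shared by the spatial and expression variants.
# For each LR pair and ordered type pair (A, B):
#   S = mean ligand over the chosen A-cells + mean receptor over the chosen
#   B-cells, compared to n_perm scores from random same-size same-pool
#   subsets.
.communication_scores <- function(expr, lrdb, pair_sets, n_perm, min_cells,
                                  seed, offset, literal) {
  genes <- rownames(expr)
  lr <- lrdb[lrdb$ligand %in% genes & lrdb$receptor %in% genes, , drop = FALSE]
  if (nrow(lr) == 0) stop("no ligand-receptor pair genes found in the dataset")
  L <- expr[lr$ligand, , drop = FALSE]
  R <- expr[lr$receptor, , drop = FALSE]
  set.seed(seed)
  rows <- list()
  for (ps in pair_sets) {
    n <- length(ps$intA); m <- length(ps$intB)
    if (n < min_cells || m < min_cells) next
    S <- rowMeans(L[, ps$intA, drop = FALSE]) +
      rowMeans(R[, ps$intB, drop = FALSE])
    # null: random same-size subsets drawn from the permutation pools
    TA <- Matrix::sparseMatrix(
      i = as.vector(replicate(n_perm, sample(seq_along(ps$poolA), n))),
      j = rep(seq_len(n_perm), each = n), x = 1 / n,
      dims = c(length(ps$poolA), n_perm))
    TB <- Matrix::sparseMatrix(
      i = as.vector(replicate(n_perm, sample(seq_along(ps$poolB), m))),
      j = rep(seq_len(n_perm), each = m), x = 1 / m,
      dims = c(length(ps$poolB), n_perm))
    Sp <- as.matrix(L[, ps$poolA, drop = FALSE] %*% TA) +
      as.matrix(R[, ps$poolB, drop = FALSE] %*% TB)
    perm_mean <- rowMeans(Sp)
    # tolerance so exact ties (e.g. constant genes) count on both sides
    tol <- 1e-9 * pmax(abs(S), 1)
    p_high <- (1 + rowSums(Sp >= S - tol)) / (n_perm + 1)
    p_low <- (1 + rowSums(Sp <= S + tol)) / (n_perm + 1)
    rows[[length(rows) + 1L]] <- data.frame(
      ligand = lr$ligand, receptor = lr$receptor,
      type_a = ps$A, type_b = ps$B,
      n = n, m = m, S = unname(S), perm_mean = perm_mean,
      log2fc = log2((S + offset) / (perm_mean + offset)),
      p_value = pmin(1, 2 * pmin(p_high, p_low)),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(ligand = character(), receptor = character(),
                      type_a = character(), type_b = character(),
                      n = integer(), m = integer(), S = numeric(),
                      perm_mean = numeric(), log2fc = numeric(),
                      p_value = numeric(), adjusted_p = numeric(),
                      activity_score = numeric()))
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out$activity_score <- if (literal) out$log2fc * out$adjusted_p
  else out$log2fc * -log10(pmax(out$adjusted_p, 1e-300))
  rownames(out) <- NULL
  out
}

#' Spatially informed ligand-receptor communication scores
#'
#' For ligand L, receptor R and cell types A, B, the communication score is
#' `S = mean(L over interacting A-cells) + mean(R over interacting
#' B-cells)`, where the interacting A-cells are the A-cells with at least
#' one network neighbor of type B (and vice versa). The null shuffles cell
#' positions within each of the two focal types (network fixed), which is
#' equivalent to drawing random same-size subsets of the A- and B-cells;
#' p-values are two-sided empirical, BH-adjusted over all rows. The
#' activity score multiplies the log2 fold change (observed vs permutation
#' mean) by -log10(adjusted p); set `literal = TRUE` to multiply by the
#' adjusted p itself.
#'
#' @param state A `spat_state` with a normalized layer.
#' @param network A `spat_network` over the dataset cells.
#' @param labels Cell type labels named by cell id (or in cell order).
#' @param lrdb data.frame with `ligand` and `receptor` gene columns.
#' @param n_perm Number of permutations (default 1000).
#' @param min_cells Minimum interacting cells on each side; smaller pairs
#'   are dropped (default 4).
#' @param seed Integer seed (default 0).
#' @param offset Pseudo-count in the log2 fold change (default 0.1).
#' @param literal Use the literal product with adjusted p (default FALSE).
#' @return data.frame with columns `ligand`, `receptor`, `type_a`,
#'   `type_b`, `n`, `m`, `S`, `perm_mean`, `log2fc`, `p_value`,
#'   `adjusted_p`, `activity_score`.
#' @export
spatial_lr_communication <- function(state, network, labels, lrdb,
                                     n_perm = 1000, min_cells = 4, seed = 0,
                                     offset = 0.1, literal = FALSE) {
  expr <- get_expression(state, "normalized")
  labels <- .align_labels(labels, state$cells$cell_id)
  code <- labels
  nbr <- .adjacency_list(network, ncol(expr))
  types <- sort(unique(code))
  idx_of <- split(seq_along(code), code)
  pair_sets <- list()
  for (a in types) for (b in types) {
    intA <- .interacting_cells(nbr, code, a, b)
    intB <- .interacting_cells(nbr, code, b, a)
    if (length(intA) == 0 || length(intB) == 0) next
    pair_sets[[paste(a, b, sep = "--")]] <-
      list(A = a, B = b, intA = intA, intB = intB,
           poolA = idx_of[[a]], poolB = idx_of[[b]])
  }
  .communication_scores(expr, lrdb, pair_sets, n_perm, min_cells, seed,
                        offset, literal)
}

#' Expression-only ligand-receptor communication scores
#'
#' As [spatial_lr_communication()] but without spatial information: the
#' score uses all A-cells and all B-cells, and the null reshuffles all cell
#' labels (subsets are drawn from the whole dataset). Mimics a scRNA-seq
#' analysis.
#'
#' @inheritParams spatial_lr_communication
#' @return As [spatial_lr_communication()].
#' @export
expression_lr_communication <- function(state, labels, lrdb, n_perm = 1000,
                                        min_cells = 4, seed = 0,
                                        offset = 0.1, literal = FALSE) {
  expr <- get_expression(state, "normalized")
  labels <- .align_labels(labels, state$cells$cell_id)
  types <- sort(unique(labels))
  idx_of <- split(seq_along(labels), labels)
  all_cells <- seq_len(ncol(expr))
  pair_sets <- list()
  for (a in types) for (b in types) {
    pair_sets[[paste(a, b, sep = "--")]] <-
      list(A = a, B = b, intA = idx_of[[a]], intB = idx_of[[b]],
           poolA = all_cells, poolB = all_cells)
  }
  .communication_scores(expr, lrdb, pair_sets, n_perm, min_cells, seed,
                        offset, literal)
}

#' How well does expression-only ranking recover the spatial top pairs?
#'
#' Within each cell-type pair, rows are ranked by each method's activity
#' score; the spatially top-ranked ligand-receptor pair is the positive and
#' the AUC measures how early the expression-only ranking recovers it
#' (fraction of other rows ranked below it, ties counted half). The overall
#' AUC averages over type pairs with at least two shared rows.
#'
#' @param spatial Result of [spatial_lr_communication()].
#' @param expr Result of [expression_lr_communication()].
#' @return List with `auc` (mean over type pairs) and `per_pair` (named
#'   vector).
#' @export
compare_communication_rankings <- function(spatial, expr) {
  key <- function(d) paste(d$ligand, d$receptor, d$type_a, d$type_b)
  shared <- intersect(key(spatial), key(expr))
  if (length(shared) == 0) stop("no shared rows between the two analyses")
  sp <- spatial[key(spatial) %in% shared, ]
  ex <- expr[match(key(sp), key(expr)), ]
  pairkey <- paste(sp$type_a, sp$type_b, sep = "--")
  per_pair <- c()
  for (pk in unique(pairkey)) {
    sel <- pairkey == pk
    if (sum(sel) < 2) next
    pos <- which.max(sp$activity_score[sel])
    s <- ex$activity_score[sel]
    r <- rank(s, ties.method = "average")
    per_pair[pk] <- (r[pos] - 1) / (sum(sel) - 1)
  }
  if (length(per_pair) == 0) stop("no type pair with at least two shared rows")
  list(auc = mean(per_pair), per_pair = per_pair)
}

#' Interaction changed genes (ICG)
#'
#' For each source cell type A and neighbor type B, the A-cells are split
#' into those with at least one network neighbor of type B and the rest,
#' and each gene is tested for differential expression between the two
#' subgroups with a t-test, Wilcoxon rank-sum test, or a permutation test
#' that reshuffles the subgroup membership among the A-cells. p-values are
#' BH-adjusted within each (A, B) block.
#'
#' @param state A `spat_state` with a normalized layer.
#' @param network A `spat_network`.
#' @param labels Cell type labels named by cell id (or in cell order).
#' Because the normalized layer is on the log2 scale, the reported `log2fc`
#' is the difference of subgroup means of log2-normalized expression (the
#' usual log fold-change convention for log-transformed data).
#'
#' @param test `"t"`, `"wilcoxon"` or `"permutation"`.
#' @param n_perm Permutations for the permutation test (default 1000).
#' @param seed Integer seed (default 0).
#' @return data.frame with one row per (gene, A, B): `gene`,
#'   `source_type`, `neighbor_type`, `n_with`, `n_without`, `mean_with`,
#'   `mean_without`, `log2fc`, `statistic`, `p_value`, `adjusted_p`.
#'   Blocks where either subgroup has fewer than 2 cells are skipped.
#' @export
find_icg <- function(state, network, labels,
                     test = c("t", "wilcoxon", "permutation"),
                     n_perm = 1000, seed = 0) {
  test <- match.arg(test)
  expr <- get_expression(state, "normalized")
  labels <- .align_labels(labels, state$cells$cell_id)
  nbr <- .adjacency_list(network, ncol(expr))
  types <- sort(unique(labels))
  set.seed(seed)
  blocks <- list()
  for (a in types) for (b in setdiff(types, a)) {
    A <- which(labels == a)
    g1 <- .interacting_cells(nbr, labels, a, b)
    g2 <- setdiff(A, g1)
    if (length(g1) < 2 || length(g2) < 2) next
    X1 <- expr[, g1, drop = FALSE]; X2 <- expr[, g2, drop = FALSE]
    n1 <- length(g1); n2 <- length(g2)
    m1 <- rowMeans(X1); m2 <- rowMeans(X2)
    v1 <- .row_vars(X1); v2 <- .row_vars(X2)
    if (test == "t") {
      se2 <- v1 / n1 + v2 / n2
      stat <- (m1 - m2) / sqrt(pmax(se2, 1e-300))
      df <- se2^2 / pmax((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1),
                         1e-300)
      pv <- 2 * stats::pt(-abs(stat), df)
      pv[se2 == 0] <- 1
    } else if (test == "wilcoxon") {
      res <- apply(expr[, c(g1, g2), drop = FALSE], 1, function(v) {
        w <- suppressWarnings(
          stats::wilcox.test(v[seq_len(n1)], v[-seq_len(n1)], exact = FALSE))
        c(w$statistic, w$p.value)
      })
      stat <- res[1, ]; pv <- res[2, ]
      pv[is.na(pv)] <- 1
    } else {
      obs <- m1 - m2
      pool <- expr[, c(g1, g2), drop = FALSE]
      W <- vapply(seq_len(n_perm), function(i) {
        s <- sample.int(n1 + n2)
        w <- numeric(n1 + n2)
        w[s[seq_len(n1)]] <- 1 / n1
        w[s[-seq_len(n1)]] <- -1 / n2
        w
      }, numeric(n1 + n2))
      perm_stat <- pool %*% W
      stat <- obs
      pv <- (1 + rowSums(abs(perm_stat) >= abs(obs))) / (n_perm + 1)
    }
    blocks[[paste(a, b)]] <- data.frame(
      gene = rownames(expr), source_type = a, neighbor_type = b,
      n_with = n1, n_without = n2,
      mean_with = unname(m1), mean_without = unname(m2),
      log2fc = unname(m1 - m2),
      statistic = unname(stat), p_value = unname(pv),
      adjusted_p = stats::p.adjust(pv, method = "BH"),
      stringsAsFactors = FALSE)
  }
  if (length(blocks) == 0)
    stop("no (source, neighbor) block with at least 2 cells per subgroup")
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

.row_vars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1)
}

#' Filter an ICG table
#'
#' Removes rows with too few cells in either subgroup, too high an adjusted
#' p-value, too small an absolute log2 fold change, or too low expression
#' in both subgroups.
#'
#' @param table Result of [find_icg()].
#' @param min_cells Minimum `n_with` and `n_without` (default 0).
#' @param min_fdr Maximum adjusted p-value (default 1).
#' @param min_log2fc Minimum `|log2fc|` (default 0).
#' @param min_expr Minimum of `max(mean_with, mean_without)` (default 0).
#' @return The filtered table, with the number of rows removed per
#'   criterion recorded in the `"filter_counts"` attribute.
#' @export
filter_icg <- function(table, min_cells = 0, min_fdr = 1, min_log2fc = 0,
                       min_expr = 0) {
  if (nrow(table) == 0) stop("empty ICG table")
  ok_cells <- table$n_with >= min_cells & table$n_without >= min_cells
  ok_fdr <- table$adjusted_p <= min_fdr
  ok_fc <- abs(table$log2fc) >= min_log2fc
  ok_expr <- pmax(table$mean_with, table$mean_without) >= min_expr
  out <- table[ok_cells & ok_fdr & ok_fc & ok_expr, , drop = FALSE]
  attr(out, "filter_counts") <- c(cells = sum(!ok_cells), fdr = sum(!ok_fdr),
                                  log2fc = sum(!ok_fc), expr = sum(!ok_expr))
  rownames(out) <- NULL
  out
}
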