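#' Filter low-quality cells and lowly detected genes
#'
#' Cells with fewer than `min_detected_genes_per_cell` genes at or above the
#' detection threshold are removed first; genes detected in fewer than
#' `min_cells_per_gene` of the surviving cells are removed second. The
#' cells-then-genes order makes the result independent of gene ordering.
#'
#' @param state A `spat_state` with a raw layer.
#' @param detection_threshold A gene counts as detected in a cell when its raw
#'   value is >= this threshold (default 1).
#' @param min_detected_genes_per_cell Minimum detected genes a cell must have.
#' @param min_cells_per_gene Minimum surviving cells a gene must be detected in.
#' @return A new filtered `spat_state` (derived layers are dropped; re-run
#'   normalization after filtering).
#' @export
filter_dataset <- function(state, detection_threshold = 1,
                           min_detected_genes_per_cell = 0,
                           min_cells_per_gene = 0) {
  stopifnot(inherits(state, "spat_state"))
  raw <- state$expr$raw
  if (min_detected_genes_per_cell > nrow(raw))
    stop("min_detected_genes_per_cell (", min_detected_genes_per_cell,
         ") exceeds the number of genes (", nrow(raw), ")")
  det <- raw >= detection_threshold
  keep_cells <- colSums(det) >= min_detected_genes_per_cell
  if (!any(keep_cells))
    stop("all cells removed; lower min_detected_genes_per_cell (",
         min_detected_genes_per_cell, ") or detection_threshold")
  keep_genes <- rowSums(det[, keep_cells, drop = FALSE]) >= min_cells_per_gene
  if (!any(keep_genes))
    stop("all genes removed; lower min_cells_per_gene (", min_cells_per_gene, ")")

  out <- create_spat_state(
    raw[keep_genes, keep_cells, drop = FALSE],
    spat_coords(state)[keep_cells, , drop = FALSE],
    annotations = state$cells[keep_cells,
      setdiff(names(state$cells), c("cell_id", "sdimx", "sdimy", "sdimz")),
      drop = FALSE])
  .log_call(out, "filter_dataset",
            list(detection_threshold = detection_threshold,
                 min_detected_genes_per_cell = min_detected_genes_per_cell,
                 min_cells_per_gene = min_cells_per_gene,
                 n_cells_removed = sum(!keep_cells),
                 n_genes_removed = sum(!keep_genes)))
}

#' Library-size normalization, log transform and optional gene-wise rescaling
#'
#' The normalized layer is
#' `log_base( raw / libsize * scale_factor + log_offset )` computed per cell,
#' where libsize is the cell's total raw count. With `rescale = TRUE` a
#' `scaled` layer of gene-wise z-scores of the normalized values is added
#' (genes with zero variance become all-zero rows).
#'
#' @param state A `spat_state` with a raw layer; all library sizes must be
#'   positive (filter empty cells first).
#' @param scale_factor Target library size (default 6000).
#' @param log_base Logarithm base (default 2).
#' @param log_offset Pseudo-count added before the log (default 1).
#' @param rescale Also compute the scaled (z-score) layer.
#' @return The state with `normalized` (and optionally `scaled`) layers set.
#' @export
normalize_default <- function(state, scale_factor = 6000, log_base = 2,
                              log_offset = 1, rescale = FALSE) {
  stopifnot(inherits(state, "spat_state"))
  raw <- state$expr$raw
  libsize <- colSums(raw)
  if (any(libsize <= 0))
    stop("cells with zero library size present (",
         paste(utils::head(colnames(raw)[libsize <= 0], 5), collapse = ", "),
         "); filter them first")
  norm <- log(sweep(raw, 2, libsize, "/") * scale_factor + log_offset,
              base = log_base)
  state$expr$normalized <- norm
  if (rescale) state$expr$scaled <- .rowwise_zscore(norm)
  .log_call(state, "normalize_default",
            list(scale_factor = scale_factor, log_base = log_base,
                 log_offset = log_offset, rescale = rescale))
}

# gene-wise z-scores; zero-variance rows -> 0
.rowwise_zscore <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

#' Add per-cell and per-gene summary statistics
#'
#' Cells gain `total_counts` and `n_detected_genes`; genes gain
#' `mean_expression` (of the normalized layer if present, else raw) and
#' `detection_fraction` (fraction of cells with raw value >= the detection
#' threshold).
#'
#' @param state A `spat_state`.
#' @param detection_threshold Detection threshold on the raw layer (default 1).
#' @return The state with statistics columns filled in.
#' @export
add_statistics <- function(state, detection_threshold = 1) {
  stopifnot(inherits(state, "spat_state"))
  raw <- state$expr$raw
  det <- raw >= detection_threshold
  state$cells$total_counts <- unname(colSums(raw))
  state$cells$n_detected_genes <- unname(colSums(det))
  state$genes$mean_expression <- unname(rowMeans(.expr_or_raw(state)))
  state$genes$detection_fraction <- unname(rowMeans(det))
  .log_call(state, "add_statistics",
            list(detection_threshold = detection_threshold))
}

#' Regress technical covariates out of the normalized layer
#'
#' Per gene, a linear model of normalized expression on the named covariate
#' columns is fitted (categorical covariates are one-hot encoded with a
#' dropped reference level) and the normalized value is replaced by
#' residual + gene mean, so per-gene means are preserved.
#'
#' @param state A `spat_state` with a normalized layer.
#' @param covariate_names Character vector of cell annotation columns.
#' @return The state with its normalized layer replaced by adjusted values.
#' @export
adjust_for_covariates <- function(state, covariate_names) {
  norm <- get_expression(state, "normalized")
  miss <- setdiff(covariate_names, names(state$cells))
  if (length(miss)) stop("unknown covariate(s): ", paste(miss, collapse = ", "))
  covs <- state$cells[, covariate_names, drop = FALSE]
  for (nm in covariate_names) {
    v <- covs[[nm]]
    if (length(unique(v)) < 2) stop("covariate '", nm, "' is constant across cells")
    if (!is.numeric(v)) {
      if (length(unique(v)) >= nrow(covs))
        stop("covariate '", nm, "' has as many levels as cells")
      covs[[nm]] <- factor(v)
    }
  }
  X <- stats::model.matrix(~ ., data = covs)
  if (qr(X)$rank > ncol(norm)) stop("more covariate parameters than cells")
  fit <- stats::lm.fit(X, t(norm))
  adjusted <- t(as.matrix(fit$residuals)) + rowMeans(norm)
  dimnames(adjusted) <- dimnames(norm)
  state$expr$normalized <- adjusted
  if (!is.null(state$expr$scaled)) state$expr$scaled <- .rowwise_zscore(adjusted)
  .log_call(state, "adjust_for_covariates", list(covariates = covariate_names))
}
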