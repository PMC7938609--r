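#' Central analysis container for spatial expression data
#'
#' A `spat_state` holds a gene-by-cell expression matrix (raw counts plus
#' derived `normalized` and `scaled` layers), per-cell metadata including the
#' centroid coordinates, per-gene metadata, and any spatial networks, spatial
#' grids and analysis result tables derived from them. All toolkit functions
#' take and return this container.
#'
#' @param raw Numeric matrix, genes x cells, finite and non-negative, with
#'   unique rownames (gene ids) and colnames (cell ids).
#' @param coords Numeric matrix or data.frame of cell centroid positions with
#'   2 or 3 columns (x, y and optionally z), one row per cell, in the same
#'   order as the columns of `raw`. Units are arbitrary length units
#'   (e.g. pixels or micrometers).
#' @param annotations Optional data.frame of per-cell annotation columns
#'   (e.g. cell type labels), one row per cell in matching order.
#' @return An object of class `spat_state`.
#' @examples
#' m <- matrix(rpois(20, 3), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
#' xy <- cbind(x = runif(5), y = runif(5))
#' s <- create_spat_state(m, xy)
#' s
#' @export
create_spat_state <- function(raw, coords, annotations = NULL) {
  raw <- as.matrix(raw)
  if (is.null(rownames(raw)) || is.null(colnames(raw)))
    stop("raw matrix must carry gene ids as rownames and cell ids as colnames")
  if (anyDuplicated(rownames(raw))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(raw))) stop("duplicate cell ids")
  if (!all(is.finite(raw)) || any(raw < 0))
    stop("raw layer must contain only finite non-negative values")

  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != ncol(raw))
    stop("unmatched cell ids: coordinate table has ", nrow(coords),
         " rows but expression matrix has ", ncol(raw), " cells")
  if (!all(is.finite(coords))) stop("non-numeric or non-finite coordinates")
  ndim <- ncol(coords)
  if (!ndim %in% c(2L, 3L)) stop("coordinates must have 2 or 3 dimensions")
  colnames(coords) <- c("sdimx", "sdimy", "sdimz")[seq_len(ndim)]

  cells <- data.frame(cell_id = colnames(raw), coords,
                      row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    if (nrow(annotations) != ncol(raw))
      stop("annotations must have one row per cell")
    annotations$cell_id <- NULL
    cells <- cbind(cells, annotations)
  }
  genes <- data.frame(gene_id = rownames(raw),
                      row.names = NULL, stringsAsFactors = FALSE)

  structure(list(
    expr = list(raw = raw, normalized = NULL, scaled = NULL),
    cells = cells,
    genes = genes,
    networks = list(),
    grids = list(),
    results = list(),
    log = list()
  ), class = "spat_state")
}

#' Retrieve an expression layer
#'
#' @param state A `spat_state`.
#' @param values Layer name: `"normalized"`, `"raw"` or `"scaled"`.
#' @return Genes x cells numeric matrix.
#' @export
get_expression <- function(state, values = c("normalized", "raw", "scaled")) {
  stopifnot(inherits(state, "spat_state"))
  values <- match.arg(values)
  m <- state$expr[[values]]
  if (is.null(m)) stop("layer '", values, "' not present; run the ",
                       switch(values, normalized = "normalize_default()",
                              scaled = "normalize_default(rescale = TRUE)",
                              "constructor"), " step first")
  m
}

# default expression layer for analyses: normalized if present, else raw
.expr_or_raw <- function(state) {
  if (!is.null(state$expr$normalized)) state$expr$normalized else state$expr$raw
}

#' Cell centroid coordinates
#' @param state A `spat_state`.
#' @return Numeric matrix, cells x 2 (or 3), rownames = cell ids.
#' @export
spat_coords <- function(state) {
  stopifnot(inherits(state, "spat_state"))
  cols <- intersect(c("sdimx", "sdimy", "sdimz"), names(state$cells))
  m <- as.matrix(state$cells[, cols, drop = FALSE])
  rownames(m) <- state$cells$cell_id
  m
}

# append one entry to the parameter log
.log_call <- function(state, what, params) {
  state$log[[length(state$log) + 1L]] <- c(list(step = what), params)
  state
}

#' @export
print.spat_state <- function(x, ...) {
  cat("spat_state:", nrow(x$expr$raw), "genes x", ncol(x$expr$raw), "cells\n")
  lay <- names(Filter(Negate(is.null), x$expr))
  cat("  layers:", paste(lay, collapse = ", "), "\n")
  ndim <- sum(c("sdimx", "sdimy", "sdimz") %in% names(x$cells))
  cat("  spatial dimensions:", ndim, "\n")
  ann <- setdiff(names(x$cells), c("cell_id", "sdimx", "sdimy", "sdimz"))
  if (length(ann)) cat("  cell annotations:", paste(ann, collapse = ", "), "\n")
  if (length(x$networks))
    cat("  spatial networks:", paste(names(x$networks), collapse = ", "), "\n")
  if (length(x$grids))
    cat("  spatial grids:", paste(names(x$grids), collapse = ", "), "\n")
  if (length(x$results))
    cat("  results:", paste(names(x$results), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spat_state <- function(x) dim(x$expr$raw)

#' @export
summary.spat_state <- function(object, ...) {
  print(object)
  cat("  total counts:", sum(object$expr$raw), "\n")
  invisible(object)
}

# internal consistency check used by tests and after structural edits
.validate_state <- function(state) {
  stopifnot(inherits(state, "spat_state"))
  r <- state$expr$raw
  stopifnot(identical(state$cells$cell_id, colnames(r)),
            identical(state$genes$gene_id, rownames(r)))
  for (nm in c("normalized", "scaled")) {
    l <- state$expr[[nm]]
    if (!is.null(l)) stopifnot(identical(dimnames(l), dimnames(r)))
  }
  for (net in state$networks)
    stopifnot(all(c(net$edges$cell_a, net$edges$cell_b) %in% state$cells$cell_id))
  invisible(TRUE)
}
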