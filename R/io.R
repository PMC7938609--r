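#' Read an expression matrix and cell coordinates into a spat_state
#'
#' Two on-disk layouts are supported. `format = "tsv"` expects a dense
#' tab-separated matrix with genes as rows, a header of cell ids, and gene ids
#' in the first column. `format = "mtx"` expects a Matrix Market triplet file
#' with `genes.tsv` and `barcodes.tsv` sidecar files (one id per line) in the
#' same directory, following the conventional 10x-style layout.
#'
#' @param matrix_path Path to the matrix file.
#' @param coords_path Path to a TSV with header `cell_id`, `x`, `y` (and
#'   optionally `z`).
#' @param format `"tsv"` or `"mtx"`.
#' @param annotations_path Optional TSV of per-cell annotations keyed by a
#'   `cell_id` column.
#' @return A `spat_state` with the raw layer populated.
#' @export
read_inputs <- function(matrix_path, coords_path, format = c("tsv", "mtx"),
                        annotations_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  if (!file.exists(coords_path)) stop("coordinate file not found: ", coords_path)

  if (format == "tsv") {
    tab <- utils::read.delim(matrix_path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    raw <- as.matrix(tab[, -1, drop = FALSE])
    rownames(raw) <- as.character(tab[[1]])
  } else {
    raw <- as.matrix(Matrix::readMM(matrix_path))
    dir <- dirname(matrix_path)
    gpath <- file.path(dir, "genes.tsv")
    bpath <- file.path(dir, "barcodes.tsv")
    if (!file.exists(gpath) || !file.exists(bpath))
      stop("mtx format requires genes.tsv and barcodes.tsv sidecars in ", dir)
    rownames(raw) <- readLines(gpath)
    colnames(raw) <- readLines(bpath)
  }
  if (anyDuplicated(rownames(raw))) stop("duplicate gene ids in matrix")
  if (anyDuplicated(colnames(raw))) stop("duplicate cell ids in matrix")

  co <- utils::read.delim(coords_path, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(co)) stop("coordinate table must have a cell_id column")
  axis_cols <- intersect(c("x", "y", "z"), names(co))
  if (length(axis_cols) < 2) stop("coordinate table needs at least x and y columns")
  if (!all(vapply(co[axis_cols], is.numeric, logical(1))))
    stop("non-numeric coordinates")
  if (anyDuplicated(co$cell_id)) stop("duplicate cell ids in coordinates")
  if (!setequal(co$cell_id, colnames(raw)))
    stop("unmatched cell ids between expression matrix and coordinates")
  co <- co[match(colnames(raw), co$cell_id), , drop = FALSE]

  ann <- NULL
  if (!is.null(annotations_path)) {
    ann <- utils::read.delim(annotations_path, stringsAsFactors = FALSE)
    if (!"cell_id" %in% names(ann)) stop("annotation table must have a cell_id column")
    if (!all(colnames(raw) %in% ann$cell_id))
      stop("annotation table missing cells")
    ann <- ann[match(colnames(raw), ann$cell_id), , drop = FALSE]
  }
  create_spat_state(raw, co[, axis_cols, drop = FALSE], annotations = ann)
}

#' Read cell-type marker gene sets
#'
#' Accepts either a GMT file (one set per line: name, description, genes,
#' tab-separated) or a two-column TSV with header `cell_type`, `gene`.
#'
#' @param path File path.
#' @param format `"auto"`, `"gmt"` or `"tsv"`.
#' @return Named list mapping cell type to character vector of gene ids
#'   (duplicates removed).
#' @export
read_signatures <- function(path, format = c("auto", "gmt", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  if (format == "gmt") {
    if (requireNamespace("fgsea", quietly = TRUE)) {
      sets <- fgsea::gmtPathways(path)
    } else {
      lines <- strsplit(readLines(path), "\t", fixed = TRUE)
      sets <- lapply(lines, function(x) x[-(1:2)])
      names(sets) <- vapply(lines, `[`, character(1), 1L)
    }
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    sets <- split(as.character(tab[[2]]), tab[[1]])
  }
  lapply(sets, unique)
}

#' Read a ligand-receptor pair table
#'
#' @param path TSV with columns `ligand` and `receptor` (e.g. a FANTOM5
#'   export).
#' @return data.frame with unique (ligand, receptor) rows.
#' @export
read_lr_pairs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(tab)))
    stop("ligand-receptor table must have 'ligand' and 'receptor' columns")
  unique(tab[, c("ligand", "receptor")])
}

#' Serialize a spat_state to a directory of TSV files plus a JSON manifest
#'
#' Layers are written as dense TSVs, cell and gene metadata as TSVs, networks
#' as edge tables, and a `manifest.json` records layer names, the parameter
#' log and the package version, sufficient to replay a run.
#'
#' @param state A `spat_state`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_state <- function(state, dir) {
  stopifnot(inherits(state, "spat_state"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_matrix_tsv <- function(m, path) {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  layers <- names(Filter(Negate(is.null), state$expr))
  for (nm in layers)
    .write_matrix_tsv(state$expr[[nm]], file.path(dir, paste0(nm, ".tsv")))
  utils::write.table(state$cells, file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(state$genes, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(state$networks))
    utils::write.table(state$networks[[nm]]$edges,
                       file.path(dir, paste0("network_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(state$results)) {
    r <- state$results[[nm]]
    if (is.data.frame(r))
      utils::write.table(r, file.path(dir, paste0("result_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package = "spatkit",
    version = as.character(utils::packageVersion("spatkit")),
    layers = layers,
    networks = names(state$networks),
    results = names(state$results),
    log = state$log
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Load a spat_state previously written with [write_state()]
#'
#' @param dir Directory produced by [write_state()].
#' @return A `spat_state`.
#' @export
read_state <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  .read_matrix_tsv <- function(path) {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
    m
  }
  cells <- utils::read.delim(file.path(dir, "cells.tsv"), stringsAsFactors = FALSE)
  raw <- .read_matrix_tsv(file.path(dir, "raw.tsv"))
  axis_cols <- intersect(c("sdimx", "sdimy", "sdimz"), names(cells))
  ann_cols <- setdiff(names(cells), c("cell_id", axis_cols))
  state <- create_spat_state(raw, cells[, axis_cols, drop = FALSE],
                             annotations = cells[, ann_cols, drop = FALSE])
  for (nm in setdiff(unlist(man$layers), "raw"))
    state$expr[[nm]] <- .read_matrix_tsv(file.path(dir, paste0(nm, ".tsv")))
  for (nm in unlist(man$networks)) {
    edges <- utils::read.delim(file.path(dir, paste0("network_", nm, ".tsv")),
                               stringsAsFactors = FALSE)
    state$networks[[nm]] <- structure(list(edges = edges, parameters = list()),
                                      class = "spat_network")
  }
  state$log <- man$log
  state
}
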