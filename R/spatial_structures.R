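#' Spatial grid over cell centroids
#'
#' Partitions the bounding region of the centroids into boxes of the given
#' step sizes, anchored at the minimum coordinate of each axis. Boxes are
#' half-open on the high side except the last box on each axis, which is
#' closed so the maximum coordinate maps into it; every cell therefore maps
#' to exactly one box. Expression is aggregated per box by averaging
#' (this module's convention; see [coarse_grain_spots()] for the summing
#' variant used to emulate spot data).
#'
#' @param state A `spat_state` with coordinates.
#' @param step_x,step_y Box widths along x and y (> 0).
#' @param step_z Optional box width along z for 3D data.
#' @param values Expression layer to aggregate (default normalized if
#'   present, else raw).
#' @param name Name under which to store the grid in the state.
#' @return The state with a `spat_grid` appended under `grids`. The grid
#'   holds `breaks` (per-axis break points), `box_id` (per cell),
#'   `aggregated` (genes x boxes mean-expression matrix) and `empty`
#'   (logical per box).
#' @export
create_spatial_grid <- function(state, step_x, step_y, step_z = NULL,
                                values = NULL, name = "grid") {
  stopifnot(inherits(state, "spat_state"))
  co <- spat_coords(state)
  steps <- c(step_x, step_y, step_z)[seq_len(ncol(co))]
  if (length(steps) < ncol(co)) stop("step_z required for 3D coordinates")
  if (any(steps <= 0)) stop("grid steps must be positive")
  expr <- if (is.null(values)) .expr_or_raw(state)
          else get_expression(state, values)

  axes <- lapply(seq_len(ncol(co)), function(d) {
    lo <- min(co[, d]); hi <- max(co[, d])
    # the top box is closed, so an exact-multiple maximum falls into the
    # last box via the clamp below
    nb <- max(1L, as.integer(ceiling((hi - lo) / steps[d])))
    list(breaks = lo + steps[d] * (0:nb), n = nb)
  })
  idx <- vapply(seq_len(ncol(co)), function(d) {
    i <- as.integer(floor((co[, d] - axes[[d]]$breaks[1]) / steps[d])) + 1L
    pmin(pmax(i, 1L), axes[[d]]$n)   # closed top box
  }, integer(nrow(co)))
  dims <- vapply(axes, `[[`, integer(1), "n")
  box_id <- as.integer(idx[, 1])
  mult <- 1L
  for (d in seq_len(ncol(co))[-1]) {
    mult <- mult * dims[d - 1]
    box_id <- box_id + (idx[, d] - 1L) * mult
  }
  n_boxes <- prod(dims)
  counts <- tabulate(box_id, nbins = n_boxes)
  agg <- matrix(0, nrow(expr), n_boxes,
                dimnames = list(rownames(expr),
                                paste0("box_", seq_len(n_boxes))))
  ind <- Matrix::sparseMatrix(i = box_id, j = seq_along(box_id),
                              x = 1, dims = c(n_boxes, length(box_id)))
  sums <- as.matrix(Matrix::tcrossprod(expr, ind))
  nonempty <- counts > 0
  agg[, nonempty] <- sweep(sums[, nonempty, drop = FALSE], 2,
                           counts[nonempty], "/")
  grid <- structure(list(
    breaks = lapply(axes, `[[`, "breaks"),
    dims = dims,
    box_id = stats::setNames(box_id, state$cells$cell_id),
    counts = counts,
    aggregated = agg,
    empty = !nonempty,
    parameters = list(steps = steps, values = values)
  ), class = "spat_grid")
  state$grids[[name]] <- grid
  .log_call(state, "create_spatial_grid", list(name = name, steps = steps))
}

# construct a spat_network from an index-pair edge list
.make_network <- function(state, a, b, parameters,
                          weight_mode = c("binary", "inverse_distance")) {
  weight_mode <- match.arg(weight_mode)
  co <- spat_coords(state)
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- lo * (nrow(co) + 1) + hi
  first <- !duplicated(key)
  lo <- lo[first]; hi <- hi[first]
  o <- order(lo, hi)
  lo <- lo[o]; hi <- hi[o]
  d <- sqrt(rowSums((co[lo, , drop = FALSE] - co[hi, , drop = FALSE])^2))
  edges <- data.frame(
    cell_a = state$cells$cell_id[lo],
    cell_b = state$cells$cell_id[hi],
    idx_a = lo, idx_b = hi,
    distance = d,
    weight = if (weight_mode == "binary") rep(1, length(d)) else 1 / (1 + d),
    stringsAsFactors = FALSE)
  structure(list(edges = edges, parameters = parameters),
            class = "spat_network")
}

#' @export
print.spat_network <- function(x, ...) {
  cat("spat_network (", x$parameters$method, "): ", nrow(x$edges),
      " edges over ", length(unique(c(x$edges$cell_a, x$edges$cell_b))),
      " cells\n", sep = "")
  invisible(x)
}

#' Delaunay spatial network
#'
#' Connects neighboring cells through the edges of the Delaunay
#' triangulation of their centroids (2D). Optionally removes edges longer
#' than `max_dist`. Edge weights are binary (1).
#'
#' @param state A `spat_state` with 2D coordinates (for 3D data use
#'   [create_knn_network()]).
#' @param max_dist Optional maximum edge length.
#' @param name Name under which to store the network.
#' @return The state with the network appended under `networks`.
#' @export
create_delaunay_network <- function(state, max_dist = NULL,
                                    name = "delaunay") {
  co <- spat_coords(state)
  if (ncol(co) != 2)
    stop("Delaunay networks are 2D only; use create_knn_network for 3D data")
  dup <- duplicated(co)
  if (any(dup))
    stop("duplicate coordinates for cells: ",
         paste(utils::head(state$cells$cell_id[dup], 5), collapse = ", "))
  if (qr(sweep(co, 2, colMeans(co)))$rank < 2)
    stop("all points are collinear; Delaunay triangulation undefined - ",
         "use create_knn_network instead")
  dd <- deldir::deldir(co[, 1], co[, 2])
  a <- dd$delsgs$ind1
  b <- dd$delsgs$ind2
  net <- .make_network(state, a, b,
                       parameters = list(method = "delaunay",
                                         max_dist = max_dist))
  if (!is.null(max_dist))
    net$edges <- net$edges[net$edges$distance <= max_dist, , drop = FALSE]
  state$networks[[name]] <- net
  .log_call(state, "create_delaunay_network",
            list(name = name, max_dist = max_dist,
                 n_edges = nrow(net$edges)))
}

#' k-nearest-neighbor spatial network
#'
#' Each cell is connected to its k nearest neighbors by Euclidean distance;
#' the directed relation is symmetrized into an undirected edge set. With
#' `max_dist`, longer edges are removed, except that every cell always
#' retains its `min_k` nearest edges regardless of distance.
#'
#' @param state A `spat_state` (2D or 3D coordinates).
#' @param k Number of neighbors (default 4; clamped to #cells - 1 with a
#'   warning).
#' @param max_dist Optional maximum edge length.
#' @param min_k Number of nearest edges each cell keeps regardless of
#'   `max_dist` (default 0; must not exceed `k`).
#' @param weight_mode `"binary"` (weight 1) or `"inverse_distance"`
#'   (weight 1/(1+d)).
#' @param name Name under which to store the network.
#' @return The state with the network appended under `networks`.
#' @export
create_knn_network <- function(state, k = 4, max_dist = NULL, min_k = 0,
                               weight_mode = c("binary", "inverse_distance"),
                               name = "knn") {
  weight_mode <- match.arg(weight_mode)
  co <- spat_coords(state)
  n <- nrow(co)
  if (k < 1) stop("k must be >= 1")
  if (min_k > k) stop("min_k must not exceed k")
  if (k >= n) {
    warning("k clamped to #cells - 1 = ", n - 1L)
    k <- n - 1L
  }
  nn <- .knn_indices(co, k)
  from <- rep(seq_len(n), each = k)
  to <- as.vector(t(nn))
  rank_in_list <- rep(seq_len(k), times = n)
  net <- .make_network(state, from, to,
                       parameters = list(method = "knn", k = k,
                                         max_dist = max_dist, min_k = min_k),
                       weight_mode = weight_mode)
  if (!is.null(max_dist)) {
    keep <- net$edges$distance <= max_dist
    if (min_k > 0) {
      # protected pairs: each cell's min_k nearest directed edges
      prot <- rank_in_list <= min_k
      pl <- pmin(from, to)[prot]; ph <- pmax(from, to)[prot]
      pkey <- paste(pl, ph)
      ekey <- paste(net$edges$idx_a, net$edges$idx_b)
      keep <- keep | ekey %in% pkey
    }
    net$edges <- net$edges[keep, , drop = FALSE]
  }
  state$networks[[name]] <- net
  .log_call(state, "create_knn_network",
            list(name = name, k = k, max_dist = max_dist, min_k = min_k,
                 weight_mode = weight_mode, n_edges = nrow(net$edges)))
}

#' Export a spatial network as a TSV edge table
#' @param network A `spat_network`.
#' @param path Output file.
#' @export
write_network <- function(network, path) {
  utils::write.table(
    network$edges[, c("cell_a", "cell_b", "distance", "weight")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# neighbor list (by cell index) from a network; returns list of integer
# vectors, one per cell
.adjacency_list <- function(network, n_cells) {
  e <- network$edges
  nbr <- vector("list", n_cells)
  idx <- c(e$idx_a, e$idx_b)
  val <- c(e$idx_b, e$idx_a)
  sp <- split(val, idx)
  nbr[as.integer(names(sp))] <- sp
  nbr[vapply(nbr, is.null, logical(1))] <- list(integer(0))
  nbr
}
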