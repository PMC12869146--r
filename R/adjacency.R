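#' Adjacency matrices for areal data
#'
#' The neighbourhood graph of the lattice: a symmetric, zero-diagonal binary
#' relation over areas, stored as a set of unordered index pairs. It carries
#' the i ~ j relation of the intrinsic conditional autoregressive (ICAR)
#' prior.
#'
#' @param n_areas number of areas.
#' @param pairs two-column integer matrix of neighbour pairs (1-based area
#'   indices); order within a pair and duplicate pairs are normalized away.
#' @param area_ids optional character vector of area ids (length `n_areas`).
#' @return an object of class `adjacency_matrix` with elements `n_areas`,
#'   `pairs` (i < j, one row per unordered pair), `degrees`, `area_ids`.
#' @export
adjacency_matrix <- function(n_areas, pairs, area_ids = NULL) {
  n_areas <- as.integer(n_areas)
  if (n_areas < 1) abort("`n_areas` must be >= 1")
  if (is.null(pairs) || length(pairs) == 0) {
    pairs <- matrix(integer(0), ncol = 2)
  }
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (any(pairs < 1 | pairs > n_areas)) abort("pair indices out of range")
  if (any(pairs[, 1] == pairs[, 2])) abort("self-neighbours are not allowed")
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  degrees <- tabulate(c(pairs[, 1], pairs[, 2]), nbins = n_areas)
  if (!is.null(area_ids)) {
    area_ids <- as.character(area_ids)
    if (length(area_ids) != n_areas) abort("`area_ids` length mismatch")
  }
  structure(list(n_areas = n_areas, pairs = pairs, degrees = degrees,
                 area_ids = area_ids),
            class = "adjacency_matrix")
}

#' @export
print.adjacency_matrix <- function(x, ...) {
  cat(sprintf("<adjacency_matrix> %d areas, %d neighbour pairs\n",
              x$n_areas, nrow(x$pairs)))
  invisible(x)
}

#' Queen-contiguity adjacency from polygons
#'
#' Two areas are neighbours iff their polygon boundaries share at least one
#' point — a stretch of common edge or a single corner (queen rule, as
#' opposed to rook contiguity which requires a shared edge). Sharing is
#' assessed within a small distance `tolerance`, because serialization
#' round-trips (e.g. via GeoJSON) can perturb coordinates.
#'
#' @param lattice an [area_lattice].
#' @param tolerance nonnegative distance (coordinate units) within which two
#'   boundary points are considered identical. Default 1e-9.
#' @return an [adjacency_matrix] over the lattice's areas, in lattice order.
#' @export
#' @examples
#' lat <- generate_grid_lattice(2, 2, seed = 1)
#' queen_adjacency(lat)$pairs  # complete graph on 4 cells
queen_adjacency <- function(lattice, tolerance = 1e-9) {
  if (!inherits(lattice, "area_lattice")) abort("`lattice` must be an area_lattice")
  if (!is.numeric(tolerance) || tolerance < 0) abort("`tolerance` must be >= 0")
  ids <- lattice$areas$area_id
  n <- length(ids)
  for (id in ids) validate_ring(lattice$polygons[[id]], id)
  rings <- lattice$polygons[ids]
  # bounding-box prefilter
  bb <- t(vapply(rings, function(r) c(min(r[, 1]), max(r[, 1]),
                                      min(r[, 2]), max(r[, 2])),
                 numeric(4)))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    js <- which(seq_len(n) > i &
                  bb[, 1] <= bb[i, 2] + tolerance &
                  bb[, 2] >= bb[i, 1] - tolerance &
                  bb[, 3] <= bb[i, 4] + tolerance &
                  bb[, 4] >= bb[i, 3] - tolerance)
    hits <- js[vapply(js, function(j) {
      boundaries_touch(rings[[i]], rings[[j]], tolerance)
    }, logical(1))]
    if (length(hits)) out[[i]] <- cbind(i, hits)
  }
  pairs <- do.call(rbind, out)
  adjacency_matrix(n, pairs, area_ids = ids)
}

# boundaries share a point iff some vertex of one ring lies on (within tol of)
# the other ring's boundary; covers shared edges, corners and T-junctions of
# a planar partition (proper crossings would mean overlapping areas)
boundaries_touch <- function(ring_a, ring_b, tol) {
  min_vertex_boundary_dist(ring_a, ring_b) <= tol ||
    min_vertex_boundary_dist(ring_b, ring_a) <= tol
}

# smallest distance from any vertex of `ring_p` to the boundary of `ring_q`
min_vertex_boundary_dist <- function(ring_p, ring_q) {
  px <- ring_p[-nrow(ring_p), 1]; py <- ring_p[-nrow(ring_p), 2]
  ax <- ring_q[-nrow(ring_q), 1]; ay <- ring_q[-nrow(ring_q), 2]
  bx <- ring_q[-1, 1];            by <- ring_q[-1, 2]
  dmin <- Inf
  for (s in seq_along(ax)) {
    vx <- bx[s] - ax[s]; vy <- by[s] - ay[s]
    len2 <- vx * vx + vy * vy
    t <- if (len2 == 0) rep(0, length(px)) else
      pmax(0, pmin(1, ((px - ax[s]) * vx + (py - ay[s]) * vy) / len2))
    dx <- px - (ax[s] + t * vx); dy <- py - (ay[s] + t * vy)
    dmin <- min(dmin, sqrt(min(dx * dx + dy * dy)))
  }
  dmin
}

#' Connected components of an adjacency graph
#'
#' Component labels are needed because the ICAR prior is improper: the
#' structured effect is only identified up to a constant shift within each
#' connected component, and the sum-to-zero constraint is imposed per
#' component. Isolated areas form singleton components.
#'
#' @param adjacency an [adjacency_matrix].
#' @return list with `label` (integer component id per area, 1-based,
#'   consecutive) and `n_components`.
#' @export
connected_components <- function(adjacency) {
  stopifnot(inherits(adjacency, "adjacency_matrix"))
  g <- igraph::make_empty_graph(n = adjacency$n_areas, directed = FALSE)
  if (nrow(adjacency$pairs) > 0) {
    g <- igraph::add_edges(g, t(adjacency$pairs))
  }
  comp <- igraph::components(g)
  list(label = as.integer(comp$membership), n_components = comp$no)
}

# proper vertex colouring (greedy); colour classes are conditionally
# independent sets, used to vectorize single-site Metropolis updates
colour_classes <- function(adjacency) {
  n <- adjacency$n_areas
  nb <- vector("list", n)
  for (r in seq_len(nrow(adjacency$pairs))) {
    i <- adjacency$pairs[r, 1]; j <- adjacency$pairs[r, 2]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  col <- integer(n)
  for (i in order(-adjacency$degrees)) {
    used <- col[nb[[i]]]
    col[i] <- min(setdiff(seq_len(n), used[used > 0]))
  }
  split(seq_len(n), col)
}

# dense / sparse matrix views
adjacency_to_sparse <- function(adjacency) {
  p <- adjacency$pairs
  Matrix::sparseMatrix(i = c(p[, 1], p[, 2]), j = c(p[, 2], p[, 1]),
                       x = 1, dims = c(adjacency$n_areas, adjacency$n_areas))
}

#' Edge-list input/output
#'
#' The adjacency is serialized as a two-column CSV of 0-based area indices
#' (`from`, `to`), one row per unordered pair; `write_adjacency_mtx` writes
#' the symmetric binary matrix in Matrix Market coordinate format.
#'
#' @param adjacency an [adjacency_matrix].
#' @param path file path.
#' @param n_areas number of areas (needed on read: isolated areas do not
#'   appear in the edge list).
#' @return the written path (invisibly), or the read [adjacency_matrix].
#' @export
write_edge_list <- function(adjacency, path) {
  df <- data.frame(from = adjacency$pairs[, 1] - 1L,
                   to = adjacency$pairs[, 2] - 1L)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path, n_areas) {
  df <- utils::read.csv(path)
  adjacency_matrix(n_areas, cbind(df$from + 1L, df$to + 1L))
}

#' @rdname write_edge_list
#' @export
write_adjacency_mtx <- function(adjacency, path) {
  Matrix::writeMM(adjacency_to_sparse(adjacency), path)
  invisible(path)
}
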