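#' Area lattices
#'
#' An `area_lattice` is the spatial frame of the analysis: a set of small
#' areas (the role played by ZIP-code tabulation areas in claims studies),
#' each with an identifier, a planar polygon, a resident population, and a
#' rurality class (`city`, `suburban_town`, or `rural`; `NA` is tolerated for
#' areas whose class is unknown in real data, though the generator always
#' assigns one).
#'
#' @param areas data.frame with columns `area_id` (character, unique),
#'   `population` (integer >= 1) and `rurality`.
#' @param polygons named list (names = area ids) of closed rings: numeric
#'   matrices with columns x, y whose last vertex repeats the first.
#' @return an object of class `area_lattice`: a list with elements `areas`
#'   (the data.frame) and `polygons`.
#' @export
area_lattice <- function(areas, polygons) {
  required <- c("area_id", "population", "rurality")
  if (!is.data.frame(areas) || !all(required %in% names(areas))) {
    abort("`areas` must be a data.frame with columns %s",
          paste(required, collapse = ", "))
  }
  areas$area_id <- as.character(areas$area_id)
  if (anyDuplicated(areas$area_id)) abort("area ids must be unique")
  if (any(!is.finite(areas$population)) || any(areas$population < 1)) {
    abort("populations must be >= 1")
  }
  areas$population <- as.numeric(areas$population)
  bad_rur <- !(areas$rurality %in% rurality_classes() | is.na(areas$rurality))
  if (any(bad_rur)) {
    abort("unknown rurality class(es): %s",
          paste(unique(areas$rurality[bad_rur]), collapse = ", "))
  }
  if (!is.list(polygons) || !setequal(names(polygons), areas$area_id)) {
    abort("`polygons` must be a list named by the area ids")
  }
  for (id in areas$area_id) {
    ring <- polygons[[id]]
    validate_ring(ring, id)
  }
  structure(list(areas = areas[, required],
                 polygons = polygons[areas$area_id]),
            class = "area_lattice")
}

#' @export
print.area_lattice <- function(x, ...) {
  tab <- table(factor(x$areas$rurality, levels = rurality_classes()),
               useNA = "ifany")
  cat(sprintf("<area_lattice> %d areas (%s)\n", nrow(x$areas),
              paste(sprintf("%s: %d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}

#' @rdname area_lattice
#' @export
rurality_classes <- function() c("city", "suburban_town", "rural")

n_areas <- function(lattice) nrow(lattice$areas)

# a ring must be a closed, non-self-intersecting polygon
validate_ring <- function(ring, id) {
  if (!is.matrix(ring) || ncol(ring) != 2 || nrow(ring) < 4 ||
      !all(is.finite(ring))) {
    abort("polygon for area '%s' must be a numeric matrix (>= 4 rows, 2 cols)",
          id)
  }
  if (any(ring[1, ] != ring[nrow(ring), ])) {
    abort("polygon for area '%s' is not closed (first vertex must repeat last)",
          id)
  }
  if (ring_self_intersects(ring)) {
    abort("polygon for area '%s' is self-intersecting", id)
  }
  invisible(TRUE)
}

# proper-crossing test between non-adjacent edges; O(k^2), rings are small
ring_self_intersects <- function(ring) {
  k <- nrow(ring) - 1L
  if (k < 4) return(FALSE)
  for (i in seq_len(k - 2L)) {
    jmax <- if (i == 1L) k - 1L else k
    for (j in (i + 2L):jmax) {
      if (segments_cross(ring[i, ], ring[i + 1L, ], ring[j, ], ring[j + 1L, ]))
        return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Generate a rectangular grid lattice
#'
#' Tiles an `n_rows` x `n_cols` rectangle with unit-square areas, assigns
#' populations uniformly from `population_range`, and assigns rurality by a
#' deterministic row-banding rule: rows are split into three equal bands,
#' top-to-bottom `city`, `suburban_town`, `rural` (so all three classes occur
#' whenever `n_rows >= 3`; with fewer rows only the leading bands occur).
#'
#' @param n_rows,n_cols positive integers, grid dimensions.
#' @param seed integer seed for the population draw.
#' @param population_range length-2 integer vector, min/max area population.
#' @return an [area_lattice].
#' @export
#' @examples
#' lat <- generate_grid_lattice(3, 3, seed = 7)
#' table(lat$areas$rurality)
generate_grid_lattice <- function(n_rows, n_cols, seed,
                                  population_range = c(500L, 5000L)) {
  if (!is.numeric(n_rows) || !is.numeric(n_cols) ||
      n_rows < 1 || n_cols < 1 ||
      n_rows != round(n_rows) || n_cols != round(n_cols)) {
    abort("`n_rows` and `n_cols` must be positive integers")
  }
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (length(population_range) != 2 || population_range[1] < 1 ||
      population_range[2] < population_range[1]) {
    abort("`population_range` must be c(min, max) with 1 <= min <= max")
  }
  n <- n_rows * n_cols
  row_idx <- rep(seq_len(n_rows), each = n_cols)
  col_idx <- rep(seq_len(n_cols), times = n_rows)
  ids <- sprintf("A%04d", seq_len(n))
  band <- pmin(floor((row_idx - 1L) * 3 / n_rows) + 1L, 3L)
  rurality <- rurality_classes()[band]
  pops <- with_seed(seed, {
    sample(seq.int(population_range[1], population_range[2]), n, replace = TRUE)
  })
  polys <- vector("list", n)
  names(polys) <- ids
  for (i in seq_len(n)) {
    x0 <- col_idx[i] - 1; y0 <- n_rows - row_idx[i]  # row 1 at the top
    polys[[i]] <- cbind(x = c(x0, x0 + 1, x0 + 1, x0, x0),
                        y = c(y0, y0, y0 + 1, y0 + 1, y0))
  }
  area_lattice(data.frame(area_id = ids, population = pops,
                          rurality = rurality, stringsAsFactors = FALSE),
               polys)
}

#' Write / read an area lattice as GeoJSON
#'
#' The lattice is serialized as a GeoJSON FeatureCollection of Polygon
#' features with `area_id`, `population` and `rurality` properties, in planar
#' coordinates.
#'
#' @param lattice an [area_lattice].
#' @param path file path.
#' @return `write_lattice_geojson` returns `path` invisibly;
#'   `read_lattice_geojson` returns an [area_lattice].
#' @export
write_lattice_geojson <- function(lattice, path) {
  feats <- lapply(seq_len(n_areas(lattice)), function(i) {
    id <- lattice$areas$area_id[i]
    ring <- lattice$polygons[[id]]
    list(
      type = "Feature",
      properties = list(area_id = id,
                        population = lattice$areas$population[i],
                        rurality = lattice$areas$rurality[i]),
      geometry = list(type = "Polygon",
                      coordinates = list(unname(apply(ring, 1, c,
                                                      simplify = FALSE))))
    )
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lattice_geojson
#' @export
read_lattice_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) {
    abort("'%s' is not a GeoJSON FeatureCollection", path)
  }
  feats <- fc$features
  areas <- data.frame(
    area_id = vapply(feats, function(f) as.character(f$properties$area_id), ""),
    population = vapply(feats, function(f) as.numeric(f$properties$population), 0),
    rurality = vapply(feats, function(f) {
      r <- f$properties$rurality
      if (is.null(r)) NA_character_ else as.character(r)
    }, ""),
    stringsAsFactors = FALSE
  )
  polys <- lapply(feats, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(pt) as.numeric(unlist(pt))))
    colnames(m) <- c("x", "y")
    m
  })
  names(polys) <- areas$area_id
  area_lattice(areas, polys)
}
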