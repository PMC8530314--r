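#' Construct a protected-site polygon
#'
#' Geometry is one or more simple outer rings (no holes) in grid coordinates
#' (km, equal-area plane). Multi-part sites are given as a list of rings.
#'
#' @param site_id character scalar, unique site identifier.
#' @param rings an `n x 2` coordinate matrix, or a list of such matrices
#'   (vertices in order, ring closure implied; do not repeat the first point).
#' @param is_marine logical flag; marine sites are excluded from the analysis.
#' @param biogeo_region,admin_region optional categorical labels.
#' @param validate check ring validity (>= 3 vertices, positive area, simple);
#'   an invalid geometry raises an error naming the site.
#' @return An object of class `site_polygon`.
#' @export
site_polygon <- function(site_id, rings, is_marine = FALSE,
                         biogeo_region = NA_character_,
                         admin_region = NA_character_, validate = TRUE) {
  if (is.matrix(rings)) rings <- list(rings)
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    storage.mode(r) <- "double"
    r
  })
  if (validate) {
    for (r in rings) {
      if (nrow(r) < 3 || ncol(r) != 2 || anyNA(r))
        stop(sprintf("invalid geometry for site '%s'", site_id))
      if (abs(ring_signed_area(r)) <= 0)
        stop(sprintf("invalid geometry for site '%s': zero area ring", site_id))
      if (ring_self_intersects(r))
        stop(sprintf("invalid geometry for site '%s': self-intersecting ring", site_id))
    }
  }
  structure(list(site_id = as.character(site_id), rings = rings,
                 is_marine = isTRUE(is_marine),
                 biogeo_region = as.character(biogeo_region),
                 admin_region = as.character(admin_region)),
            class = "site_polygon")
}

ring_signed_area <- function(r) {
  n <- nrow(r)
  j <- c(n, seq_len(n - 1))
  sum(r[j, 1] * r[, 2] - r[, 1] * r[j, 2]) / 2
}

ring_self_intersects <- function(r) {
  n <- nrow(r)
  if (n < 4) return(FALSE)
  p1 <- r
  p2 <- r[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    js <- seq(i + 2, jmax)
    if (length(js) == 0) next
    if (any(segments_intersect(p1[i, ], p2[i, ], p1[js, , drop = FALSE],
                               p2[js, , drop = FALSE]))) return(TRUE)
  }
  FALSE
}

segments_intersect <- function(a1, a2, b1, b2) {
  # proper intersection test, vectorized over rows of b1/b2
  d1x <- a2[1] - a1[1]; d1y <- a2[2] - a1[2]
  o1 <- d1x * (b1[, 2] - a1[2]) - d1y * (b1[, 1] - a1[1])
  o2 <- d1x * (b2[, 2] - a1[2]) - d1y * (b2[, 1] - a1[1])
  d2x <- b2[, 1] - b1[, 1]; d2y <- b2[, 2] - b1[, 2]
  o3 <- d2x * (a1[2] - b1[, 2]) - d2y * (a1[1] - b1[, 1])
  o4 <- d2x * (a2[2] - b1[, 2]) - d2y * (a2[1] - b1[, 1])
  (o1 * o2 < 0) & (o3 * o4 < 0)
}

#' Polygon area (km2)
#' @param poly a `site_polygon`.
#' @export
polygon_area <- function(poly) sum(vapply(poly$rings, function(r) abs(ring_signed_area(r)), 0))

polygon_bbox <- function(poly) {
  xs <- unlist(lapply(poly$rings, function(r) r[, 1]))
  ys <- unlist(lapply(poly$rings, function(r) r[, 2]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

#' Point-in-polygon test (closed rule)
#'
#' Points on the polygon boundary count as covered: the deterministic
#' tie-break used for cell-center rasterization throughout the package.
#'
#' @param poly a `site_polygon`.
#' @param x,y point coordinates (km).
#' @return logical vector.
#' @export
polygon_contains <- function(poly, x, y) {
  points_in_rings_cpp(as.numeric(x), as.numeric(y), poly$rings)
}

#' Euclidean distance from points to a polygon (0 inside)
#' @param poly a `site_polygon`.
#' @param x,y point coordinates (km).
#' @return numeric vector of distances (km).
#' @export
polygon_distance <- function(poly, x, y) {
  dist_to_rings_cpp(as.numeric(x), as.numeric(y), poly$rings)
}

#' Reporting cells covered by a polygon (cell-center rule)
#'
#' A cell is covered exactly when its center point lies inside the polygon or
#' on its boundary. Small or elongated polygons may cover no center, in which
#' case an empty set is returned (such sites are excluded downstream).
#'
#' @param poly a `site_polygon`.
#' @param grid a `grid_spec`.
#' @return integer vector of covered cell ids (possibly empty), sorted.
#' @export
cells_covered_by_polygon <- function(poly, grid) {
  bb <- polygon_bbox(poly)
  cand <- cells_in_bbox(grid, bb)
  if (nrow(cand) == 0) return(integer(0))
  keep <- polygon_contains(poly, cand$x, cand$y)
  sort(cand$cell[keep])
}

cells_in_bbox <- function(grid, bb, pad = 0) {
  cs <- grid$cell_size
  col0 <- max(1L, as.integer(floor((bb["xmin"] - pad - grid$origin_x) / cs - 0.5)) + 1L)
  col1 <- min(grid$n_cols, as.integer(ceiling((bb["xmax"] + pad - grid$origin_x) / cs + 0.5)))
  row0 <- max(1L, as.integer(floor((bb["ymin"] - pad - grid$origin_y) / cs - 0.5)) + 1L)
  row1 <- min(grid$n_rows, as.integer(ceiling((bb["ymax"] + pad - grid$origin_y) / cs + 0.5)))
  if (col0 > col1 || row0 > row1)
    return(data.frame(cell = integer(0), row = integer(0), col = integer(0),
                      x = numeric(0), y = numeric(0)))
  rows <- rep(row0:row1, each = col1 - col0 + 1L)
  cols <- rep(col0:col1, times = row1 - row0 + 1L)
  cells <- (rows - 1L) * grid$n_cols + cols
  data.frame(cell = cells, row = rows, col = cols,
             x = grid$origin_x + (cols - 0.5) * cs,
             y = grid$origin_y + (rows - 0.5) * cs)
}

#' Buffer ring (annulus) around a site
#'
#' The Euclidean buffer of the site geometry minus the site itself. The ring
#' is represented by its exact membership predicate: a point belongs to the
#' ring iff its distance to the site is positive and at most `distance_km`.
#' This is the exact buffer; no polygonal approximation is involved. Rings
#' around multi-part sites may merge into one connected annulus.
#'
#' @param poly a `site_polygon`.
#' @param distance_km buffer distance in km (> 0, default 5).
#' @return An object of class `buffer_ring`.
#' @export
buffer_ring <- function(poly, distance_km = 5) {
  if (!is.numeric(distance_km) || length(distance_km) != 1 || distance_km <= 0)
    stop("buffer distance must be a positive number of km")
  structure(list(site = poly, distance_km = as.numeric(distance_km)),
            class = "buffer_ring")
}

#' Ring membership test
#' @param ring a `buffer_ring`.
#' @param x,y point coordinates (km).
#' @return logical vector: inside the annulus (outside the site, within the
#'   buffer distance).
#' @export
ring_contains <- function(ring, x, y) {
  d <- polygon_distance(ring$site, x, y)
  d > 0 & d <= ring$distance_km
}

#' Numeric ring area (km2)
#'
#' Integrates the ring membership predicate on a square lattice of spacing
#' `resolution` km over the buffered bounding box. For convex sites the
#' result approaches the closed form `P * d + pi * d^2` (perimeter P,
#' distance d) as the resolution is refined.
#'
#' @param ring a `buffer_ring`.
#' @param resolution lattice spacing in km (default 0.05).
#' @export
ring_area <- function(ring, resolution = 0.05) {
  bb <- polygon_bbox(ring$site)
  d <- ring$distance_km
  xs <- seq(bb["xmin"] - d - resolution / 2, bb["xmax"] + d + resolution / 2,
            by = resolution)
  ys <- seq(bb["ymin"] - d - resolution / 2, bb["ymax"] + d + resolution / 2,
            by = resolution)
  total <- 0
  for (yv in ys) { # row-wise to bound memory on large sites
    total <- total + sum(ring_contains(ring, xs, rep(yv, length(xs))))
  }
  total * resolution^2
}
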