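# Planar/spherical geometry helpers shared across modules.
#
# All user-facing coordinates are WGS84 decimal degrees. Internally the
# synthetic city and the spatial indexes work on a local equirectangular
# projection anchored at a declared WGS84 point; at the <= 50 m scales used
# here the projection error is negligible, and every distance that feeds a
# threshold decision is exact-refined with the haversine formula.

EARTH_RADIUS_M <- 6371008.8 # WGS84 mean radius

#' Great-circle distance between points
#'
#' Haversine distance on the WGS84 mean-radius sphere, vectorised and
#' recycled over the longer input.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Distances in metres.
#' @export
haversine_m <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lon2))
  if (n == 0) return(numeric(0))
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_M)
}

#' Local equirectangular projection
#'
#' Projects WGS84 coordinates to metric x/y around an anchor point
#' (`local_project()`) and back (`local_unproject()`). Used by the
#' synthetic-city generator and by the spatial index of
#' [find_path_crossings()]; threshold decisions are always refined with
#' [haversine_m()].
#'
#' @param lon,lat Coordinates in decimal degrees.
#' @param x,y Metric coordinates relative to the anchor.
#' @param anchor Numeric `c(lon, lat)` anchor of the projection.
#' @return A tibble with columns `x`,`y` (or `lon`,`lat`).
#' @export
local_project <- function(lon, lat, anchor) {
  k <- pi / 180 * EARTH_RADIUS_M
  tibble::tibble(
    x = (lon - anchor[1]) * k * cos(anchor[2] * pi / 180),
    y = (lat - anchor[2]) * k
  )
}

#' @rdname local_project
#' @export
local_unproject <- function(x, y, anchor) {
  k <- pi / 180 * EARTH_RADIUS_M
  tibble::tibble(
    lon = anchor[1] + x / (k * cos(anchor[2] * pi / 180)),
    lat = anchor[2] + y / k
  )
}

# Even-odd ray-casting containment test for one polygon ring.
# `ring` is a two-column matrix (first column = horizontal coordinate).
# Boundary points count as inside (closed polygons).
point_in_ring <- function(px, py, ring) {
  n <- length(px)
  if (n == 0) return(logical(0))
  rx <- ring[, 1]; ry <- ring[, 2]
  m <- length(rx)
  if (m > 1 && rx[1] == rx[m] && ry[1] == ry[m]) { # drop duplicated closure
    rx <- rx[-m]; ry <- ry[-m]; m <- m - 1
  }
  inside <- logical(n)
  on_edge <- logical(n)
  j <- m
  for (i in seq_len(m)) {
    xi <- rx[i]; yi <- ry[i]; xj <- rx[j]; yj <- ry[j]
    # boundary check: point on segment (i, j)
    dx <- xj - xi; dy <- yj - yi
    seg_len2 <- dx * dx + dy * dy
    if (seg_len2 > 0) {
      tt <- pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / seg_len2))
      d2 <- (xi + tt * dx - px)^2 + (yi + tt * dy - py)^2
    } else {
      d2 <- (px - xi)^2 + (py - yi)^2
    }
    on_edge <- on_edge | d2 <= 1e-18
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

# Vectorised shortest distance (same planar units) from points to a
# polyline given as a two-column matrix of vertices.
dist_points_to_polyline <- function(px, py, line) {
  n <- length(px)
  if (n == 0) return(numeric(0))
  best <- rep(Inf, n)
  for (i in seq_len(nrow(line) - 1)) {
    xi <- line[i, 1]; yi <- line[i, 2]
    dx <- line[i + 1, 1] - xi; dy <- line[i + 1, 2] - yi
    seg_len2 <- dx * dx + dy * dy
    if (seg_len2 == 0) {
      d2 <- (px - xi)^2 + (py - yi)^2
    } else {
      tt <- pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / seg_len2))
      d2 <- (xi + tt * dx - px)^2 + (yi + tt * dy - py)^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# Shortest distance from points to a polygon ring boundary; 0 for points
# inside the ring.
dist_points_to_polygon <- function(px, py, ring) {
  if (nrow(ring) > 1 && (ring[1, 1] != ring[nrow(ring), 1] ||
                         ring[1, 2] != ring[nrow(ring), 2])) {
    ring <- rbind(ring, ring[1, , drop = FALSE])
  }
  d <- dist_points_to_polyline(px, py, ring)
  d[point_in_ring(px, py, ring)] <- 0
  d
}

# Shoelace area (planar units^2) of one ring.
polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  m <- length(x)
  if (m > 1 && x[1] == x[m] && y[1] == y[m]) { x <- x[-m]; y <- y[-m]; m <- m - 1 }
  if (m < 3) return(0)
  j <- c(m, seq_len(m - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Vertex-average centroid of one ring (adequate for the convex/rectangular
# polygons produced and consumed here).
polygon_centroid <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  m <- length(x)
  if (m > 1 && x[1] == x[m] && y[1] == y[m]) { x <- x[-m]; y <- y[-m] }
  c(mean(x), mean(y))
}

# Axis-aligned rectangle ring.
rect_ring <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

# Clip a convex polygon ring by the half-plane a*x + b*y <= c
# (Sutherland-Hodgman step). Returns a matrix, possibly with 0 rows.
clip_halfplane <- function(ring, a, b, cc) {
  m <- nrow(ring)
  out_x <- numeric(0); out_y <- numeric(0)
  f <- a * ring[, 1] + b * ring[, 2] - cc
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    pi_in <- f[i] <= 0; pj_in <- f[j] <= 0
    if (pi_in) { out_x <- c(out_x, ring[i, 1]); out_y <- c(out_y, ring[i, 2]) }
    if (pi_in != pj_in) {
      tt <- f[i] / (f[i] - f[j])
      out_x <- c(out_x, ring[i, 1] + tt * (ring[j, 1] - ring[i, 1]))
      out_y <- c(out_y, ring[i, 2] + tt * (ring[j, 2] - ring[i, 2]))
    }
  }
  cbind(out_x, out_y)
}

# Voronoi cells of `seeds` (two-column matrix) clipped to the rectangle
# [0,w] x [0,h], via half-plane intersection (O(K^2), fine for <= a few
# hundred tracts). Returns a list of rings in seed order; cells partition
# the rectangle.
voronoi_cells <- function(seeds, w, h) {
  k <- nrow(seeds)
  lapply(seq_len(k), function(i) {
    ring <- rect_ring(0, 0, w, h)
    for (j in seq_len(k)) {
      if (j == i || nrow(ring) == 0) next
      # keep points closer to seed i than seed j: bisector half-plane
      a <- 2 * (seeds[j, 1] - seeds[i, 1])
      b <- 2 * (seeds[j, 2] - seeds[i, 2])
      cc <- sum(seeds[j, ]^2) - sum(seeds[i, ]^2)
      ring <- clip_halfplane(ring, a, b, cc)
    }
    ring
  })
}
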