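# Spatial layers: tibbles of polygon/polyline features with GeoJSON I/O.
#
# A layer is a tibble with columns
#   id        feature id, unique within the layer
#   kind      "tract", "poi", "hub", "road" or "rail"
#   naics     optional NAICS category code (POIs/hubs)
#   target_ses optional synthetic venue target SES
#   geom_type "polygon" or "line"
#   geometry  list of two-column (lon, lat) matrices; polygon rings are
#             stored unclosed and treated as closed

LAYER_KINDS <- c("tract", "poi", "hub", "road", "rail")

new_layer <- function(id, kind, geometry, geom_type,
                      naics = NA_character_, target_ses = NA_real_) {
  tibble::tibble(
    id = as.character(id), kind = kind, naics = naics,
    target_ses = target_ses, geom_type = geom_type, geometry = geometry
  )
}

#' Validate a spatial layer
#'
#' Checks id uniqueness and polygon validity (at least three vertices,
#' non-zero area, no self-intersection for the simple rings used here).
#' Invalid features raise an error naming the feature id.
#'
#' @param layer A layer tibble (see [read_layer_geojson()]).
#' @return The layer, invisibly, if valid.
#' @export
validate_layer <- function(layer) {
  if (anyDuplicated(layer$id)) {
    stop("duplicate feature ids in layer: ",
         paste(unique(layer$id[duplicated(layer$id)]), collapse = ", "))
  }
  polys <- which(layer$geom_type == "polygon")
  for (i in polys) {
    ring <- layer$geometry[[i]]
    if (!is.matrix(ring) || nrow(ring) < 3 || polygon_area(ring) <= 0) {
      stop("invalid polygon for feature id ", layer$id[i],
           ": need >= 3 vertices and non-zero area")
    }
    if (ring_self_intersects(ring)) {
      stop("invalid polygon for feature id ", layer$id[i],
           ": ring is self-intersecting")
    }
  }
  invisible(layer)
}

# Segment-pair self-intersection scan; adjacent segments share a vertex and
# are skipped. O(m^2), rings here have few vertices.
ring_self_intersects <- function(ring) {
  m <- nrow(ring)
  if (m > 1 && all(ring[1, ] == ring[m, ])) { ring <- ring[-m, , drop = FALSE]; m <- m - 1 }
  if (m < 4) return(FALSE)
  seg <- function(i) list(p = ring[i, ], q = ring[if (i == m) 1L else i + 1L, ])
  cross2 <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  for (i in seq_len(m - 2)) {
    si <- seg(i)
    jmax <- if (i == 1) m - 1 else m
    for (j in (i + 2):jmax) {
      sj <- seg(j)
      d1 <- cross2(si$p, si$q, sj$p); d2 <- cross2(si$p, si$q, sj$q)
      d3 <- cross2(sj$p, sj$q, si$p); d4 <- cross2(sj$p, sj$q, si$q)
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Read and write spatial layers as GeoJSON
#'
#' `read_layer_geojson()` parses a GeoJSON FeatureCollection of Polygon and
#' LineString features with properties `id`, `kind` (one of tract, poi, hub,
#' road, rail) and optional `naics` and `target_ses`. Features with an
#' unknown `kind` are skipped with a warning; invalid polygons raise an
#' error naming the feature id. `write_layer_geojson()` is the inverse.
#'
#' @param path File path.
#' @param layer A layer tibble.
#' @return `read_layer_geojson()` returns a layer tibble;
#'   `write_layer_geojson()` returns `path` invisibly.
#' @export
read_layer_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection in ", path)
  }
  rows <- purrr::map(gj$features, function(ft) {
    props <- ft$properties
    kind <- props$kind
    if (is.null(kind) || !kind %in% LAYER_KINDS) {
      warning("skipping feature with unknown kind: ",
              if (is.null(kind)) "<missing>" else kind, call. = FALSE)
      return(NULL)
    }
    gtype <- ft$geometry$type
    if (gtype == "Polygon") {
      coords <- ft$geometry$coordinates[[1]]
      geom_type <- "polygon"
    } else if (gtype == "LineString") {
      coords <- ft$geometry$coordinates
      geom_type <- "line"
    } else {
      warning("skipping unsupported geometry type: ", gtype, call. = FALSE)
      return(NULL)
    }
    mat <- do.call(rbind, purrr::map(coords, ~ c(.x[[1]], .x[[2]])))
    if (geom_type == "polygon" && nrow(mat) > 1 &&
        all(mat[1, ] == mat[nrow(mat), ])) {
      mat <- mat[-nrow(mat), , drop = FALSE]
    }
    new_layer(
      id = props$id, kind = kind, geometry = list(mat), geom_type = geom_type,
      naics = props$naics %||% NA_character_,
      target_ses = as.numeric(props$target_ses %||% NA_real_)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) validate_layer(out)
  out
}

#' @rdname read_layer_geojson
#' @export
write_layer_geojson <- function(layer, path) {
  features <- purrr::pmap(layer, function(id, kind, naics, target_ses,
                                          geom_type, geometry, ...) {
    coords <- purrr::map(seq_len(nrow(geometry)),
                         ~ c(geometry[.x, 1], geometry[.x, 2]))
    if (geom_type == "polygon") {
      coords <- c(coords, coords[1]) # close the ring
      geom <- list(type = "Polygon", coordinates = list(coords))
    } else {
      geom <- list(type = "LineString", coordinates = coords)
    }
    props <- list(id = id, kind = kind)
    if (!is.na(naics)) props$naics <- naics
    if (!is.na(target_ses)) props$target_ses <- target_ses
    list(type = "Feature", properties = props, geometry = geom)
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features), path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

# Containment of points in a layer's polygons, resolving overlaps by the
# smallest containing polygon. Returns the matched feature id (NA if none)
# for each point. Coordinates and rings share the same (lon/lat) system;
# at these scales the degree-space test agrees with the metric one.
match_smallest_polygon <- function(lon, lat, layer) {
  polys <- layer[layer$geom_type == "polygon", ]
  n <- length(lon)
  out <- rep(NA_character_, n)
  if (nrow(polys) == 0 || n == 0) return(out)
  areas <- vapply(polys$geometry, polygon_area, numeric(1))
  best_area <- rep(Inf, n)
  for (i in order(areas)) {
    ring <- polys$geometry[[i]]
    # cheap bounding-box prefilter
    cand <- which(lon >= min(ring[, 1]) & lon <= max(ring[, 1]) &
                  lat >= min(ring[, 2]) & lat <= max(ring[, 2]) &
                  !(best_area <= areas[i]))
    if (!length(cand)) next
    hit <- cand[point_in_ring(lon[cand], lat[cand], ring)]
    take <- hit[best_area[hit] > areas[i]]
    out[take] <- polys$id[i]
    best_area[take] <- areas[i]
  }
  out
}
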