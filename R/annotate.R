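# Spatial-context annotation of exposure edges. All annotations use the
# exposure midpoint (the edge's lat/lon); boundary points count as inside.

#' Flag exposures at either endpoint's home
#'
#' Sets `at_home_i` / `at_home_j` when the exposure point lies within
#' `radius_m` of that endpoint's home location. Endpoints without a home
#' get `NA` with a message.
#'
#' @param edges Edge tibble from [find_path_crossings()].
#' @param individuals Tibble with `user_id`, `home_lat`, `home_lon`.
#' @param radius_m At-home radius in metres (default 50).
#' @return `edges` with logical `at_home_i`, `at_home_j`.
#' @export
annotate_home <- function(edges, individuals, radius_m = 50) {
  at_home_for <- function(ids) {
    idx <- match(ids, individuals$user_id)
    if (anyNA(idx)) {
      message(sum(is.na(idx)), " edge endpoint(s) without an inferred home")
    }
    d <- haversine_m(edges$lon, edges$lat,
                     individuals$home_lon[idx], individuals$home_lat[idx])
    d <= radius_m
  }
  dplyr::mutate(edges, at_home_i = at_home_for(edges$user_i),
                at_home_j = at_home_for(edges$user_j))
}

#' Classify exposures by home-tract component
#'
#' Labels each exposure by how many of the two endpoints were inside their
#' own home census tract at the time of the exposure:
#' `both_in_home_tract`, `one_in_home_tract` or `neither_in_home_tract`.
#' Exposures outside all tracts are `neither_in_home_tract` (counted as
#' out-of-region in a message).
#'
#' @param edges Edge tibble.
#' @param individuals Tibble with `user_id`, `home_tract_id`.
#' @param tract_layer Tract layer tibble.
#' @return `edges` with a `component` factor column.
#' @export
classify_component <- function(edges, individuals, tract_layer) {
  tract_at <- match_smallest_polygon(edges$lon, edges$lat, tract_layer)
  if (anyNA(tract_at)) {
    message(sum(is.na(tract_at)), " exposure(s) outside all tracts")
  }
  home_of <- function(ids) {
    individuals$home_tract_id[match(ids, individuals$user_id)]
  }
  n_in <- (!is.na(tract_at) & tract_at == home_of(edges$user_i)) +
    (!is.na(tract_at) & tract_at == home_of(edges$user_j))
  dplyr::mutate(edges, component = factor(
    c("neither_in_home_tract", "one_in_home_tract",
      "both_in_home_tract")[n_in + 1],
    levels = c("both_in_home_tract", "one_in_home_tract",
               "neither_in_home_tract")))
}

#' Annotate exposures with POI and hub polygons
#'
#' Sets `poi_id` (+ `poi_category`, the NAICS code) or `hub_id` when the
#' exposure point lies inside a polygon of the layer; overlapping polygons
#' resolve to the smallest containing one. A POI nested inside a hub yields
#' both annotations.
#'
#' @param edges Edge tibble.
#' @param poi_layer,hub_layer Layer tibbles (validated at load).
#' @return `edges` with the annotation columns added.
#' @export
annotate_poi <- function(edges, poi_layer) {
  validate_layer(poi_layer)
  ids <- match_smallest_polygon(edges$lon, edges$lat, poi_layer)
  dplyr::mutate(edges, poi_id = ids,
                poi_category = poi_layer$naics[match(ids, poi_layer$id)])
}

#' @rdname annotate_poi
#' @export
annotate_hub <- function(edges, hub_layer) {
  validate_layer(hub_layer)
  dplyr::mutate(edges,
                hub_id = match_smallest_polygon(edges$lon, edges$lat,
                                                hub_layer))
}

#' Flag exposures near linear features
#'
#' Sets `near_road` when the exposure point lies within `buffer_m` of any
#' polyline in the layer (roads/railways).
#'
#' @param edges Edge tibble.
#' @param line_layer Layer tibble with `geom_type == "line"` features.
#' @param buffer_m Buffer distance in metres (default 20).
#' @return `edges` with a logical `near_road` column.
#' @export
annotate_linear <- function(edges, line_layer, buffer_m = 20) {
  lines <- line_layer[line_layer$geom_type == "line", ]
  if (nrow(lines) == 0 || nrow(edges) == 0) {
    return(dplyr::mutate(edges, near_road = rep(FALSE, nrow(edges))))
  }
  anchor <- c(mean(edges$lon), mean(edges$lat))
  pt <- local_project(edges$lon, edges$lat, anchor)
  best <- rep(Inf, nrow(edges))
  for (g in lines$geometry) {
    ll <- local_project(g[, 1], g[, 2], anchor)
    best <- pmin(best, dist_points_to_polyline(pt$x, pt$y,
                                               cbind(ll$x, ll$y)))
  }
  dplyr::mutate(edges, near_road = best <= buffer_m)
}

#' Annotate an edge table with all spatial context at once
#'
#' Convenience wrapper chaining [annotate_home()], [classify_component()],
#' [annotate_poi()], [annotate_hub()] and (when a line layer is given)
#' [annotate_linear()]. Annotations are idempotent and order-invariant.
#'
#' @param edges Edge tibble.
#' @param individuals Individual tibble with homes and home tracts.
#' @param tract_layer,poi_layer,hub_layer,line_layer Layer tibbles
#'   (`line_layer` optional).
#' @return The annotated edge tibble.
#' @export
annotate_exposures <- function(edges, individuals, tract_layer, poi_layer,
                               hub_layer, line_layer = NULL) {
  edges <- annotate_home(edges, individuals)
  edges <- classify_component(edges, individuals, tract_layer)
  edges <- annotate_poi(edges, poi_layer)
  edges <- annotate_hub(edges, hub_layer)
  if (!is.null(line_layer)) edges <- annotate_linear(edges, line_layer)
  edges
}

#' Hub coverage of exposures and land area
#'
#' Computes the fraction of exposures occurring within `radius_m` of a hub
#' polygon and the fraction of the region's land area within the same
#' buffer (Monte-Carlo estimate over the region polygon, with its standard
#' error).
#'
#' @param edges Edge tibble.
#' @param hub_layer Hub layer tibble (empty layer gives fractions 0).
#' @param radius_m Buffer radius in metres (default 1000).
#' @param region_ring Two-column (lon, lat) matrix of the region polygon.
#' @param n_mc Monte-Carlo sample size for the land-area fraction.
#' @param seed Seed for the Monte-Carlo draw.
#' @return Tibble `exposure_fraction`, `land_fraction`, `land_fraction_se`.
#' @export
hub_coverage_stats <- function(edges, hub_layer, radius_m = 1000,
                               region_ring, n_mc = 20000, seed = 1) {
  hubs <- hub_layer[hub_layer$geom_type == "polygon", ]
  if (nrow(hubs) == 0) {
    return(tibble::tibble(exposure_fraction = 0, land_fraction = 0,
                          land_fraction_se = 0))
  }
  anchor <- polygon_centroid(region_ring)
  hub_rings <- lapply(hubs$geometry, function(g) {
    ll <- local_project(g[, 1], g[, 2], anchor)
    cbind(ll$x, ll$y)
  })
  near_any_hub <- function(x, y) {
    best <- rep(Inf, length(x))
    for (r in hub_rings) best <- pmin(best, dist_points_to_polygon(x, y, r))
    best <= radius_m
  }
  pe <- local_project(edges$lon, edges$lat, anchor)
  exposure_fraction <- if (nrow(edges)) mean(near_any_hub(pe$x, pe$y)) else 0

  rr <- local_project(region_ring[, 1], region_ring[, 2], anchor)
  ring <- cbind(rr$x, rr$y)
  set.seed(seed)
  px <- runif(n_mc, min(ring[, 1]), max(ring[, 1]))
  py <- runif(n_mc, min(ring[, 2]), max(ring[, 2]))
  in_region <- point_in_ring(px, py, ring)
  hit <- near_any_hub(px[in_region], py[in_region])
  p <- mean(hit)
  tibble::tibble(exposure_fraction = exposure_fraction, land_fraction = p,
                 land_fraction_se = sqrt(p * (1 - p) / sum(in_region)))
}
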