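#' Link inferred homes to the nearest registry property
#'
#' Each individual is linked to the nearest property in the registry
#' (great-circle distance); individuals whose nearest property lies farther
#' than `max_link_distance_m` are dropped, mirroring the 100 m home-to-
#' property quality filter. SES is the linked property's monthly rent.
#'
#' @param individuals Tibble with `user_id`, `home_lat`, `home_lon`.
#' @param registry Tibble with `property_id`, `lat`, `lon`,
#'   `rent_usd_month`.
#' @param max_link_distance_m Link cutoff in metres (default 100; the
#'   boundary value is kept).
#' @return `individuals` with `property_id`, `ses` (USD/month) and
#'   `link_distance_m`; unlinked rows are dropped.
#' @export
link_ses <- function(individuals, registry, max_link_distance_m = 100) {
  if (is.null(registry) || nrow(registry) == 0) {
    stop("property registry is empty; cannot link SES")
  }
  n <- nrow(individuals)
  if (n == 0) {
    return(dplyr::mutate(individuals, property_id = character(0),
                         ses = numeric(0), link_distance_m = numeric(0)))
  }
  nearest <- nearest_point_index(individuals$home_lon, individuals$home_lat,
                                 registry$lon, registry$lat)
  d <- haversine_m(individuals$home_lon, individuals$home_lat,
                   registry$lon[nearest], registry$lat[nearest])
  out <- dplyr::mutate(individuals,
                       property_id = registry$property_id[nearest],
                       ses = registry$rent_usd_month[nearest],
                       link_distance_m = d)
  dplyr::filter(out, .data$link_distance_m <= max_link_distance_m)
}

# Nearest-neighbour indices via a planar equirectangular approximation in
# chunks (exact at the <= city scales used here for selecting the nearest
# point; the reported distance is recomputed with haversine).
nearest_point_index <- function(qlon, qlat, rlon, rlat) {
  anchor <- c(mean(rlon), mean(rlat))
  q <- local_project(qlon, qlat, anchor)
  r <- local_project(rlon, rlat, anchor)
  out <- integer(length(qlon))
  chunk <- max(1L, floor(2e7 / length(rlon)))
  for (s in seq(1, length(qlon), by = chunk)) {
    e <- min(s + chunk - 1L, length(qlon))
    d2 <- outer(q$x[s:e], r$x, "-")^2 + outer(q$y[s:e], r$y, "-")^2
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Winsorize SES at an upper cap
#'
#' Caps monthly rents at `cap` (no lower winsorization), guarding the
#' correlation estimates against a handful of extreme rents.
#'
#' @param individuals Tibble with an `ses` column, or a bare numeric
#'   vector.
#' @param cap Upper cap in USD/month (default 20000).
#' @return Same shape as the input with `ses <- pmin(ses, cap)`.
#' @export
winsorize_ses <- function(individuals, cap = 20000) {
  if (is.numeric(individuals)) return(pmin(individuals, cap))
  dplyr::mutate(individuals, ses = pmin(.data$ses, cap))
}

#' Alternative SES measures
#'
#' `"percentile"` replaces rent with its within-region average-rank
#' percentile (ties share the mean rank, scaled to `[0, 100]`, so a single
#' tie group maps to 50). `"cbg_income"` assigns the synthetic block-group
#' (tract) median household income of the home tract.
#'
#' @param individuals Tibble with `ses` (and `home_tract_id` for
#'   `"cbg_income"`).
#' @param mode `"percentile"` or `"cbg_income"`.
#' @param tract_income Tibble `tract_id`, `median_income_usd_year`
#'   (required for `"cbg_income"`).
#' @return `individuals` with an `ses_alt` column.
#' @export
alternative_ses <- function(individuals, mode = c("percentile", "cbg_income"),
                            tract_income = NULL) {
  mode <- tryCatch(match.arg(mode),
                   error = function(e) stop("unknown SES mode: ",
                                            paste(mode, collapse = "/")))
  if (mode == "percentile") {
    r <- rank(individuals$ses, ties.method = "average")
    dplyr::mutate(individuals,
                  ses_alt = 100 * (r - 0.5) / nrow(individuals))
  } else {
    if (is.null(tract_income)) {
      stop("cbg_income mode needs a tract_income table")
    }
    idx <- match(individuals$home_tract_id, tract_income$tract_id)
    dplyr::mutate(individuals,
                  ses_alt = tract_income$median_income_usd_year[idx])
  }
}

#' Quality filters on linked individuals
#'
#' `filter_identical_homes()` removes every individual whose home
#' coordinates are exactly (floating-point) equal to another individual's
#' home — a device-artifact signature. `filter_shared_property()` removes
#' individuals linked to a registry property shared by more than
#' `max_users` individuals.
#'
#' @param individuals Tibble with `home_lat`, `home_lon` (and
#'   `property_id`).
#' @param max_users Occupancy cap per property (default 10).
#' @return The filtered tibble; removed ids in `attr(, "removed")`.
#' @export
filter_identical_homes <- function(individuals) {
  key <- paste(sprintf("%.12f", individuals$home_lat),
               sprintf("%.12f", individuals$home_lon))
  dup_keys <- unique(key[duplicated(key)])
  keep <- !(key %in% dup_keys)
  out <- individuals[keep, ]
  attr(out, "removed") <- individuals$user_id[!keep]
  out
}

#' @rdname filter_identical_homes
#' @export
filter_shared_property <- function(individuals, max_users = 10) {
  occ <- table(individuals$property_id)
  bad <- names(occ)[occ > max_users]
  keep <- !(individuals$property_id %in% bad)
  out <- individuals[keep, ]
  attr(out, "removed") <- individuals$user_id[!keep]
  out
}

#' Assign each individual's home census tract
#'
#' Point-in-polygon of the home location against the tract layer
#' (smallest containing polygon under overlap).
#'
#' @param individuals Tibble with `home_lat`, `home_lon`.
#' @param tract_layer Tract layer tibble.
#' @return `individuals` with a `home_tract_id` column (NA outside all
#'   tracts).
#' @export
assign_home_tract <- function(individuals, tract_layer) {
  dplyr::mutate(individuals, home_tract_id = match_smallest_polygon(
    .data$home_lon, .data$home_lat, tract_layer))
}
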