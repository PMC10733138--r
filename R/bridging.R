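# Bridging index: within-nearest-hub-cluster economic diversity relative
# to the whole region.

#' Gini index of a set of non-negative values
#'
#' Population (uncorrected) Gini: mean absolute pairwise difference divided
#' by twice the mean, computed with the sorted O(n log n) identity
#' `G = 2 * sum(i * x_(i)) / (n * sum(x)) - (n + 1) / n`.
#'
#' @param values Non-negative numeric vector, not all zero.
#' @return Gini index in `[0, 1)`.
#' @export
gini <- function(values) {
  if (length(values) < 1 || anyNA(values)) {
    stop("gini() needs at least one non-missing value")
  }
  if (any(values < 0)) stop("gini() is undefined for negative values")
  s <- sum(values)
  if (s == 0) stop("gini() is undefined when all values are zero")
  n <- length(values)
  x <- sort(values)
  2 * sum(seq_len(n) * x) / (n * s) - (n + 1) / n
}

#' Assign residents to their nearest hub
#'
#' Each individual is assigned to the hub whose centroid minimizes the
#' great-circle distance from their home; ties break towards the smaller
#' hub id.
#'
#' @param individuals Tibble with `home_lat`, `home_lon`.
#' @param hub_layer Hub layer tibble (polygon features; the hub point is
#'   the polygon centroid), or a tibble with `id`, `lon`, `lat` point
#'   columns.
#' @return Character vector of hub ids, one per individual.
#' @export
assign_nearest_hub <- function(individuals, hub_layer) {
  pts <- hub_points(hub_layer)
  if (nrow(pts) == 0) stop("no hubs to cluster on")
  ord <- order(pts$id) # ties resolved towards the smaller hub id
  pts <- pts[ord, ]
  n <- nrow(individuals)
  best_d <- rep(Inf, n); best <- rep(NA_character_, n)
  for (i in seq_len(nrow(pts))) {
    d <- haversine_m(individuals$home_lon, individuals$home_lat,
                     pts$lon[i], pts$lat[i])
    take <- d < best_d
    best[take] <- pts$id[i]; best_d[take] <- d[take]
  }
  best
}

hub_points <- function(hub_layer) {
  if (all(c("lon", "lat", "id") %in% names(hub_layer)) &&
      !"geometry" %in% names(hub_layer)) {
    return(tibble::tibble(id = as.character(hub_layer$id),
                          lon = hub_layer$lon, lat = hub_layer$lat))
  }
  polys <- hub_layer[hub_layer$geom_type == "polygon", ]
  cent <- t(vapply(polys$geometry, polygon_centroid, numeric(2)))
  tibble::tibble(id = polys$id, lon = cent[, 1], lat = cent[, 2])
}

#' Bridging index of a region's hubs
#'
#' Clusters residents by their nearest hub and measures how economically
#' diverse those clusters are relative to the whole region:
#' `sum(|H_i| * div(H_i)) / (|V| * div(V))` with `div` the Gini index (or
#' the variance). 0 means every hub serves an SES-uniform catchment; 1
#' means every catchment mirrors the region-wide SES distribution.
#'
#' @param individuals Tibble with `home_lat`, `home_lon`, `ses` (> 0).
#' @param hub_layer Hub layer (see [assign_nearest_hub()]).
#' @param measure `"gini"` (default) or `"variance"` within-cluster
#'   diversity.
#' @return An object of class `exposeg_bridging`: a list with `index`,
#'   `overall_diversity`, `n_residents`, `measure` and a `clusters` tibble
#'   (`hub_id`, `size`, `diversity`).
#' @export
bridging_index <- function(individuals, hub_layer,
                           measure = c("gini", "variance")) {
  measure <- match.arg(measure)
  if (nrow(individuals) < 2) stop("need >= 2 residents with SES")
  if (any(individuals$ses <= 0)) stop("bridging index needs positive SES")
  div <- if (measure == "gini") gini else function(v) mean((v - mean(v))^2)
  overall <- div(individuals$ses)
  if (overall == 0) {
    stop("overall diversity is zero (all SES equal); bridging index undefined")
  }
  hub <- assign_nearest_hub(individuals, hub_layer)
  clusters <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(hub_id = hub, ses = individuals$ses),
                    .data$hub_id),
    size = dplyr::n(),
    diversity = if (dplyr::n() >= 1) div(.data$ses) else 0,
    .groups = "drop")
  idx <- sum(clusters$size * clusters$diversity) /
    (nrow(individuals) * overall)
  structure(list(index = idx, overall_diversity = overall,
                 n_residents = nrow(individuals), measure = measure,
                 clusters = clusters),
            class = "exposeg_bridging")
}

#' @export
print.exposeg_bridging <- function(x, ...) {
  cat("<exposeg_bridging> index = ", signif(x$index, 4), " (", x$measure,
      "), K = ", nrow(x$clusters), " clusters, ", x$n_residents,
      " residents\n", sep = "")
  invisible(x)
}

#' @rdname bridging_index
#' @param x An `exposeg_bridging` object.
#' @param ... Unused.
#' @export
tidy.exposeg_bridging <- function(x, ...) x$clusters

#' @rdname bridging_index
#' @export
glance.exposeg_bridging <- function(x, ...) {
  tibble::tibble(index = x$index, overall_diversity = x$overall_diversity,
                 n_clusters = nrow(x$clusters), n_residents = x$n_residents,
                 measure = x$measure)
}
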