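#' Generate a synthetic city
#'
#' Lays out tract polygons partitioning the city rectangle, draws each
#' individual's home uniformly over the city, assigns log-normal monthly
#' rents with a tract-level mean shift controlled by
#' `tract_ses_autocorrelation`, places POIs (each with a target SES that
#' drives homophilous venue choice) and hub polygons containing POIs, and
#' emits a property registry with one residential property per home.
#'
#' Hub placement controls the bridging structure of the city: `"bridging"`
#' positions hubs midway between SES-dissimilar tracts (and gives their
#' POIs a city-median target SES), `"embedded"` positions hubs inside
#' tracts spanning the SES range (their POIs inherit the tract's typical
#' rent), `"random"` scatters them uniformly.
#'
#' @param config A [city_config()].
#' @return An object of class `exposeg_city`: a list with `config`,
#'   `individuals` (ground-truth tibble: `user_id`, `true_lat`, `true_lon`,
#'   `true_tract_id`, `true_ses`), `tract_layer`, `poi_layer`, `hub_layer`
#'   (layer tibbles, see [read_layer_geojson()]), `registry` (tibble
#'   `property_id`, `lat`, `lon`, `rent_usd_month`), and `tract_info`
#'   (tibble `tract_id`, `tract_effect`, `median_income_usd_year`).
#' @export
generate_city <- function(config) {
  if (!inherits(config, "city_config")) config <- do.call(city_config, config)
  set.seed(config$seed)
  w <- config$city_width_m; h <- config$city_height_m
  anchor <- config$anchor

  ## tract polygons partitioning the rectangle (metric coords)
  tract_rings <- switch(
    config$tract_layout,
    grid = grid_cells(config$n_tracts, w, h),
    voronoi = voronoi_cells(
      cbind(runif(config$n_tracts, 0, w), runif(config$n_tracts, 0, h)), w, h
    )
  )
  tract_ids <- sprintf("tract%03d", seq_len(config$n_tracts))
  tract_centroids <- t(vapply(tract_rings, polygon_centroid, numeric(2)))

  ## tract-level SES effect: a spatially smooth field (random linear
  ## gradient plus tract noise, standardized across tracts) so the city has
  ## coherent richer and poorer sides, as real SES geographies do
  phi <- runif(1, 0, 2 * pi)
  grad <- (cos(phi) * tract_centroids[, 1] + sin(phi) * tract_centroids[, 2])
  grad <- if (sd(grad) > 0) (grad - mean(grad)) / sd(grad) else grad * 0
  tract_effect <- grad + 0.4 * rnorm(config$n_tracts)
  if (sd(tract_effect) > 0) {
    tract_effect <- (tract_effect - mean(tract_effect)) / sd(tract_effect)
  }

  ## homes: uniform over the rectangle; tract = containing cell
  ux <- runif(config$n_individuals, 0, w)
  uy <- runif(config$n_individuals, 0, h)
  tract_idx <- locate_in_rings(ux, uy, tract_rings)
  if (anyNA(tract_idx)) { # numeric edge cases on shared boundaries
    miss <- which(is.na(tract_idx))
    for (i in miss) {
      d <- (tract_centroids[, 1] - ux[i])^2 + (tract_centroids[, 2] - uy[i])^2
      tract_idx[i] <- which.min(d)
    }
  }

  rho <- config$tract_ses_autocorrelation
  mu <- config$rent_lognormal_mu; sig <- config$rent_lognormal_sigma
  log_rent <- mu + sig * (sqrt(rho) * tract_effect[tract_idx] +
                            sqrt(1 - rho) * rnorm(config$n_individuals))
  rent <- exp(log_rent)

  home_ll <- local_unproject(ux, uy, anchor)
  individuals <- tibble::tibble(
    user_id = sprintf("u%05d", seq_len(config$n_individuals)),
    true_lon = home_ll$lon, true_lat = home_ll$lat,
    true_x = ux, true_y = uy,
    true_tract_id = tract_ids[tract_idx],
    true_ses = rent
  )

  ## hubs
  hub_centers <- place_hubs(config, tract_centroids, tract_effect, w, h)
  half <- config$hub_size_m / 2
  hub_rings <- lapply(seq_len(config$n_hubs), function(i) {
    rect_ring(hub_centers[i, 1] - half, hub_centers[i, 2] - half,
              hub_centers[i, 1] + half, hub_centers[i, 2] + half)
  })

  ## POIs: half inside hubs (>= 1 each), rest standalone
  n_hub_pois <- max(config$n_hubs, floor(config$n_pois / 2))
  n_hub_pois <- min(n_hub_pois, config$n_pois)
  hub_of_poi <- rep(seq_len(config$n_hubs), length.out = n_hub_pois)
  n_free <- config$n_pois - n_hub_pois
  pad <- config$poi_size_m
  poi_cx <- c(hub_centers[hub_of_poi, 1] + runif(n_hub_pois, -half + pad, half - pad),
              runif(n_free, pad, w - pad))
  poi_cy <- c(hub_centers[hub_of_poi, 2] + runif(n_hub_pois, -half + pad, half - pad),
              runif(n_free, pad, h - pad))

  ## venue target SES: what rent level the venue caters to
  hub_target <- switch(
    config$hub_placement,
    bridging = rep(exp(mu), config$n_hubs),
    embedded = exp(mu + sig * sqrt(rho) *
                     tract_effect[attr(hub_centers, "tract_idx")]),
    random = exp(mu + sig * rnorm(config$n_hubs))
  )
  target_ses <- c(hub_target[hub_of_poi], exp(mu + sig * rnorm(n_free)))

  qp <- config$poi_size_m / 2
  poi_rings <- lapply(seq_len(config$n_pois), function(i) {
    rect_ring(poi_cx[i] - qp, poi_cy[i] - qp, poi_cx[i] + qp, poi_cy[i] + qp)
  })
  # a small NAICS vocabulary so activity decomposition has categories
  naics_pool <- c("722511", "722513", "713940", "813110", "711212")
  poi_naics <- sample(naics_pool, config$n_pois, replace = TRUE)

  ring_to_ll <- function(ring) {
    ll <- local_unproject(ring[, 1], ring[, 2], anchor)
    cbind(ll$lon, ll$lat)
  }
  tract_layer <- new_layer(tract_ids, "tract", lapply(tract_rings, ring_to_ll),
                           "polygon")
  poi_layer <- new_layer(sprintf("poi%03d", seq_len(config$n_pois)), "poi",
                         lapply(poi_rings, ring_to_ll), "polygon",
                         naics = poi_naics, target_ses = target_ses)
  hub_layer <- new_layer(sprintf("hub%02d", seq_len(config$n_hubs)), "hub",
                         lapply(hub_rings, ring_to_ll), "polygon",
                         naics = "531120")
  validate_layer(tract_layer); validate_layer(poi_layer); validate_layer(hub_layer)

  registry <- tibble::tibble(
    property_id = sprintf("prop%05d", seq_len(config$n_individuals)),
    lon = individuals$true_lon, lat = individuals$true_lat,
    rent_usd_month = rent
  )

  tract_info <- tibble::tibble(
    tract_id = tract_ids,
    tract_effect = tract_effect,
    # synthetic block-group income: monotone in the tract rent level
    median_income_usd_year = round(12 * exp(mu + sig * sqrt(rho) * tract_effect) * 3)
  )

  structure(
    list(config = config, individuals = individuals,
         tract_layer = tract_layer, poi_layer = poi_layer,
         hub_layer = hub_layer, registry = registry, tract_info = tract_info,
         poi_xy = cbind(poi_cx, poi_cy), hub_xy = hub_centers),
    class = "exposeg_city"
  )
}

#' @export
print.exposeg_city <- function(x, ...) {
  cat("<exposeg_city> ", nrow(x$individuals), " individuals, ",
      nrow(x$tract_layer), " tracts, ", nrow(x$poi_layer), " POIs, ",
      nrow(x$hub_layer), " hubs\n", sep = "")
  invisible(x)
}

# Exact partition of [0,w]x[0,h] into n cells on a near-square grid; rows
# may carry one extra cell so the count is exactly n.
grid_cells <- function(n, w, h) {
  nr <- max(1L, floor(sqrt(n)))
  base <- n %/% nr; extra <- n %% nr
  per_row <- rep(base, nr)
  if (extra > 0) per_row[seq_len(extra)] <- base + 1L
  rings <- list()
  y0 <- 0
  for (r in seq_len(nr)) {
    y1 <- h * r / nr
    nc <- per_row[r]
    xs <- w * (0:nc) / nc
    for (cidx in seq_len(nc)) {
      rings[[length(rings) + 1L]] <- rect_ring(xs[cidx], y0, xs[cidx + 1], y1)
    }
    y0 <- y1
  }
  rings
}

# Index of the ring containing each point (first match in area order).
locate_in_rings <- function(px, py, rings) {
  out <- rep(NA_integer_, length(px))
  for (i in seq_along(rings)) {
    todo <- which(is.na(out))
    if (!length(todo)) break
    hit <- point_in_ring(px[todo], py[todo], rings[[i]])
    out[todo[hit]] <- i
  }
  out
}

# Hub centre placement. Returns an n_hubs x 2 matrix; for "embedded" the
# chosen tract index is attached as attr "tract_idx".
place_hubs <- function(config, tract_centroids, tract_effect, w, h) {
  k <- config$n_hubs
  switch(
    config$hub_placement,
    random = cbind(runif(k, w * 0.1, w * 0.9), runif(k, h * 0.1, h * 0.9)),
    embedded = {
      ord <- order(tract_effect)
      pick <- ord[unique(pmax(1, round(seq(1, length(ord), length.out = k))))]
      pick <- rep(pick, length.out = k)
      out <- tract_centroids[pick, , drop = FALSE]
      attr(out, "tract_idx") <- pick
      out
    },
    bridging = {
      ord <- order(tract_effect)
      lo <- ord[seq_len(k)]
      hi <- rev(ord)[seq_len(k)]
      (tract_centroids[lo, , drop = FALSE] +
         tract_centroids[hi, , drop = FALSE]) / 2
    }
  )
}
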