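# Independent oracles and fixture builders used across the suite. Each
# oracle is a deliberately simple reimplementation, kept separate from the
# package's code paths.

# Textbook haversine, written out from the formula.
oracle_haversine <- function(lon1, lat1, lon2, lat2, R = 6371008.8) {
  to_rad <- pi / 180
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlam / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

# Winding-number point-in-polygon (independent of the package's even-odd
# ray casting). Boundary points are resolved by a tiny outward nudge test,
# so comparisons exclude exact-boundary cases.
oracle_in_polygon <- function(px, py, ring) {
  m <- nrow(ring)
  if (all(ring[1, ] == ring[m, ])) { ring <- ring[-m, , drop = FALSE]; m <- m - 1 }
  vapply(seq_along(px), function(i) {
    wn <- 0
    for (v in seq_len(m)) {
      w <- if (v == m) 1L else v + 1L
      x1 <- ring[v, 1]; y1 <- ring[v, 2]; x2 <- ring[w, 1]; y2 <- ring[w, 2]
      is_left <- (x2 - x1) * (py[i] - y1) - (px[i] - x1) * (y2 - y1)
      if (y1 <= py[i]) {
        if (y2 > py[i] && is_left > 0) wn <- wn + 1
      } else {
        if (y2 <= py[i] && is_left < 0) wn <- wn - 1
      }
    }
    wn != 0
  }, logical(1))
}

# O(n^2) pairwise-difference Gini.
oracle_gini_pairwise <- function(x) {
  n <- length(x)
  mean(abs(outer(x, x, "-"))) / (2 * mean(x))
}

# Brute-force nearest-neighbour index (great-circle).
oracle_nearest <- function(qlon, qlat, rlon, rlat) {
  vapply(seq_along(qlon), function(i) {
    which.min(oracle_haversine(qlon[i], qlat[i], rlon, rlat))
  }, integer(1))
}

# Minimal ping tibble constructor.
make_pings <- function(user_id, t, lat, lon, accuracy_m = 10) {
  tibble::tibble(user_id = user_id, timestamp_s = as.numeric(t),
                 lat = lat, lon = lon, accuracy_m = accuracy_m)
}

# Random clustered ping cloud: `n` pings from `n_users` devices visiting a
# few hotspots over one day; produces a healthy number of path crossings.
random_ping_cloud <- function(n, n_users = 50, n_spots = 8, seed = 1,
                              spread_m = 60) {
  set.seed(seed)
  spot_lon <- runif(n_spots, -97.02, -96.98)
  spot_lat <- runif(n_spots, 38.98, 39.02)
  s <- sample.int(n_spots, n, replace = TRUE)
  make_pings(
    user_id = sprintf("u%03d", sample.int(n_users, n, replace = TRUE)),
    t = round(runif(n, 0, 86400)),
    lat = spot_lat[s] + rnorm(n, 0, spread_m / 111320),
    lon = spot_lon[s] + rnorm(n, 0, spread_m / 85000)
  )
}

# Ego-partner records with known true correlation rho between ego SES and
# the latent mean partner SES (unit-variance latent parts, residual sd 1).
gen_records <- function(seed, rho, n_egos = 2000, n_partners = 3,
                        resid_sd = 1) {
  set.seed(seed)
  x <- as.numeric(scale(rnorm(n_egos)))
  m <- rho * x + rnorm(n_egos, 0, sqrt(1 - rho^2))
  tibble::tibble(
    ego = rep(sprintf("e%05d", seq_len(n_egos)), each = n_partners),
    x = rep(x, each = n_partners),
    y = rep(m, each = n_partners) + rnorm(n_egos * n_partners, 0, resid_sd)
  )
}

# One small processed city shared by the heavier integration tests.
small_city_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- city_config(n_individuals = 120, n_tracts = 9, n_pois = 20,
                       n_hubs = 3, n_days = 7, pings_per_day = 20,
                       duplicate_device_rate = 0.05, seed = 7)
    city <- generate_city(cfg)
    traces <- generate_traces(city, ground_truth_cap = 0)
    pings <- dedupe_duplicate_users(filter_pings(traces$pings))
    homes <- infer_homes(pings, home_inference_params(min_pings = 50))
    ind <- link_ses(homes$homes, city$registry)
    ind <- winsorize_ses(ind)
    ind <- assign_home_tract(ind, city$tract_layer)
    edges <- find_path_crossings(pings)
    edges <- edges[edges$user_i %in% ind$user_id &
                     edges$user_j %in% ind$user_id, ]
    annotated <- annotate_exposures(edges, ind, city$tract_layer,
                                    city$poi_layer, city$hub_layer)
    cache <<- list(city = city, traces = traces, pings = pings,
                   individuals = ind, edges = edges, annotated = annotated)
    cache
  }
})
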