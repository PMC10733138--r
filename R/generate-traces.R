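#' Generate GPS-like traces for a synthetic city
#'
#' Emits at most one ping per device-hour (Bernoulli with rate
#' `pings_per_day / 24`). During the local night window the device is at
#' home; during two daily outings (two-hour blocks in day hours) it is at a
#' venue chosen by a softmax over `-distance/1km -
#' venue_homophily * |log target SES - log own SES| / sigma`; remaining day
#' hours are spent at home. Recorded coordinates add isotropic Gaussian
#' noise with per-ping scale `accuracy_noise_sd * u` (`u` log-normal), and
#' the scale is reported as the ping's `accuracy_m`. A
#' `duplicate_device_rate` fraction of extra devices clone 90% of a host
#' device's pings verbatim to exercise de-duplication.
#'
#' @param city An [generate_city()] result.
#' @param thresholds [exposure_thresholds()] used for the ground-truth
#'   co-location list.
#' @param ground_truth_cap Maximum ping count for which the ground-truth
#'   co-location events are computed (with the brute-force detector on the
#'   noiseless true positions); above it `ground_truth_exposures` is `NULL`.
#' @return An object of class `exposeg_traces`: a list with `pings`
#'   (tibble `user_id`, `timestamp_s`, `lat`, `lon`, `accuracy_m`),
#'   `true_pings` (same rows with noiseless coordinates and no duplicate
#'   devices), `duplicate_ids`, and `ground_truth_exposures`.
#' @export
generate_traces <- function(city, thresholds = exposure_thresholds(),
                            ground_truth_cap = 50000) {
  stopifnot(inherits(city, "exposeg_city"))
  config <- city$config
  set.seed(config$seed + 1L)
  ind <- city$individuals
  n <- nrow(ind)
  anchor <- config$anchor
  sig <- max(config$rent_lognormal_sigma, 1e-8)

  ## venue-choice probabilities: n_individuals x n_pois softmax
  poi_xy <- city$poi_xy
  dist_m <- sqrt(outer(ind$true_x, poi_xy[, 1], "-")^2 +
                   outer(ind$true_y, poi_xy[, 2], "-")^2)
  ses_gap <- abs(outer(log(ind$true_ses), log(city$poi_layer$target_ses), "-")) / sig
  util <- -dist_m / 1000 - config$venue_homophily * ses_gap
  util <- util - apply(util, 1, max)
  pmat <- exp(util)
  pmat <- pmat / rowSums(pmat)

  ## schedule: per device-day, two 2 h outings in local day hours
  local_hours <- 0:23
  day_hours <- local_hours[!in_night_window(local_hours, config$night_start,
                                            config$night_end)]
  if (length(day_hours) == 0) day_hours <- integer(0)
  n_days <- config$n_days
  n_out <- if (length(day_hours)) 2L else 0L

  sched <- vector("list", n)
  for (i in seq_len(n)) {
    if (n_out == 0) { sched[[i]] <- integer(0); next }
    venues <- sample.int(nrow(poi_xy), n_days * n_out, replace = TRUE,
                         prob = pmat[i, ])
    starts <- sample(day_hours, n_days * n_out, replace = TRUE)
    # venue index per (day, local hour); 0 = at home
    at <- matrix(0L, n_days, 24)
    d <- rep(seq_len(n_days), each = n_out)
    for (s in seq_along(starts)) {
      hh <- c(starts[s], starts[s] + 1L) %% 24
      hh <- hh[hh %in% day_hours]
      at[d[s], hh + 1L] <- venues[s]
    }
    sched[[i]] <- at
  }

  ## hourly Bernoulli ping emission (UTC hour grid)
  p_hour <- config$pings_per_day / 24
  grid <- data.table::CJ(i = seq_len(n), day = seq_len(n_days) - 1L,
                         hh = 0:23)
  keep <- runif(nrow(grid)) < p_hour
  grid <- grid[keep]
  hh_local <- (grid$hh + config$timezone_offset) %% 24
  venue <- integer(nrow(grid))
  if (n_out > 0) {
    venue <- vapply(seq_len(nrow(grid)), function(r) {
      sched[[grid$i[r]]][grid$day[r] + 1L, hh_local[r] + 1L]
    }, integer(1))
  }

  at_home <- venue == 0L
  tx <- ifelse(at_home, ind$true_x[grid$i], 0)
  ty <- ifelse(at_home, ind$true_y[grid$i], 0)
  if (any(!at_home)) {
    qp <- config$poi_size_m / 2
    vi <- venue[!at_home]
    tx[!at_home] <- poi_xy[vi, 1] + runif(sum(!at_home), -qp, qp)
    ty[!at_home] <- poi_xy[vi, 2] + runif(sum(!at_home), -qp, qp)
  }
  ts <- config$epoch_start + (grid$day * 24 + grid$hh) * 3600 +
    round(runif(nrow(grid), 0, 3599))

  noise_scale <- config$accuracy_noise_sd *
    exp(rnorm(nrow(grid), 0, 0.4) - 0.08) # E[u] = 1
  ox <- tx + rnorm(nrow(grid), 0, 1) * noise_scale
  oy <- ty + rnorm(nrow(grid), 0, 1) * noise_scale

  true_ll <- local_unproject(tx, ty, anchor)
  obs_ll <- local_unproject(ox, oy, anchor)
  true_pings <- tibble::tibble(
    user_id = ind$user_id[grid$i],
    timestamp_s = as.numeric(ts),
    lat = true_ll$lat, lon = true_ll$lon,
    accuracy_m = pmax(noise_scale, 1)
  )
  pings <- tibble::tibble(
    user_id = ind$user_id[grid$i],
    timestamp_s = as.numeric(ts),
    lat = obs_ll$lat, lon = obs_ll$lon,
    accuracy_m = pmax(noise_scale, 1)
  )

  ## duplicate devices: clone 90% of a host's pings verbatim
  n_dup <- round(config$duplicate_device_rate * n)
  duplicate_ids <- character(0)
  if (n_dup > 0) {
    hosts <- sample(ind$user_id, n_dup)
    dup_rows <- purrr::map2(hosts, seq_len(n_dup), function(hid, j) {
      rows <- pings[pings$user_id == hid, ]
      take <- sort(sample.int(nrow(rows), ceiling(0.9 * nrow(rows))))
      out <- rows[take, ]
      out$user_id <- sprintf("dup%03d", j)
      out
    })
    duplicate_ids <- sprintf("dup%03d", seq_len(n_dup))
    pings <- dplyr::bind_rows(pings, dup_rows)
  }
  pings <- dplyr::arrange(pings, user_id, timestamp_s)
  true_pings <- dplyr::arrange(true_pings, user_id, timestamp_s)

  gt <- NULL
  if (nrow(true_pings) <= ground_truth_cap) {
    gt <- find_path_crossings_bruteforce(
      dplyr::rename(true_pings, lat = lat, lon = lon),
      thresholds, cap = ground_truth_cap
    )
  }

  structure(
    list(pings = pings, true_pings = true_pings,
         duplicate_ids = duplicate_ids, ground_truth_exposures = gt),
    class = "exposeg_traces"
  )
}

#' @export
print.exposeg_traces <- function(x, ...) {
  cat("<exposeg_traces> ", nrow(x$pings), " pings, ",
      length(unique(x$pings$user_id)), " devices (",
      length(x$duplicate_ids), " duplicates)\n", sep = "")
  invisible(x)
}
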