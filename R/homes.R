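#' Home-inference parameters
#'
#' Thresholds of the stationary-night home-location rule: devices need at
#' least `min_pings` raw pings; hourly positions are kept when the local
#' clock hour lies in `[night_start, 24) U [0, night_end)` and the device
#' moves less than `stationary_radius_m` before the next hour; such hours
#' must occur on at least `min_stationary_dates` distinct local dates with
#' at least `min_within_radius_frac` of them inside `stationary_radius_m`
#' of their centre; the home is the coordinate-wise median of the in-radius
#' night positions.
#'
#' @param min_pings Minimum raw ping count per device (default 500).
#' @param night_start,night_end Local clock hours bounding the night window.
#' @param stationary_radius_m Stationarity/clustering radius in metres.
#' @param min_stationary_dates Minimum distinct local dates with stationary
#'   night hours.
#' @param min_within_radius_frac Minimum fraction of stationary night
#'   positions within the radius of their centre.
#' @param timezone_offset Hours added to UTC for local clock time.
#' @return A list of class `home_inference_params`.
#' @export
home_inference_params <- function(min_pings = 500,
                                  night_start = 18, night_end = 9,
                                  stationary_radius_m = 50,
                                  min_stationary_dates = 3,
                                  min_within_radius_frac = 0.60,
                                  timezone_offset = 0) {
  if (min_within_radius_frac <= 0 || min_within_radius_frac > 1) {
    stop("min_within_radius_frac must lie in (0, 1]")
  }
  structure(
    list(min_pings = min_pings, night_start = night_start,
         night_end = night_end, stationary_radius_m = stationary_radius_m,
         min_stationary_dates = min_stationary_dates,
         min_within_radius_frac = min_within_radius_frac,
         timezone_offset = timezone_offset),
    class = "home_inference_params"
  )
}

#' Infer a home location from one device's hourly positions
#'
#' Applies the stationary-night rule of [home_inference_params()] to an
#' hourly-interpolated track (see [interpolate_hourly()]). Returns a
#' one-row tibble with `home_lat`/`home_lon` (and `n_stationary`), or a
#' zero-row tibble whose `attr(, "failure_reason")` is one of
#' `"min_stationary_dates"` or `"within_radius_frac"`.
#'
#' @param hourly Tibble `user_id`, `timestamp_s`, `lat`, `lon` on an hourly
#'   grid.
#' @param params A [home_inference_params()].
#' @return One- or zero-row tibble.
#' @export
infer_home <- function(hourly, params = home_inference_params()) {
  fail <- function(reason) {
    out <- tibble::tibble(home_lat = numeric(0), home_lon = numeric(0),
                          n_stationary = integer(0))
    attr(out, "failure_reason") <- reason
    out
  }
  if (nrow(hourly) < 2) return(fail("min_stationary_dates"))
  hourly <- dplyr::arrange(hourly, .data$timestamp_s)
  n <- nrow(hourly)
  # displacement to the next hourly position; last hour has none
  step_m <- haversine_m(hourly$lon[-n], hourly$lat[-n],
                        hourly$lon[-1], hourly$lat[-1])
  consec <- diff(hourly$timestamp_s) == 3600
  local_t <- hourly$timestamp_s + params$timezone_offset * 3600
  hh <- (local_t %/% 3600) %% 24
  is_night <- in_night_window(hh, params$night_start, params$night_end)
  idx <- which(is_night[-n] & consec & step_m < params$stationary_radius_m)
  if (!length(idx)) return(fail("min_stationary_dates"))
  pts <- hourly[idx, ]
  dates <- local_t[idx] %/% 86400
  if (length(unique(dates)) < params$min_stationary_dates) {
    return(fail("min_stationary_dates"))
  }
  centre_lat <- median(pts$lat); centre_lon <- median(pts$lon)
  d <- haversine_m(pts$lon, pts$lat, centre_lon, centre_lat)
  inside <- d <= params$stationary_radius_m
  if (mean(inside) < params$min_within_radius_frac) {
    return(fail("within_radius_frac"))
  }
  tibble::tibble(home_lat = median(pts$lat[inside]),
                 home_lon = median(pts$lon[inside]),
                 n_stationary = sum(inside))
}

#' Infer home locations for every device in a ping table
#'
#' Runs the full home-inference cascade: the `min_pings` device filter,
#' hourly interpolation, and the stationary-night rule of [infer_home()].
#'
#' @param pings A ping tibble (after [filter_pings()]).
#' @param params A [home_inference_params()].
#' @return A list with `homes` (tibble `user_id`, `home_lat`, `home_lon`,
#'   `n_pings`, `n_stationary`) and `failures` (tibble `user_id`, `reason`),
#'   the machine-readable audit of why devices dropped out.
#' @export
infer_homes <- function(pings, params = home_inference_params()) {
  check_ping_table(pings, need_accuracy = FALSE)
  counts <- dplyr::count(pings, .data$user_id, name = "n_pings")
  too_few <- counts$user_id[counts$n_pings < params$min_pings]
  failures <- tibble::tibble(user_id = too_few,
                             reason = rep("min_pings", length(too_few)))
  eligible <- counts[counts$n_pings >= params$min_pings, ]
  rows <- vector("list", nrow(eligible))
  for (i in seq_len(nrow(eligible))) {
    uid <- eligible$user_id[i]
    up <- pings[pings$user_id == uid, ]
    hourly <- interpolate_hourly(up)
    if (nrow(hourly) == 0) {
      failures <- dplyr::bind_rows(
        failures, tibble::tibble(user_id = uid,
                                 reason = attr(hourly, "skip_reason")))
      next
    }
    hm <- infer_home(hourly, params)
    if (nrow(hm) == 0) {
      failures <- dplyr::bind_rows(
        failures, tibble::tibble(user_id = uid,
                                 reason = attr(hm, "failure_reason")))
      next
    }
    rows[[i]] <- tibble::tibble(user_id = uid, home_lat = hm$home_lat,
                                home_lon = hm$home_lon,
                                n_pings = eligible$n_pings[i],
                                n_stationary = hm$n_stationary)
  }
  empty <- tibble::tibble(user_id = character(0), home_lat = numeric(0),
                          home_lon = numeric(0), n_pings = integer(0),
                          n_stationary = integer(0))
  list(homes = dplyr::bind_rows(empty, rows), failures = failures)
}
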