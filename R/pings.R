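#' Filter pings by reported horizontal accuracy
#'
#' Keeps pings whose reported accuracy is no worse than `max_accuracy_m`
#' (the boundary value is kept). Row order is preserved; an empty input
#' returns an empty output.
#'
#' @param pings Tibble with columns `user_id`, `timestamp_s`, `lat`, `lon`,
#'   `accuracy_m`.
#' @param max_accuracy_m Accuracy cutoff in metres (default 100).
#' @return The filtered ping tibble.
#' @export
filter_pings <- function(pings, max_accuracy_m = 100) {
  check_ping_table(pings)
  dplyr::filter(pings, .data$accuracy_m <= max_accuracy_m)
}

check_ping_table <- function(pings, need_accuracy = TRUE) {
  cols <- c("user_id", "timestamp_s", "lat", "lon",
            if (need_accuracy) "accuracy_m")
  missing <- setdiff(cols, names(pings))
  if (length(missing)) {
    stop("ping table is missing column(s): ", paste(missing, collapse = ", "))
  }
  invisible(pings)
}

#' Interpolate one device's track onto hour boundaries
#'
#' Linear interpolation of latitude and longitude onto whole-hour epochs
#' between the device's first and last ping (no extrapolation beyond the
#' observed span). Devices with fewer than two pings yield zero rows with
#' attribute `skip_reason = "too_few_pings"`.
#'
#' @param pings Pings of a single device.
#' @return Tibble `user_id`, `timestamp_s` (whole hours), `lat`, `lon`.
#' @export
interpolate_hourly <- function(pings) {
  check_ping_table(pings, need_accuracy = FALSE)
  uid <- unique(pings$user_id)
  if (length(uid) > 1) stop("interpolate_hourly() expects one device")
  pings <- dplyr::arrange(pings, .data$timestamp_s)
  empty <- tibble::tibble(user_id = character(0), timestamp_s = numeric(0),
                          lat = numeric(0), lon = numeric(0))
  if (nrow(pings) < 2) {
    attr(empty, "skip_reason") <- "too_few_pings"
    return(empty)
  }
  t0 <- ceiling(min(pings$timestamp_s) / 3600) * 3600
  t1 <- floor(max(pings$timestamp_s) / 3600) * 3600
  if (t1 < t0) {
    attr(empty, "skip_reason") <- "span_shorter_than_one_hour"
    return(empty)
  }
  hours <- seq(t0, t1, by = 3600)
  # approx() with ties = mean handles duplicate timestamps
  la <- stats::approx(pings$timestamp_s, pings$lat, xout = hours,
                      ties = mean)$y
  lo <- stats::approx(pings$timestamp_s, pings$lon, xout = hours,
                      ties = mean)$y
  tibble::tibble(user_id = uid, timestamp_s = hours, lat = la, lon = lo)
}
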