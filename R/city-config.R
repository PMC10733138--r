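#' Synthetic-city configuration
#'
#' Bundles every knob of the synthetic-city generator. All randomness in
#' [generate_city()] and [generate_traces()] flows from `seed`. Defaults
#' describe a mid-sized 10 x 10 km city: log-normal monthly rents with a
#' tract-level component, night-time pings at home, and day-time venue
#' visits with distance- and SES-driven choice.
#'
#' @param n_individuals Number of resident devices.
#' @param n_tracts Number of census-tract polygons partitioning the city.
#' @param tract_layout `"grid"` or `"voronoi"` tract geometry.
#' @param rent_lognormal_mu,rent_lognormal_sigma Location/scale of the
#'   log-normal monthly rent distribution (log-USD/month).
#' @param tract_ses_autocorrelation Share of log-rent variance explained by
#'   the tract, in `[0, 1]`; 1 makes tracts internally rent-homogeneous, 0
#'   makes rents independent of tract.
#' @param n_pois Number of points of interest (venues).
#' @param n_hubs Number of hub polygons (commercial centres); each hub
#'   contains at least one POI.
#' @param hub_placement `"bridging"` (hubs between SES-dissimilar tracts),
#'   `"embedded"` (hubs inside tracts across the SES range) or `"random"`.
#' @param venue_homophily Non-negative strength of SES matching in venue
#'   choice; 0 makes venue choice depend on distance only.
#' @param pings_per_day Expected pings emitted per device per day.
#' @param n_days Days of trace.
#' @param accuracy_noise_sd Positional noise scale in metres; 0 gives exact
#'   coordinates.
#' @param night_start,night_end Local clock hours bounding the night window
#'   `[night_start, 24) U [0, night_end)`.
#' @param timezone_offset Hours added to UTC to obtain local clock time.
#' @param duplicate_device_rate Fraction of devices that are near-clones of
#'   another device (exercises de-duplication).
#' @param city_width_m,city_height_m City rectangle dimensions in metres.
#' @param anchor WGS84 `c(lon, lat)` anchor of the local projection.
#' @param poi_size_m,hub_size_m Side lengths of the square POI/hub polygons.
#' @param epoch_start UTC epoch seconds of day 0, hour 0.
#' @param seed Integer seed driving all generator randomness.
#' @return An object of class `city_config` (a validated list).
#' @export
city_config <- function(n_individuals = 2000,
                        n_tracts = 25,
                        tract_layout = c("grid", "voronoi"),
                        rent_lognormal_mu = 7.2,
                        rent_lognormal_sigma = 0.55,
                        tract_ses_autocorrelation = 0.6,
                        n_pois = 60,
                        n_hubs = 6,
                        hub_placement = c("random", "bridging", "embedded"),
                        venue_homophily = 2,
                        pings_per_day = 24,
                        n_days = 30,
                        accuracy_noise_sd = 10,
                        night_start = 18,
                        night_end = 9,
                        timezone_offset = 0,
                        duplicate_device_rate = 0.02,
                        city_width_m = 10000,
                        city_height_m = 10000,
                        anchor = c(-97, 39),
                        poi_size_m = 40,
                        hub_size_m = 200,
                        epoch_start = 1488326400,
                        seed = 1L) {
  tract_layout <- match.arg(tract_layout)
  hub_placement <- match.arg(hub_placement)
  cfg <- list(
    n_individuals = as.integer(n_individuals), n_tracts = as.integer(n_tracts),
    tract_layout = tract_layout, rent_lognormal_mu = rent_lognormal_mu,
    rent_lognormal_sigma = rent_lognormal_sigma,
    tract_ses_autocorrelation = tract_ses_autocorrelation,
    n_pois = as.integer(n_pois), n_hubs = as.integer(n_hubs),
    hub_placement = hub_placement, venue_homophily = venue_homophily,
    pings_per_day = pings_per_day, n_days = as.integer(n_days),
    accuracy_noise_sd = accuracy_noise_sd,
    night_start = night_start, night_end = night_end,
    timezone_offset = timezone_offset,
    duplicate_device_rate = duplicate_device_rate,
    city_width_m = city_width_m, city_height_m = city_height_m,
    anchor = anchor, poi_size_m = poi_size_m, hub_size_m = hub_size_m,
    epoch_start = epoch_start, seed = as.integer(seed)
  )
  counts <- c("n_individuals", "n_tracts", "n_pois", "n_hubs", "n_days")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      stop("invalid city_config: field '", f, "' must be a count >= 1")
    }
  }
  if (!is.finite(cfg$tract_ses_autocorrelation) ||
      cfg$tract_ses_autocorrelation < 0 || cfg$tract_ses_autocorrelation > 1) {
    stop("invalid city_config: field 'tract_ses_autocorrelation' must lie in [0, 1]")
  }
  if (cfg$duplicate_device_rate < 0 || cfg$duplicate_device_rate > 1) {
    stop("invalid city_config: field 'duplicate_device_rate' must lie in [0, 1]")
  }
  if (cfg$venue_homophily < 0) {
    stop("invalid city_config: field 'venue_homophily' must be >= 0")
  }
  if (cfg$rent_lognormal_sigma < 0) {
    stop("invalid city_config: field 'rent_lognormal_sigma' must be >= 0")
  }
  if (cfg$accuracy_noise_sd < 0) {
    stop("invalid city_config: field 'accuracy_noise_sd' must be >= 0")
  }
  if (cfg$pings_per_day <= 0 || cfg$pings_per_day > 24) {
    stop("invalid city_config: field 'pings_per_day' must be in (0, 24] ",
         "(one Bernoulli draw per hour)")
  }
  for (f in c("night_start", "night_end")) {
    if (cfg[[f]] < 0 || cfg[[f]] >= 24) {
      stop("invalid city_config: field '", f, "' must be a clock hour in [0, 24)")
    }
  }
  if (cfg$city_width_m <= 0 || cfg$city_height_m <= 0) {
    stop("invalid city_config: field 'city_width_m'/'city_height_m' must be > 0")
  }
  structure(cfg, class = "city_config")
}

#' @export
print.city_config <- function(x, ...) {
  cat("<city_config> ", x$n_individuals, " individuals, ", x$n_tracts,
      " tracts (", x$tract_layout, "), ", x$n_pois, " POIs, ", x$n_hubs,
      " hubs (", x$hub_placement, "), ", x$n_days, " days, seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

# Is local clock hour h inside the (possibly wrapping) night window?
in_night_window <- function(h, night_start, night_end) {
  if (night_start < night_end) h >= night_start & h < night_end
  else h >= night_start | h < night_end
}
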