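test_that("accuracy filter keeps the boundary and preserves order", {
  p <- make_pings("u1", 1:3, 39, -97, accuracy_m = c(50, 100, 150))
  expect_equal(filter_pings(p)$accuracy_m, c(50, 100))
  p10 <- make_pings("u1", 1:5, 39, -97, accuracy_m = 10)
  expect_identical(filter_pings(p10), p10)
  expect_equal(nrow(filter_pings(p10[0, ])), 0)
  # random table: row count equals a brute-force predicate scan
  set.seed(2)
  pr <- make_pings("u1", 1:500, 39, -97, accuracy_m = runif(500, 0, 200))
  expect_equal(nrow(filter_pings(pr)), sum(pr$accuracy_m <= 100))
  expect_false(is.unsorted(filter_pings(pr)$timestamp_s))
})

test_that("hourly interpolation is linear and never extrapolates", {
  p <- make_pings("u1", c(0, 7200), c(0, 0), c(0, 0.002))
  h <- interpolate_hourly(p)
  expect_equal(h$timestamp_s, c(0, 3600, 7200))
  expect_equal(h$lon[2], 0.001)
  expect_equal(h$lat[2], 0)
  # stationary device: all hourly positions equal its single location
  ps <- make_pings("u2", c(100, 90000), 39.5, -96.5)
  hs <- interpolate_hourly(ps)
  expect_true(all(hs$lat == 39.5 & hs$lon == -96.5))
  expect_gte(min(hs$timestamp_s), 100)
  expect_lte(max(hs$timestamp_s), 90000)
  # piecewise random trajectory matches an independent interpolation oracle
  set.seed(4)
  tt <- sort(sample(0:50000, 40))
  pw <- make_pings("u3", tt, cumsum(rnorm(40, 0, 1e-3)) + 39,
                   cumsum(rnorm(40, 0, 1e-3)) - 97)
  hp <- interpolate_hourly(pw)
  manual <- function(h, v) {
    i <- findInterval(h, tt)
    w <- (h - tt[i]) / (tt[i + 1] - tt[i])
    ifelse(h == tt[i], v[i], v[i] * (1 - w) + v[i + 1] * w)
  }
  expect_equal(hp$lat, manual(hp$timestamp_s, pw$lat), tolerance = 1e-12)
  expect_equal(hp$lon, manual(hp$timestamp_s, pw$lon), tolerance = 1e-12)
  # single ping: skipped with a reason
  one <- interpolate_hourly(make_pings("u4", 5, 39, -97))
  expect_equal(nrow(one), 0)
  expect_equal(attr(one, "skip_reason"), "too_few_pings")
})

test_that("home inference recovers a fixed night location", {
  # nightly pings at one exact point across 5 dates
  t0 <- as.numeric(as.POSIXct("2017-03-06 20:00:00", tz = "UTC"))
  tt <- as.vector(outer(0:5 * 3600, 0:4 * 86400, "+")) + t0
  p <- make_pings("u1", tt, 39.123456, -96.654321)
  h <- infer_home(interpolate_hourly(p))
  expect_equal(h$home_lat, 39.123456)
  expect_equal(h$home_lon, -96.654321)
})

test_that("devices with too few pings fail with reason min_pings", {
  p <- make_pings("u1", seq(0, by = 3600, length.out = 499), 39, -97)
  res <- infer_homes(p, home_inference_params())
  expect_equal(nrow(res$homes), 0)
  expect_equal(res$failures$reason, "min_pings")
})

test_that("date and radius criteria produce their failure reasons", {
  # stationary night hours on a single local date
  t0 <- as.numeric(as.POSIXct("2017-03-06 19:00:00", tz = "UTC"))
  tt <- t0 + 0:3 * 3600
  h <- infer_home(interpolate_hourly(make_pings("u1", tt, 39, -97)))
  expect_equal(nrow(h), 0)
  expect_equal(attr(h, "failure_reason"), "min_stationary_dates")
  # two distant stationary night clusters: within-radius fraction fails
  tt2 <- as.vector(outer(0:5 * 3600, 0:5 * 86400, "+")) + t0
  lat <- rep(c(39, 39.01), each = length(tt2) / 2) # ~1.1 km apart
  h2 <- infer_home(interpolate_hourly(make_pings("u1", sort(tt2), lat, -97)))
  expect_equal(nrow(h2), 0)
  expect_equal(attr(h2, "failure_reason"), "within_radius_frac")
})

test_that("synthetic homes are recovered within the stationary radius", {
  cfg <- city_config(n_individuals = 100, n_tracts = 9, n_pois = 12,
                     n_hubs = 2, n_days = 7, pings_per_day = 20,
                     accuracy_noise_sd = 20, duplicate_device_rate = 0,
                     seed = 31)
  city <- generate_city(cfg)
  tr <- generate_traces(city, ground_truth_cap = 0)
  hm <- infer_homes(tr$pings, home_inference_params(min_pings = 50))
  idx <- match(hm$homes$user_id, city$individuals$user_id)
  d <- haversine_m(hm$homes$home_lon, hm$homes$home_lat,
                   city$individuals$true_lon[idx],
                   city$individuals$true_lat[idx])
  recovered <- sum(d <= 50)
  expect_gte(recovered / nrow(city$individuals), 0.99)
})

test_that("SES linking matches a brute-force nearest-property scan", {
  # home exactly at a property takes that property's rent
  reg <- tibble::tibble(property_id = c("a", "b"),
                        lon = c(-97, -96.99), lat = c(39, 39),
                        rent_usd_month = c(1200, 3400))
  ind <- tibble::tibble(user_id = "u1", home_lat = 39, home_lon = -97)
  expect_equal(link_ses(ind, reg)$ses, 1200)
  # home 150 m from any property is dropped
  far <- tibble::tibble(user_id = "u2", home_lat = 39 + 150 / 111320,
                        home_lon = -97)
  expect_equal(nrow(link_ses(far, reg)), 0)
  expect_error(link_ses(ind, reg[0, ]), "empty")
  # random geometry: links equal the O(n*m) oracle
  set.seed(9)
  regr <- tibble::tibble(property_id = sprintf("p%03d", 1:80),
                         lon = -97 + runif(80, 0, 0.02),
                         lat = 39 + runif(80, 0, 0.02),
                         rent_usd_month = rlnorm(80, 7, 0.5))
  indr <- tibble::tibble(user_id = sprintf("u%03d", 1:60),
                         home_lat = 39 + runif(60, 0, 0.02),
                         home_lon = -97 + runif(60, 0, 0.02))
  got <- link_ses(indr, regr, max_link_distance_m = Inf)
  want <- regr$property_id[oracle_nearest(indr$home_lon, indr$home_lat,
                                          regr$lon, regr$lat)]
  expect_equal(got$property_id, want)
})

test_that("winsorization caps only the upper tail", {
  expect_equal(winsorize_ses(25000), 20000)
  expect_equal(winsorize_ses(1500), 1500)
  v <- c(100, 19999, 20000, 20001, 1e6)
  expect_equal(winsorize_ses(v), pmin(v, 20000))
  ind <- tibble::tibble(ses = v)
  expect_equal(winsorize_ses(ind)$ses, pmin(v, 20000))
})

test_that("alternative SES measures follow their conventions", {
  ind <- tibble::tibble(user_id = c("a", "b", "c"), ses = c(100, 200, 300))
  p <- alternative_ses(ind, "percentile")$ses_alt
  expect_equal(p, c(100 / 6, 50, 500 / 6), tolerance = 1e-12)
  # ties: all-equal rents share percentile 50
  tied <- tibble::tibble(user_id = letters[1:4], ses = rep(900, 4))
  expect_equal(alternative_ses(tied, "percentile")$ses_alt, rep(50, 4))
  # rank invariance under monotone transforms
  set.seed(5)
  r <- tibble::tibble(user_id = sprintf("u%02d", 1:30), ses = rlnorm(30, 7))
  r2 <- dplyr::mutate(r, ses = ses^3 + 5)
  expect_equal(alternative_ses(r, "percentile")$ses_alt,
               alternative_ses(r2, "percentile")$ses_alt)
  expect_error(alternative_ses(ind, "banana"), "unknown SES mode")
  # cbg income mode pulls the home tract's synthetic income
  ind$home_tract_id <- c("t1", "t2", "t1")
  ti <- tibble::tibble(tract_id = c("t1", "t2"),
                       median_income_usd_year = c(40000, 90000))
  expect_equal(alternative_ses(ind, "cbg_income", ti)$ses_alt,
               c(40000, 90000, 40000))
})

test_that("identical-home and shared-property filters drop the right users", {
  ind <- tibble::tibble(user_id = c("a", "b", "c"),
                        home_lat = c(39, 39, 39.001),
                        home_lon = c(-97, -97, -97),
                        property_id = c("p1", "p1", "p2"))
  kept <- filter_identical_homes(ind)
  expect_equal(kept$user_id, "c")
  expect_setequal(attr(kept, "removed"), c("a", "b"))
  crowd <- tibble::tibble(user_id = sprintf("u%02d", 1:12),
                          property_id = rep("p1", 12))
  kept2 <- filter_shared_property(crowd, max_users = 10)
  expect_equal(nrow(kept2), 0)
  ok <- tibble::tibble(user_id = sprintf("u%02d", 1:10),
                       property_id = rep("p1", 10))
  expect_equal(nrow(filter_shared_property(ok, max_users = 10)), 10)
})
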