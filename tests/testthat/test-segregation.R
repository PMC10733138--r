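mk_net <- function(ui, uj) {
  tibble::tibble(user_i = ui, user_j = uj, k = 1L, t = 0,
                 lat = NA_real_, lon = NA_real_)
}

test_that("ego records deduplicate partners and restrict egos by region", {
  ind <- tibble::tibble(user_id = c("a", "b", "c", "d", "e"),
                        ses = c(1000, 2000, 3000, 4000, 5000),
                        region = c("R", "R", "R", "R", "S"))
  # resident with no exposures yields no record
  e <- mk_net(c("a", "a", "a"), c("b", "c", "d"))
  rec <- build_ego_records(e, ind, region = "R")
  expect_false("e" %in% rec$ego)
  expect_equal(sort(rec$y[rec$ego == "a"]), c(2000, 3000, 4000))
  # five repeated events with one partner collapse to one partner value
  e5 <- dplyr::bind_rows(mk_net(rep("a", 5), rep("b", 5)), mk_net("c", "d"))
  rec5 <- build_ego_records(e5, ind, region = "R")
  expect_equal(sum(rec5$ego == "a"), 1)
  # partners outside the region are retained as partners, not egos
  ecross <- mk_net(c("a", "b"), c("e", "e"))
  recc <- build_ego_records(ecross, ind, region = "R")
  expect_setequal(unique(recc$ego), c("a", "b"))
  expect_true(all(recc$y == 5000))
  # x is standardized over the egos entering estimation
  expect_equal(mean(tapply(rec$x, rec$ego, `[`, 1)), 0, tolerance = 1e-12)
  expect_equal(sd(tapply(rec$x, rec$ego, `[`, 1)), 1, tolerance = 1e-12)
  # a single-ego region refuses estimation
  expect_error(build_ego_records(mk_net("a", "e"), ind, region = "R"),
               "fewer than 2 egos")
})

test_that("naive estimator is the Pearson correlation of ego and partner means", {
  ind <- tibble::tibble(user_id = letters[1:4], ses = c(1, 2, 3, 4))
  e <- mk_net(c("a", "b", "c", "d"), c("b", "c", "d", "a"))
  rec <- build_ego_records(e, ind)
  # 10-ego random fixture matches the closed-form Pearson formula
  set.seed(14)
  rec10 <- gen_records(1, 0.6, n_egos = 10, n_partners = 4)
  got <- naive_exposure_segregation(rec10)
  xs <- tapply(rec10$x, rec10$ego, `[`, 1)
  ys <- tapply(rec10$y, rec10$ego, mean)
  num <- sum((xs - mean(xs)) * (ys - mean(ys)))
  den <- sqrt(sum((xs - mean(xs))^2) * sum((ys - mean(ys))^2))
  expect_equal(got$estimate, num / den, tolerance = 1e-12)
  # partner means equal to own x give correlation 1
  perf <- tibble::tibble(ego = letters[1:5], x = 1:5, y = 1:5)
  expect_equal(naive_exposure_segregation(perf)$estimate, 1)
  # constant partner means: undefined with a reason
  flat <- tibble::tibble(ego = letters[1:5], x = 1:5, y = 7)
  out <- naive_exposure_segregation(flat)
  expect_true(is.na(out$estimate))
  expect_equal(out$note, "zero_variance")
})

test_that("REML recovers known parameters within Monte-Carlo error", {
  # a = 0.5, var1 = 0.25, var2 = 1, 5 partners per ego
  reps <- 40
  est <- matrix(NA_real_, reps, 3)
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    G <- 800
    x <- as.numeric(scale(rnorm(G)))
    m <- 0.5 * x + rnorm(G, 0, 0.5)
    rec <- tibble::tibble(ego = rep(seq_len(G), each = 5),
                          x = rep(x, each = 5),
                          y = rep(m, each = 5) + rnorm(5 * G))
    f <- fit_mixed_model(rec)
    est[r, ] <- c(f$a, f$var1, f$var2)
  }
  truth <- c(0.5, 0.25, 1)
  for (j in 1:3) {
    mc_se <- sd(est[, j]) / sqrt(reps)
    expect_lt(abs(mean(est[, j]) - truth[j]), 3 * mc_se + 1e-6)
  }
})

test_that("REML agrees with lme4 and the balanced closed form", {
  skip_if_not_installed("lme4")
  set.seed(15)
  G <- 200
  x <- as.numeric(scale(rnorm(G)))
  n_i <- sample(2:6, G, replace = TRUE)
  m <- 0.4 * x + rnorm(G, 0, 0.7)
  rec <- tibble::tibble(ego = rep(seq_len(G), n_i), x = rep(x, n_i),
                        y = rep(m, n_i) + rnorm(sum(n_i)))
  f <- fit_mixed_model(rec)
  lf <- lme4::lmer(y ~ x + (1 | ego), data = rec, REML = TRUE)
  expect_equal(f$a, lme4::fixef(lf)[["x"]], tolerance = 1e-5)
  expect_equal(f$var1, as.numeric(lme4::VarCorr(lf)$ego[1]),
               tolerance = 1e-4)
  expect_equal(f$var2, stats::sigma(lf)^2, tolerance = 1e-5)
  # balanced design: closed-form one-way variance components
  recb <- gen_records(3, 0.5, n_egos = 400, n_partners = 4)
  fb <- fit_mixed_model(recb)
  G <- 400; n <- 4; N <- G * n
  xs <- tapply(recb$x, recb$ego, `[`, 1)
  ybar <- tapply(recb$y, recb$ego, mean)
  ssw <- sum(tapply(recb$y, recb$ego, function(v) sum((v - mean(v))^2)))
  fitg <- lm(ybar ~ xs)
  B <- sum(stats::resid(fitg)^2)
  msw <- ssw / (N - G)
  msb <- n * B / (G - 2)
  expect_equal(fb$var2, msw, tolerance = 1e-6)
  expect_equal(fb$var1, max(0, (msb - msw) / n), tolerance = 1e-6)
  expect_equal(fb$a, unname(coef(fitg)[2]), tolerance = 1e-8)
})

test_that("REML sits on the boundary when the ego variance is zero", {
  rec <- gen_records(8, 0.5, n_egos = 500, n_partners = 4)
  # rebuild with var1 = 0: latent mean is exactly 0.5 * x
  set.seed(88)
  xe <- tapply(rec$x, rec$ego, `[`, 1)
  rec0 <- tibble::tibble(ego = rep(names(xe), each = 4),
                         x = rep(unname(xe), each = 4),
                         y = rep(0.5 * unname(xe), each = 4) +
                           rnorm(4 * length(xe)))
  f <- fit_mixed_model(rec0)
  expect_lt(f$var1, 0.02)
})

test_that("the mixed model demands identifiable variance components", {
  rec1 <- tibble::tibble(ego = letters[1:5], x = rnorm(5), y = rnorm(5))
  expect_error(fit_mixed_model(rec1), "identifiable")
  expect_error(fit_mixed_model(rec1[1, ]), ">= 2 egos")
})

test_that("corrected estimator evaluates the attenuation formula", {
  mf <- function(a, var1, lrt_p = 0) {
    exposeg:::new_mixfit(a = a, b = 0, var1 = var1, var2 = 1, theta = var1,
                         converged = TRUE, n_egos = 100L, n_obs = 300L,
                         null_lrt_stat = 50, null_lrt_p = lrt_p,
                         degenerate = NA_character_)
  }
  expect_equal(corrected_exposure_segregation(mf(1, 0))$estimate, 1)
  expect_equal(corrected_exposure_segregation(mf(0, 0.5))$estimate, 0)
  expect_equal(corrected_exposure_segregation(mf(3, 16))$estimate, 0.6)
  expect_equal(corrected_exposure_segregation(mf(-3, 16))$estimate, -0.6)
  # indistinguishable from random mixing: 0 with a note
  gated <- corrected_exposure_segregation(mf(0.01, 0, lrt_p = 0.5))
  expect_equal(gated$estimate, 0)
  expect_equal(gated$note, "random_mixing")
})

test_that("corrected estimates are scale-invariant and bounded", {
  rec <- gen_records(5, 0.5, n_egos = 400, n_partners = 3)
  base <- corrected_exposure_segregation(fit_mixed_model(rec))$estimate
  # affine rescaling of partner SES leaves the correlation unchanged
  rec2 <- dplyr::mutate(rec, y = 250 * y + 1700)
  expect_equal(corrected_exposure_segregation(fit_mixed_model(rec2))$estimate,
               base, tolerance = 1e-6)
  for (rho in c(0, 0.25, 0.75)) {
    est <- corrected_exposure_segregation(
      fit_mixed_model(gen_records(6, rho, 500, 3)))$estimate
    expect_gte(est, -1); expect_lte(est, 1)
  }
})

test_that("neighbourhood sorting index matches its definition", {
  two <- tibble::tibble(user_id = letters[1:4],
                        ses = c(1, 1, 5, 5),
                        home_tract_id = c("t1", "t1", "t2", "t2"))
  expect_equal(neighbourhood_sorting_index(two)$estimate, 1)
  # SES independent of tract: near zero at large n
  set.seed(16)
  big <- tibble::tibble(user_id = sprintf("u%04d", 1:4000),
                        ses = rlnorm(4000, 7, 0.5),
                        home_tract_id = sample(sprintf("t%02d", 1:40),
                                               4000, TRUE))
  expect_lt(abs(neighbourhood_sorting_index(big)$estimate), 0.15)
  # three-tract fixture against a hand computation
  fix <- tibble::tibble(user_id = letters[1:7],
                        ses = c(10, 20, 30, 40, 50, 60, 100),
                        home_tract_id = c("a", "a", "b", "b", "b", "c", "c"))
  x <- as.numeric(scale(fix$ses))
  tm <- stats::ave(x, fix$home_tract_id)
  expect_equal(neighbourhood_sorting_index(fix)$estimate, cor(x, tm),
               tolerance = 1e-12)
  expect_error(neighbourhood_sorting_index(
    dplyr::mutate(fix, home_tract_id = "a")), "single tract")
})

test_that("the dense synthetic tract network reproduces the NSI", {
  city <- generate_city(city_config(n_individuals = 500, n_tracts = 9,
                                    n_pois = 5, n_hubs = 1, n_days = 1,
                                    duplicate_device_rate = 0, seed = 23))
  ind <- dplyr::transmute(city$individuals, user_id,
                          ses = true_ses, home_tract_id = true_tract_id)
  nsi <- neighbourhood_sorting_index(ind)$estimate
  net <- synthetic_tract_network(ind, "all")
  rec <- build_ego_records(net, ind)
  seg <- corrected_exposure_segregation(fit_mixed_model(rec))$estimate
  expect_lt(abs(seg - nsi), 0.01)
  # reproducible under a fixed seed
  n1 <- synthetic_tract_network(ind, 3, seed = 4)
  n2 <- synthetic_tract_network(ind, 3, seed = 4)
  expect_identical(n1, n2)
})

test_that("sparse tract draws recover the dense-network NSI via the mixed model", {
  city <- generate_city(city_config(n_individuals = 500, n_tracts = 9,
                                    n_pois = 5, n_hubs = 1, n_days = 1,
                                    duplicate_device_rate = 0, seed = 29))
  ind <- dplyr::transmute(city$individuals, user_id,
                          ses = true_ses, home_tract_id = true_tract_id)
  nsi <- neighbourhood_sorting_index(ind)$estimate
  ests <- vapply(1:8, function(s) {
    net <- synthetic_tract_network(ind, 3, seed = s)
    rec <- build_ego_records(net, ind)
    corrected_exposure_segregation(fit_mixed_model(rec))$estimate
  }, numeric(1))
  naives <- vapply(1:8, function(s) {
    net <- synthetic_tract_network(ind, 3, seed = s)
    naive_exposure_segregation(build_ego_records(net, ind))$estimate
  }, numeric(1))
  # mixed estimates centre on the NSI; the naive ones sit below it
  expect_lt(abs(mean(ests) - nsi), 3 * sd(ests) / sqrt(8) + 0.02)
  expect_lt(mean(naives), mean(ests))
})

test_that("decomposition re-estimates per stratum and partitions events", {
  fx <- small_city_fixture()
  d <- decompose_segregation(fx$annotated, fx$individuals, by = "component")
  expect_true(all(c("both_in_home_tract", "one_in_home_tract",
                    "neither_in_home_tract") %in% d$stratum |
                    nrow(d) <= 3))
  # time windows partition the edge set
  dt <- decompose_segregation(fx$annotated, fx$individuals,
                              by = "time_window")
  hh <- (fx$annotated$t / 3600) %% 24
  expect_equal(sum(table(floor(hh / 3) * 3)), nrow(fx$annotated))
  expect_equal(length(unique(floor(hh / 3))), nrow(dt))
  # single-category stratum equals the global estimate
  one_cat <- dplyr::mutate(fx$annotated, poi_category = "722511")
  dg <- decompose_segregation(one_cat, fx$individuals, by = "poi_category")
  glob <- exposure_segregation(build_ego_records(fx$annotated,
                                                 fx$individuals))
  expect_equal(dg$estimate, glob$estimate, tolerance = 1e-10)
  # an empty stratum reports not-estimable rather than erroring
  tiny <- fx$annotated[1, ]
  dts <- decompose_segregation(tiny, fx$individuals, by = "component")
  expect_true(grepl("not_estimable", dts$note[1]))
})

test_that("in-tract homophily raises the both-in-tract stratum above neither", {
  diffs <- vapply(1:3, function(s) {
    cfg <- city_config(n_individuals = 200, n_tracts = 16, n_pois = 24,
                       n_hubs = 3, n_days = 7, pings_per_day = 20,
                       venue_homophily = 0, tract_ses_autocorrelation = 0.9,
                       duplicate_device_rate = 0, seed = s)
    city <- generate_city(cfg)
    tr <- generate_traces(city, ground_truth_cap = 0)
    p <- filter_pings(tr$pings)
    hm <- infer_homes(p, home_inference_params(min_pings = 50))
    ind <- assign_home_tract(
      winsorize_ses(link_ses(hm$homes, city$registry)), city$tract_layer)
    e <- find_path_crossings(p)
    e <- e[e$user_i %in% ind$user_id & e$user_j %in% ind$user_id, ]
    ea <- annotate_exposures(e, ind, city$tract_layer, city$poi_layer,
                             city$hub_layer)
    d <- decompose_segregation(ea, ind, by = "component")
    d$estimate[d$stratum == "both_in_home_tract"] -
      d$estimate[d$stratum == "neither_in_home_tract"]
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
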