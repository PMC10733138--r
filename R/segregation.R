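# Exposure-segregation estimators and decompositions.

new_estimate <- function(estimate, method, n_egos, n_obs = NA_integer_,
                         stratum = NA_character_, ci_low = NA_real_,
                         ci_high = NA_real_, note = NA_character_) {
  out <- tibble::tibble(stratum = stratum, method = method,
                        estimate = estimate, ci_low = ci_low,
                        ci_high = ci_high, n_egos = n_egos, n_obs = n_obs,
                        note = note)
  class(out) <- c("exposeg_estimate", class(out))
  out
}

#' Naive exposure segregation
#'
#' The sample Pearson correlation between each ego's SES and the mean SES
#' of their (deduplicated) exposure partners. Downward-biased when partner
#' samples are sparse; see [fit_mixed_model()] for the corrected
#' estimator.
#'
#' @param records An [build_ego_records()] tibble (`ego`, `x`, `y`).
#' @return A one-row `exposeg_estimate` tibble; when either vector has
#'   zero variance the estimate is `NA` with `note = "zero_variance"`.
#' @export
naive_exposure_segregation <- function(records) {
  by_ego <- dplyr::summarise(dplyr::group_by(records, .data$ego),
                             x = .data$x[1], ybar = mean(.data$y),
                             .groups = "drop")
  if (nrow(by_ego) < 2) stop("need >= 2 egos for a correlation")
  if (sd(by_ego$x) == 0 || sd(by_ego$ybar) == 0) {
    return(new_estimate(NA_real_, "naive", nrow(by_ego), nrow(records),
                        note = "zero_variance"))
  }
  new_estimate(cor(by_ego$x, by_ego$ybar), "naive", nrow(by_ego),
               nrow(records))
}

#' Corrected exposure segregation from a mixed-model fit
#'
#' The model-implied correlation between ego SES and the latent mean SES
#' of the ego's exposure pool: `a / sqrt(a^2 + var1)` (ego SES has unit
#' variance by construction). Two degenerate regimes are recognised:
#' a perfect noiseless linear fit returns `sign(a)`; and when the fit is
#' statistically indistinguishable from the i.i.d. null (no slope, no
#' ego-level variance; `null_lrt_p > null_alpha`) the estimate is 0 with
#' `note = "random_mixing"`, the estimand's value under complete random
#' mixing — without this rule the plug-in ratio is unstable when `var1`
#' sits on its 0 boundary.
#'
#' @param fit An [fit_mixed_model()] result.
#' @param null_alpha Significance level of the random-mixing guard
#'   (default 0.001).
#' @return A one-row `exposeg_estimate` tibble with `method = "mixed"`.
#' @export
corrected_exposure_segregation <- function(fit, null_alpha = 0.001) {
  stopifnot(inherits(fit, "exposeg_mixfit"))
  if (!fit$converged) {
    return(new_estimate(NA_real_, "mixed", fit$n_egos, fit$n_obs,
                        note = "not_converged"))
  }
  if (!is.na(fit$degenerate) && fit$degenerate == "zero_variance") {
    return(new_estimate(0, "mixed", fit$n_egos, fit$n_obs,
                        note = "zero_variance"))
  }
  if (!is.na(fit$degenerate) && fit$degenerate == "perfect_fit") {
    return(new_estimate(sign(fit$a), "mixed", fit$n_egos, fit$n_obs,
                        note = "perfect_fit"))
  }
  if (fit$a == 0 && fit$var1 == 0) {
    return(new_estimate(0, "mixed", fit$n_egos, fit$n_obs,
                        note = "degenerate_zero"))
  }
  if (fit$null_lrt_p > null_alpha) {
    return(new_estimate(0, "mixed", fit$n_egos, fit$n_obs,
                        note = "random_mixing"))
  }
  new_estimate(fit$a / sqrt(fit$a^2 + fit$var1), "mixed", fit$n_egos,
               fit$n_obs)
}

#' Estimate exposure segregation from ego records
#'
#' One-call wrapper: fits the mixed model (or the naive correlation) on
#' ego records and optionally attaches a percentile bootstrap CI that
#' resamples egos.
#'
#' @param records An [build_ego_records()] tibble.
#' @param method `"mixed"` (default) or `"naive"`.
#' @param n_boot Bootstrap replications for the CI (0 = no CI).
#' @param ci_level Confidence level (default 0.95).
#' @param seed Seed for the bootstrap resampling.
#' @return A one-row `exposeg_estimate` tibble.
#' @export
exposure_segregation <- function(records, method = c("mixed", "naive"),
                                 n_boot = 0, ci_level = 0.95, seed = 1) {
  method <- match.arg(method)
  point <- if (method == "mixed") {
    corrected_exposure_segregation(fit_mixed_model(records))
  } else {
    naive_exposure_segregation(records)
  }
  if (n_boot > 0 && is.finite(point$estimate)) {
    egos <- unique(records$ego)
    by_ego <- split(seq_len(nrow(records)), records$ego)
    stat <- function(ids) {
      rows <- unlist(by_ego[ids], use.names = FALSE)
      rec <- records[rows, ]
      # resampled egos repeat; relabel so repeats stay distinct egos
      rec$ego <- rep(seq_along(ids),
                     times = lengths(by_ego[ids]))
      if (method == "mixed") {
        corrected_exposure_segregation(fit_mixed_model(rec))$estimate
      } else {
        naive_exposure_segregation(rec)$estimate
      }
    }
    bt <- bootstrap_ci(egos, stat, n_reps = n_boot, ci_level = ci_level,
                       seed = seed)
    point$ci_low <- bt$ci_low; point$ci_high <- bt$ci_high
  }
  point
}

#' Neighbourhood sorting index
#'
#' The Pearson correlation between each person's SES and the mean SES of
#' their home census tract (the ego included in the tract mean, matching
#' census-style computation). The static special case of exposure
#' segregation in which everyone is exposed uniformly to their tract's
#' co-residents.
#'
#' @param individuals Tibble with `ses` and `home_tract_id`.
#' @return A one-row `exposeg_estimate` tibble with `method = "nsi"`.
#' @export
neighbourhood_sorting_index <- function(individuals) {
  ind <- individuals[!is.na(individuals$home_tract_id), ]
  if (nrow(ind) < 2) stop("need >= 2 individuals with home tracts")
  if (length(unique(ind$home_tract_id)) < 2) {
    stop("neighbourhood sorting index is undefined with a single tract")
  }
  x <- as.numeric(scale(ind$ses))
  tract_mean <- stats::ave(x, ind$home_tract_id)
  if (sd(tract_mean) == 0) {
    return(new_estimate(NA_real_, "nsi", nrow(ind), note = "zero_variance"))
  }
  new_estimate(cor(x, tract_mean), "nsi", nrow(ind))
}

#' Synthetic within-tract exposure network
#'
#' The exposure network implied by the neighbourhood-sorting-index
#' assumptions: each person is exposed only to co-residents of their home
#' tract, uniformly at random. With `partners_per_ego = "all"` the network
#' is dense and exposure segregation on it reproduces the neighbourhood
#' sorting index (up to the ego-inclusion convention); sparse draws
#' exercise the attenuation correction.
#'
#' @param individuals Tibble with `user_id`, `home_tract_id`.
#' @param partners_per_ego `"all"` or a count of uniform draws without
#'   replacement per ego.
#' @param seed Seed for the draws.
#' @return An edge tibble compatible with [build_ego_records()]. Residents
#'   of single-occupant tracts get no partners (logged via message).
#' @export
synthetic_tract_network <- function(individuals, partners_per_ego = "all",
                                    seed = 1) {
  ind <- individuals[!is.na(individuals$home_tract_id), ]
  set.seed(seed)
  singles <- 0L
  rows <- lapply(split(ind$user_id, ind$home_tract_id), function(ids) {
    if (length(ids) < 2) { singles <<- singles + length(ids); return(NULL) }
    if (identical(partners_per_ego, "all")) {
      pr <- t(utils::combn(ids, 2))
      return(tibble::tibble(user_i = pr[, 1], user_j = pr[, 2]))
    }
    m <- min(partners_per_ego, length(ids) - 1)
    purrr::map_dfr(ids, function(ego) {
      tibble::tibble(user_i = ego,
                     user_j = sample(setdiff(ids, ego), m))
    })
  })
  if (singles > 0) {
    message(singles, " resident(s) of single-occupant tracts have no partners")
  }
  e <- dplyr::bind_rows(rows)
  if (nrow(e) == 0) return(empty_edge_table())
  ui <- pmin(e$user_i, e$user_j); uj <- pmax(e$user_i, e$user_j)
  e$user_i <- ui; e$user_j <- uj
  e <- dplyr::distinct(e, .data$user_i, .data$user_j)
  dplyr::mutate(e, k = 1L, t = NA_real_, lat = NA_real_, lon = NA_real_)
}

#' Decompose exposure segregation by stratum
#'
#' Rebuilds ego records per stratum (partner deduplication within stratum)
#' and re-estimates segregation with the mixed model. Strata failing the
#' estimator's preconditions are reported as not-estimable rows rather
#' than errors.
#'
#' @param edges Annotated edge tibble.
#' @param individuals Individual tibble with `ses`.
#' @param by `"component"`, `"tie_bin"`, `"poi_category"`,
#'   `"time_window"` or `"hub"`.
#' @param window_h Width of the time-of-day windows in hours (default 3).
#' @param timezone_offset Hours added to UTC for the time windows.
#' @param region,method,n_boot,seed Passed to [exposure_segregation()].
#' @return An `exposeg_estimate` tibble, one row per stratum.
#' @export
decompose_segregation <- function(edges, individuals,
                                  by = c("component", "tie_bin",
                                         "poi_category", "time_window",
                                         "hub"),
                                  window_h = 3, timezone_offset = 0,
                                  region = NULL,
                                  method = c("mixed", "naive"),
                                  n_boot = 0, seed = 1) {
  by <- match.arg(by)
  method <- match.arg(method)
  e <- edges
  if (by == "tie_bin" && !"tie_bin" %in% names(e)) {
    e <- stratify_by_tie_strength(e)
  }
  if (by == "time_window") {
    hh <- ((e$t / 3600 + timezone_offset) %% 24)
    lo <- floor(hh / window_h) * window_h
    e$time_window <- sprintf("%02d-%02d", lo, lo + window_h)
  }
  if (by == "hub") e$hub <- e$hub_id
  e <- e[!is.na(e[[by]]), ]
  strata <- sort(unique(as.character(e[[by]])))
  purrr::map_dfr(strata, function(s) {
    sub <- e[as.character(e[[by]]) == s, ]
    res <- tryCatch({
      rec <- build_ego_records(sub, individuals, region = region)
      exposure_segregation(rec, method = method, n_boot = n_boot,
                           seed = seed)
    }, error = function(err) {
      new_estimate(NA_real_, method, n_egos = NA_integer_,
                   note = paste0("not_estimable: ", conditionMessage(err)))
    })
    res$stratum <- s
    res
  })
}
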