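#' Pipeline configuration
#'
#' A single serializable object driving [run_pipeline()]: the synthetic
#' city (or input paths), detection thresholds, home-inference parameters,
#' SES options, and inference settings. Serializes to/from a single
#' human-readable JSON file with [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param city A [city_config()] for synthetic generation.
#' @param thresholds An [exposure_thresholds()].
#' @param home_params A [home_inference_params()]; defaults inherit the
#'   city's night window and timezone.
#' @param winsor_cap SES winsorization cap (USD/month).
#' @param max_link_distance_m Home-to-property link cutoff.
#' @param collapse Collapse co-presence episodes in detection.
#' @param n_boot Bootstrap replications for the headline CI (0 = none).
#' @param seed Pipeline-level seed (bootstraps, synthetic tract draws).
#' @param out_dir Optional directory in which each stage writes its
#'   artifact (enables resuming from intermediates).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(city = city_config(),
                            thresholds = exposure_thresholds(),
                            home_params = NULL,
                            winsor_cap = 20000,
                            max_link_distance_m = 100,
                            collapse = TRUE,
                            n_boot = 0,
                            seed = 1,
                            out_dir = NULL) {
  if (is.null(home_params)) {
    home_params <- home_inference_params(
      night_start = city$night_start, night_end = city$night_end,
      timezone_offset = city$timezone_offset)
  }
  structure(list(city = city, thresholds = thresholds,
                 home_params = home_params, winsor_cap = winsor_cap,
                 max_link_distance_m = max_link_distance_m,
                 collapse = collapse, n_boot = n_boot, seed = seed,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  ser <- rapply(unclass(config), identity, how = "list")
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cc <- raw$city; cc$anchor <- as.numeric(cc$anchor)
  pipeline_config(
    city = do.call(city_config, cc),
    thresholds = exposure_thresholds(raw$thresholds$D, raw$thresholds$T),
    home_params = do.call(home_inference_params, raw$home_params),
    winsor_cap = raw$winsor_cap,
    max_link_distance_m = raw$max_link_distance_m,
    collapse = raw$collapse, n_boot = raw$n_boot, seed = raw$seed,
    out_dir = raw$out_dir
  )
}

#' Run the full exposure-segregation pipeline on a synthetic city
#'
#' Executes simulate -> filter/dedupe pings -> infer homes -> link SES ->
#' build network -> annotate -> segregate (overall, naive, NSI, component
#' decomposition) -> bridging index, logging per-stage record counts so
#' the filter cascade is auditable. When `config$out_dir` is set, each
#' stage writes its artifact there and completed stages are reloaded on a
#' rerun instead of recomputed.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage messages.
#' @return A list of class `exposeg_result`: `individuals`, `edges`
#'   (annotated), `estimates` (an `exposeg_estimate` tibble stacking the
#'   overall mixed/naive estimates, the neighbourhood sorting index and
#'   the component decomposition), `bridging`, `log` (stage record
#'   counts), and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  say <- function(...) if (!quiet) message(...)
  out_dir <- config$out_dir
  artifact <- function(name) {
    if (is.null(out_dir)) NULL else file.path(out_dir, name)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  stage <- function(name, reader, writer, compute) {
    path <- artifact(name)
    if (!is.null(path) && file.exists(path)) {
      say("stage ", name, ": reusing cached artifact")
      return(reader(path))
    }
    val <- compute()
    if (!is.null(path)) writer(val, path)
    val
  }

  city <- generate_city(config$city)
  traces <- generate_traces(city, config$thresholds)
  log$raw_pings <- nrow(traces$pings)

  pings <- stage("pings_filtered.csv", read_pings, write_pings, function() {
    p <- filter_pings(traces$pings, 100)
    log$accuracy_kept <<- nrow(p)
    p <- dedupe_duplicate_users(p)
    log$after_dedupe <<- nrow(p)
    log$removed_duplicates <<- length(attr(p, "removed_user_ids"))
    p
  })
  say("pings: ", log$raw_pings %||% nrow(traces$pings), " raw, ",
      nrow(pings), " after filters")

  individuals <- stage(
    "individuals.csv", read_individuals, write_individuals, function() {
      hm <- infer_homes(pings, config$home_params)
      log$homes_inferred <<- nrow(hm$homes)
      ind <- link_ses(hm$homes, city$registry, config$max_link_distance_m)
      ind <- winsorize_ses(ind, config$winsor_cap)
      ind <- filter_identical_homes(ind)
      ind <- filter_shared_property(ind)
      ind <- assign_home_tract(ind, city$tract_layer)
      ind <- ind[!is.na(ind$home_tract_id), ]
      log$individuals_final <<- nrow(ind)
      ind
    })
  say("individuals: ", nrow(individuals), " with home, SES and tract")
  if (nrow(individuals) < 2) stop("pipeline stage 'link-ses' failed: ",
                                  "fewer than 2 usable individuals")

  edges <- stage("edges.csv", read_edges, write_edges, function() {
    e <- find_path_crossings(pings, config$thresholds,
                             collapse = config$collapse)
    e <- e[e$user_i %in% individuals$user_id &
             e$user_j %in% individuals$user_id, ]
    annotate_exposures(e, individuals, city$tract_layer, city$poi_layer,
                       city$hub_layer)
  })
  log$exposures <- nrow(edges)
  say("network: ", nrow(edges), " exposures")
  if (nrow(edges) == 0) stop("pipeline stage 'build-network' failed: ",
                             "no exposures detected")

  records <- build_ego_records(edges, individuals)
  est_mixed <- exposure_segregation(records, "mixed",
                                    n_boot = config$n_boot,
                                    seed = config$seed)
  est_naive <- exposure_segregation(records, "naive")
  nsi <- neighbourhood_sorting_index(individuals)
  comp <- decompose_segregation(edges, individuals, by = "component")
  est_mixed$stratum <- "overall"; est_naive$stratum <- "overall"
  nsi$stratum <- "overall"
  estimates <- dplyr::bind_rows(est_mixed, est_naive, nsi, comp)
  class(estimates) <- unique(c("exposeg_estimate", class(estimates)))

  bridging <- bridging_index(individuals, city$hub_layer)
  say("segregation (mixed): ", signif(est_mixed$estimate, 3),
      "; bridging index: ", signif(bridging$index, 3))

  res <- structure(
    list(individuals = individuals, edges = edges, estimates = estimates,
         bridging = bridging, log = log, config = config, city = city),
    class = "exposeg_result"
  )
  if (!is.null(out_dir)) {
    report <- dplyr::mutate(estimates,
                            bridging_index = bridging$index)
    write_plain_csv(report, file.path(out_dir, "report.csv"))
  }
  res
}

#' @export
print.exposeg_result <- function(x, ...) {
  cat("<exposeg_result>\n")
  print(x$estimates)
  print(x$bridging)
  invisible(x)
}
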