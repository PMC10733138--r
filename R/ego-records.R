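#' Build ego-exposure records from a network
#'
#' For every region resident with at least one exposure partner, collects
#' the SES values of the distinct people they crossed paths with. Repeated
#' exposures to the same partner are not upweighted: partners are
#' deduplicated per ego (per stratum when `strata` columns are given). Ego
#' SES `x` is standardized to zero mean and unit variance across the egos
#' entering the estimation; partner SES `y` stays on its raw (winsorized)
#' scale, which leaves correlations unchanged. Only egos are
#' region-restricted; partners living outside the region still contribute
#' their SES.
#'
#' @param edges Edge tibble from [find_path_crossings()] (optionally
#'   annotated).
#' @param individuals Tibble with `user_id`, `ses` and (if `region` is
#'   used) a `region` column.
#' @param region Optional region label; egos are individuals whose
#'   `region` equals it.
#' @param strata Optional character vector of edge columns to carry as
#'   stratum labels; partner deduplication is then per ego-stratum.
#' @return A long tibble (`ego`, `x`, `y`, `partner`, strata columns) of
#'   class `ego_records`, with attributes `x_center`, `x_scale`, `n_egos`.
#' @export
build_ego_records <- function(edges, individuals, region = NULL,
                              strata = NULL) {
  stopifnot(all(c("user_id", "ses") %in% names(individuals)))
  egos <- individuals
  if (!is.null(region)) {
    if (!"region" %in% names(individuals)) {
      stop("individuals need a 'region' column to restrict egos by region")
    }
    egos <- individuals[!is.na(individuals$region) &
                          individuals$region == region, ]
  }
  keep <- c("user_i", "user_j", strata)
  missing <- setdiff(keep, names(edges))
  if (length(missing)) {
    stop("edges are missing stratum column(s): ",
         paste(missing, collapse = ", "))
  }
  e <- edges[, keep]
  both <- dplyr::bind_rows(
    stats::setNames(e, c("ego", "partner", strata)),
    stats::setNames(e[, c("user_j", "user_i", strata)],
                    c("ego", "partner", strata))
  )
  both <- both[both$ego %in% egos$user_id, ]
  both <- both[both$partner %in% individuals$user_id, ]
  both <- dplyr::distinct(both) # dedup partners per ego (per stratum)
  if (length(unique(both$ego)) < 2) {
    stop("region has fewer than 2 egos with exposure partners; ",
         "exposure segregation is not estimable")
  }
  x_raw <- individuals$ses[match(both$ego, individuals$user_id)]
  ego_x <- tapply(x_raw, both$ego, `[`, 1)
  x_center <- mean(ego_x); x_scale <- sd(ego_x)
  if (x_scale == 0) x_scale <- 1 # degenerate; flagged downstream by fit
  out <- tibble::tibble(
    ego = both$ego,
    x = (x_raw - x_center) / x_scale,
    y = individuals$ses[match(both$partner, individuals$user_id)],
    partner = both$partner
  )
  for (s in strata) out[[s]] <- both[[s]]
  structure(out, x_center = x_center, x_scale = x_scale,
            n_egos = length(ego_x),
            class = c("ego_records", class(out)))
}
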