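#' Space-time thresholds for path-crossing detection
#'
#' Two pings from distinct devices form an exposure when they are strictly
#' closer than `D` metres (great-circle) and strictly closer than `T`
#' minutes in time.
#'
#' @param D Distance threshold in metres (default 50).
#' @param T Time threshold in minutes (default 5).
#' @return A list of class `exposure_thresholds`.
#' @export
exposure_thresholds <- function(D = 50, T = 5) {
  if (D <= 0 || T <= 0) stop("thresholds D and T must be > 0")
  structure(list(D = D, T = T), class = "exposure_thresholds")
}

#' Remove duplicate devices
#'
#' For each ordered pair of devices (u, v), u is removed when more than 80%
#' of u's pings have latitude, longitude and timestamp exactly identical to
#' pings of v (the signature of one person carrying two devices). When both
#' directions exceed the threshold, only one device is removed: the one
#' with fewer pings, then the lexicographically larger id.
#'
#' @param pings A ping tibble.
#' @param frac Overlap fraction above which a device counts as a duplicate
#'   (default 0.8, strict inequality).
#' @return The ping tibble without the removed devices; removed ids in
#'   `attr(, "removed_user_ids")`.
#' @export
dedupe_duplicate_users <- function(pings, frac = 0.8) {
  check_ping_table(pings, need_accuracy = FALSE)
  if (nrow(pings) == 0) {
    attr(pings, "removed_user_ids") <- character(0)
    return(pings)
  }
  dt <- data.table::data.table(
    user_id = pings$user_id,
    trip = paste(sprintf("%.17g", pings$timestamp_s),
                 sprintf("%.17g", pings$lat), sprintf("%.17g", pings$lon))
  )
  n_by_user <- dt[, .N, by = user_id]
  # per (user, key): how many of the user's pings carry this exact triple
  uk <- dt[, .N, by = .(user_id, trip)]
  data.table::setkey(uk, trip)
  pairs <- uk[uk, on = "trip", allow.cartesian = TRUE][user_id != i.user_id]
  removed <- character(0)
  if (nrow(pairs) > 0) {
    # u = user_id matches against v = i.user_id; u's matched ping count = N
    overlap <- pairs[, .(matched = sum(N)), by = .(u = user_id, v = i.user_id)]
    overlap <- merge(overlap, n_by_user, by.x = "u", by.y = "user_id")
    overlap[, frac_u := matched / N]
    hits <- overlap[frac_u > frac]
    if (nrow(hits) > 0) {
      key_uv <- paste(pmin(hits$u, hits$v), pmax(hits$u, hits$v))
      mutual <- key_uv %in% key_uv[duplicated(key_uv)]
      npings <- setNames(n_by_user$N, n_by_user$user_id)
      removed <- unique(c(
        hits$u[!mutual],
        vapply(unique(key_uv[mutual]), function(k) {
          uv <- strsplit(k, " ", fixed = TRUE)[[1]]
          if (npings[uv[1]] != npings[uv[2]]) {
            uv[which.min(npings[uv])]
          } else {
            max(uv)
          }
        }, character(1), USE.NAMES = FALSE)
      ))
    }
  }
  out <- pings[!(pings$user_id %in% removed), ]
  attr(out, "removed_user_ids") <- sort(removed)
  out
}

#' Detect space-time path crossings
#'
#' Finds every pair of pings from distinct devices within the thresholds of
#' [exposure_thresholds()] and assembles exposure edges: `t` is the minimum
#' of the two ping timestamps and `lat`/`lon` the average of the two ping
#' coordinates. Candidate pairs come from a uniform-grid spatial index over
#' locally projected coordinates crossed with time buckets of width `T`, so
#' only the 3 x 3 x 3 neighbouring cells are scanned; every candidate is
#' exact-refined with the haversine distance. Worst case is O(n^2) when all
#' pings share one cell (everyone at one venue at once); with bounded cell
#' occupancy the cost is near-linear. Input timestamps may be unsorted;
#' rows with non-finite coordinates are dropped with a message.
#'
#' By default, consecutive qualifying ping-pairs of the same dyad whose
#' inter-event time gaps are below `T` are collapsed into one exposure
#' episode carrying the attributes of the first qualifying pair
#' (`collapse = FALSE` keeps raw ping-pair events).
#'
#' @param pings A filtered, de-duplicated ping tibble.
#' @param thresholds An [exposure_thresholds()].
#' @param collapse Collapse co-presence episodes (default `TRUE`).
#' @return An edge tibble: `user_i`, `user_j` (unordered pair stored with
#'   `user_i < user_j`), `k` (occurrence index per dyad), `t`, `lat`, `lon`.
#' @export
find_path_crossings <- function(pings, thresholds = exposure_thresholds(),
                                collapse = TRUE) {
  check_ping_table(pings, need_accuracy = FALSE)
  bad <- !is.finite(pings$lat) | !is.finite(pings$lon) |
    !is.finite(pings$timestamp_s)
  if (any(bad)) {
    message("dropping ", sum(bad), " ping(s) with non-finite coordinates")
    pings <- pings[!bad, ]
  }
  if (nrow(pings) < 2) return(empty_edge_table())
  D <- thresholds$D; T_sec <- thresholds$T * 60
  anchor <- c(mean(range(pings$lon)), mean(range(pings$lat)))
  xy <- local_project(pings$lon, pings$lat, anchor)
  cs <- D * 1.05
  dt <- data.table::data.table(
    row_id = seq_len(nrow(pings)), user_id = pings$user_id,
    t = pings$timestamp_s, lat = pings$lat, lon = pings$lon,
    cell_x = as.integer(floor(xy$x / cs)),
    cell_y = as.integer(floor(xy$y / cs)),
    cell_t = as.integer(floor(pings$timestamp_s / T_sec))
  )
  data.table::setkey(dt, cell_x, cell_y, cell_t)
  offsets <- data.table::CJ(dx = -1:1, dy = -1:1, dtt = -1:1)
  found <- vector("list", nrow(offsets))
  for (o in seq_len(nrow(offsets))) {
    probe <- data.table::data.table(
      cell_x = dt$cell_x + offsets$dx[o],
      cell_y = dt$cell_y + offsets$dy[o],
      cell_t = dt$cell_t + offsets$dtt[o],
      row_id = dt$row_id, user_id = dt$user_id,
      t = dt$t, lat = dt$lat, lon = dt$lon
    )
    m <- dt[probe, on = .(cell_x, cell_y, cell_t),
            allow.cartesian = TRUE, nomatch = NULL]
    m <- m[row_id < i.row_id & user_id != i.user_id &
             abs(t - i.t) < T_sec]
    if (nrow(m) == 0) next
    dd <- haversine_m(m$lon, m$lat, m$i.lon, m$i.lat)
    m <- m[dd < D]
    found[[o]] <- m
  }
  cand <- data.table::rbindlist(found)
  if (is.null(cand) || nrow(cand) == 0) return(empty_edge_table())
  edges <- edge_attributes(cand$user_id, cand$i.user_id, cand$t, cand$i.t,
                           cand$lat, cand$i.lat, cand$lon, cand$i.lon)
  finalize_edges(edges, T_sec, collapse)
}

#' Brute-force path-crossing oracle
#'
#' Exhaustive all-pairs scan applying the identical space-time predicate
#' and episode-collapse rule as [find_path_crossings()]; the reference
#' implementation for verification. Refuses inputs above `cap` pings.
#'
#' @inheritParams find_path_crossings
#' @param cap Maximum ping count (default 50000).
#' @return An edge tibble, as [find_path_crossings()].
#' @export
find_path_crossings_bruteforce <- function(pings,
                                           thresholds = exposure_thresholds(),
                                           collapse = TRUE, cap = 50000) {
  check_ping_table(pings, need_accuracy = FALSE)
  if (nrow(pings) > cap) {
    stop("brute-force oracle refused: ", nrow(pings), " pings exceeds cap ",
         cap)
  }
  bad <- !is.finite(pings$lat) | !is.finite(pings$lon) |
    !is.finite(pings$timestamp_s)
  pings <- pings[!bad, ]
  n <- nrow(pings)
  if (n < 2) return(empty_edge_table())
  D <- thresholds$D; T_sec <- thresholds$T * 60
  blocks <- split(seq_len(n), ceiling(seq_len(n) / 1000))
  acc <- list()
  for (a in seq_along(blocks)) {
    for (b in a:length(blocks)) {
      ia <- blocks[[a]]; ib <- blocks[[b]]
      pr <- expand.grid(i = ia, j = ib)
      pr <- pr[pr$i < pr$j, , drop = FALSE]
      if (!nrow(pr)) next
      ok <- pings$user_id[pr$i] != pings$user_id[pr$j] &
        abs(pings$timestamp_s[pr$i] - pings$timestamp_s[pr$j]) < T_sec
      pr <- pr[ok, , drop = FALSE]
      if (!nrow(pr)) next
      dd <- haversine_m(pings$lon[pr$i], pings$lat[pr$i],
                        pings$lon[pr$j], pings$lat[pr$j])
      pr <- pr[dd < D, , drop = FALSE]
      if (!nrow(pr)) next
      acc[[length(acc) + 1L]] <- edge_attributes(
        pings$user_id[pr$i], pings$user_id[pr$j],
        pings$timestamp_s[pr$i], pings$timestamp_s[pr$j],
        pings$lat[pr$i], pings$lat[pr$j],
        pings$lon[pr$i], pings$lon[pr$j])
    }
  }
  if (!length(acc)) return(empty_edge_table())
  finalize_edges(data.table::rbindlist(acc), T_sec, collapse)
}

# Unordered-pair edge attributes from qualifying ping pairs.
edge_attributes <- function(u1, u2, t1, t2, lat1, lat2, lon1, lon2) {
  data.table::data.table(
    user_i = pmin(u1, u2), user_j = pmax(u1, u2),
    t = pmin(t1, t2), lat = (lat1 + lat2) / 2, lon = (lon1 + lon2) / 2
  )
}

# Sort deterministically, optionally collapse episodes, index k per dyad.
finalize_edges <- function(edges, T_sec, collapse) {
  data.table::setorder(edges, user_i, user_j, t, lat, lon)
  if (collapse) {
    edges[, new_episode := c(TRUE, diff(t) >= T_sec),
          by = .(user_i, user_j)]
    edges <- edges[new_episode == TRUE]
    edges$new_episode <- NULL
  }
  edges[, k := seq_len(.N), by = .(user_i, user_j)]
  tibble::as_tibble(edges[, .(user_i, user_j, k, t, lat, lon)])
}

empty_edge_table <- function() {
  tibble::tibble(user_i = character(0), user_j = character(0),
                 k = integer(0), t = numeric(0), lat = numeric(0),
                 lon = numeric(0))
}

#' Tie strength of a dyad and stratification by tie strength
#'
#' `tie_strength()` counts exposure events between one unordered pair of
#' devices (0 for an unseen dyad). `stratify_by_tie_strength()` labels each
#' edge with its dyad's event count binned as 1, 2, 3, 4, "5+".
#'
#' @param edges An edge tibble from [find_path_crossings()].
#' @param dyad Character vector of two user ids.
#' @return `tie_strength()`: integer count. `stratify_by_tie_strength()`:
#'   `edges` with a `tie_bin` factor column.
#' @export
tie_strength <- function(edges, dyad) {
  stopifnot(length(dyad) == 2)
  i <- min(dyad); j <- max(dyad)
  sum(edges$user_i == i & edges$user_j == j)
}

#' @rdname tie_strength
#' @export
stratify_by_tie_strength <- function(edges) {
  counts <- dplyr::count(edges, .data$user_i, .data$user_j,
                         name = "n_events")
  out <- dplyr::left_join(edges, counts, by = c("user_i", "user_j"))
  out$tie_bin <- factor(
    ifelse(out$n_events >= 5, "5+", as.character(out$n_events)),
    levels = c("1", "2", "3", "4", "5+")
  )
  out$n_events <- NULL
  out
}
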