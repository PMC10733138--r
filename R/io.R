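# Delimited-table I/O with schema validation. All tables are plain CSV;
# coordinates are WGS84 decimal degrees, timestamps epoch seconds UTC.
# Doubles are written with full precision so write -> read round-trips
# within 1e-9 degrees.

read_schema_csv <- function(path, schema, required) {
  dt <- data.table::fread(path, colClasses = NULL, showProgress = FALSE)
  missing <- setdiff(names(schema), names(dt))
  if (length(missing)) {
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  out <- tibble::as_tibble(dt)
  for (col in names(schema)) {
    target <- schema[[col]]
    if (target == "numeric" && !is.numeric(out[[col]])) {
      coerced <- suppressWarnings(as.numeric(out[[col]]))
      bad <- which(is.na(coerced) & !is.na(out[[col]]))
      if (length(bad)) {
        stop("column '", col, "' has a malformed value at row ", bad[1],
             " of ", path)
      }
      out[[col]] <- coerced
    }
    if (target == "character") out[[col]] <- as.character(out[[col]])
    if (col %in% required) {
      bad <- which(is.na(out[[col]]))
      if (length(bad)) {
        stop("column '", col, "' is missing (NA) at row ", bad[1],
             " of ", path)
      }
    }
  }
  out
}

write_plain_csv <- function(x, path) {
  data.table::fwrite(x, path, scipen = 50)
  invisible(path)
}

#' Read and write the pipeline's delimited tables
#'
#' Ping tables carry `user_id`, `timestamp_s`, `lat`, `lon`, `accuracy_m`;
#' property registries `property_id`, `lat`, `lon`, `rent_usd_month`;
#' individual tables `user_id`, `home_lat`, `home_lon`, `home_tract_id`,
#' `ses`; edge tables `user_i`, `user_j`, `k`, `t`, `lat`, `lon` plus any
#' annotation columns. Schema violations raise an error naming the column
#' and row.
#'
#' @param path File path.
#' @param pings,registry,individuals,edges Tibbles to write.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @export
read_pings <- function(path) {
  read_schema_csv(path,
                  c(user_id = "character", timestamp_s = "numeric",
                    lat = "numeric", lon = "numeric",
                    accuracy_m = "numeric"),
                  required = c("user_id", "timestamp_s", "lat", "lon"))
}

#' @rdname read_pings
#' @export
write_pings <- function(pings, path) write_plain_csv(pings, path)

#' @rdname read_pings
#' @export
read_registry <- function(path) {
  read_schema_csv(path,
                  c(property_id = "character", lat = "numeric",
                    lon = "numeric", rent_usd_month = "numeric"),
                  required = c("property_id", "lat", "lon",
                               "rent_usd_month"))
}

#' @rdname read_pings
#' @export
write_registry <- function(registry, path) write_plain_csv(registry, path)

#' @rdname read_pings
#' @export
read_individuals <- function(path) {
  read_schema_csv(path,
                  c(user_id = "character", home_lat = "numeric",
                    home_lon = "numeric", home_tract_id = "character",
                    ses = "numeric"),
                  required = c("user_id", "home_lat", "home_lon"))
}

#' @rdname read_pings
#' @export
write_individuals <- function(individuals, path) {
  write_plain_csv(individuals, path)
}

#' @rdname read_pings
#' @export
read_edges <- function(path) {
  read_schema_csv(path,
                  c(user_i = "character", user_j = "character",
                    k = "numeric", t = "numeric", lat = "numeric",
                    lon = "numeric"),
                  required = c("user_i", "user_j", "t"))
}

#' @rdname read_pings
#' @export
write_edges <- function(edges, path) write_plain_csv(edges, path)
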