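# Visitation records: one row per captured pollinator (or aggregated count)
# on one plant during one 30-min observation sample.

record_required_cols <- c(
  "plant", "pollinator", "guild", "location", "year", "season", "sample_id"
)
record_label_cols <- c(
  "plant", "pollinator", "guild", "location", "season", "sample_id"
)

#' Read a visitation-record table from CSV
#'
#' Reads tidy visitation records: one row per captured insect (or per
#' aggregated plant--pollinator--sample count). The file must carry the
#' header columns `plant, pollinator, guild, location, year, season,
#' sample_id`; `floral_abundance` and `count` are optional (`count`
#' defaults to 1 visit per row). Species labels are matched exactly,
#' case-sensitively, after whitespace trimming.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A validated tibble of visitation records with columns
#'   `plant, pollinator, guild, location, year, season, sample_id,
#'   floral_abundance, count`.
#' @seealso [build_matrix()], [subset_records()], [reduce_by_occurrence()]
#' @examples
#' path <- system.file("extdata", "toy_records.csv", package = "pollinet")
#' read_records(path)
#' @export
read_records <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("records file not found: ", path))
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  as_records(raw)
}

#' Validate a data frame of visitation records
#'
#' Coerces and validates a data frame against the record-table contract:
#' required columns present, `count` a positive integer, `floral_abundance`
#' non-negative or missing. Label columns are whitespace-trimmed. Row order
#' is preserved. All record-consuming functions call this on entry, so plain
#' data frames can be piped anywhere a record table is expected.
#'
#' @param x A data frame of visitation records.
#' @return A validated tibble with canonical column order.
#' @export
as_records <- function(x) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(record_required_cols, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "records are missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (!"count" %in% names(x)) x$count <- 1L
  if (!"floral_abundance" %in% names(x)) x$floral_abundance <- NA_real_

  for (col in record_label_cols) {
    x[[col]] <- trimws(as.character(x[[col]]))
  }
  year <- suppressWarnings(as.integer(as.numeric(x$year)))
  if (nrow(x) > 0 && anyNA(year)) {
    abort(paste0(
      "non-numeric year at row(s): ",
      paste(head(which(is.na(year)), 5), collapse = ", ")
    ))
  }
  x$year <- year

  cnt <- suppressWarnings(as.numeric(x$count))
  cnt[is.na(x$count)] <- NA_real_
  bad <- which(is.na(cnt) | cnt < 1 | cnt != round(cnt))
  if (length(bad) > 0) {
    abort(paste0(
      "count must be a positive integer; invalid at row(s): ",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  x$count <- as.integer(round(cnt))

  fa <- suppressWarnings(as.numeric(x$floral_abundance))
  bad_fa <- which(!is.na(fa) & fa < 0)
  if (length(bad_fa) > 0) {
    abort(paste0(
      "floral_abundance must be non-negative; invalid at row(s): ",
      paste(head(bad_fa, 5), collapse = ", ")
    ))
  }
  non_numeric <- which(!is.na(x$floral_abundance) & is.na(fa))
  if (length(non_numeric) > 0) {
    abort(paste0(
      "non-numeric floral_abundance at row(s): ",
      paste(head(non_numeric, 5), collapse = ", ")
    ))
  }
  x$floral_abundance <- fa

  x[, c(record_required_cols, "floral_abundance", "count")]
}

#' Filter visitation records by location, year and/or season
#'
#' Returns exactly the rows matching every supplied filter; with no filters
#' the table is returned unchanged. A filter that matches nothing produces a
#' warning (not an error) and an empty table. Used to carve the full record
#' set into location-specific, consecutive-year and seasonal networks.
#'
#' @param records A record table (see [as_records()]).
#' @param location Optional character vector of site labels to keep.
#' @param year Optional integer vector of years to keep.
#' @param season Optional season label(s) to keep (e.g. `"rainy"`, `"dry"`).
#' @return The filtered record tibble.
#' @export
subset_records <- function(records, location = NULL, year = NULL,
                           season = NULL) {
  records <- as_records(records)
  keep <- rep(TRUE, nrow(records))
  if (!is.null(location)) {
    hit <- records$location %in% location
    if (nrow(records) > 0 && !any(hit)) {
      warn(paste0(
        "location filter matched no rows: ",
        paste(location, collapse = ", ")
      ))
    }
    keep <- keep & hit
  }
  if (!is.null(year)) {
    hit <- records$year %in% as.integer(year)
    if (nrow(records) > 0 && !any(hit)) {
      warn(paste0("year filter matched no rows: ",
                  paste(year, collapse = ", ")))
    }
    keep <- keep & hit
  }
  if (!is.null(season)) {
    hit <- records$season %in% season
    if (nrow(records) > 0 && !any(hit)) {
      warn(paste0("season filter matched no rows: ",
                  paste(season, collapse = ", ")))
    }
    keep <- keep & hit
  }
  records[keep, , drop = FALSE]
}

#' Drop species found at fewer than a minimum number of locations
#'
#' Builds the "reduced" record set: every plant and every pollinator
#' retained must occur at `min_locations` or more distinct sampling
#' locations in the *input* table. The occurrence filter is single-pass --
#' location occurrence is computed once on the original table and removal of
#' a partner's rows never triggers re-evaluation -- so the retained species
#' sets are a function of the input alone.
#'
#' @param records A record table.
#' @param min_locations Minimum number of distinct locations a species must
#'   occur at (default 2). `min_locations = 1` is the identity.
#' @return The reduced record tibble.
#' @export
reduce_by_occurrence <- function(records, min_locations = 2L) {
  records <- as_records(records)
  if (!is.numeric(min_locations) || length(min_locations) != 1 ||
      is.na(min_locations) || min_locations < 1) {
    abort("`min_locations` must be a single integer >= 1")
  }
  min_locations <- as.integer(min_locations)
  plant_occ <- records |>
    dplyr::distinct(.data$plant, .data$location) |>
    dplyr::count(.data$plant, name = "n_loc")
  pol_occ <- records |>
    dplyr::distinct(.data$pollinator, .data$location) |>
    dplyr::count(.data$pollinator, name = "n_loc")
  keep_plants <- plant_occ$plant[plant_occ$n_loc >= min_locations]
  keep_pols <- pol_occ$pollinator[pol_occ$n_loc >= min_locations]
  records |>
    dplyr::filter(
      .data$plant %in% keep_plants,
      .data$pollinator %in% keep_pols
    )
}
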