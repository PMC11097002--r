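#' Read an occurrence table from delimited text
#'
#' Reads a CSV/TSV occurrence download and maps its columns onto the standard
#' record layout. Dates are parsed to (year, month); unparseable fields are
#' marked missing, never dropped at this stage — all filtering is deferred to
#' [clean_occurrences()] so that every exclusion is counted.
#'
#' @param path delimited text file; the delimiter is inferred from the
#'   extension (`.tsv`/`.txt` = tab, otherwise comma) unless `sep` is given.
#' @param column_map named list mapping the standard fields to file columns.
#'   Required entries: `species`, `lon`, `lat`, and either `date` (a parseable
#'   date column such as ISO `"2019-03-14"`) or both `year` and `month`.
#'   Optional: `record_id`.
#' @param sep field delimiter override.
#' @return data.frame with columns `record_id`, `species`, `lon`, `lat`,
#'   `year`, `month` (one raw record per input row).
#' @export
read_occurrences <- function(path,
                             column_map = list(species = "species",
                                               lon = "decimalLongitude",
                                               lat = "decimalLatitude",
                                               year = "year", month = "month",
                                               record_id = "record_id"),
                             sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "",
                           na.strings = c("NA", ""))
  has_date <- !is.null(column_map$date)
  needed <- c(column_map$species, column_map$lon, column_map$lat,
              if (has_date) column_map$date else c(column_map$year, column_map$month))
  missing_cols <- setdiff(unlist(needed), names(raw))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))

  n <- nrow(raw)
  out <- data.frame(
    record_id = if (!is.null(column_map$record_id) &&
                    column_map$record_id %in% names(raw))
      as.character(raw[[column_map$record_id]]) else sprintf("row%06d", seq_len(n)),
    species = as.character(raw[[column_map$species]]),
    lon = suppressWarnings(as.numeric(raw[[column_map$lon]])),
    lat = suppressWarnings(as.numeric(raw[[column_map$lat]])),
    stringsAsFactors = FALSE)
  if (has_date) {
    d <- as.Date(as.character(raw[[column_map$date]]), optional = TRUE)
    out$year <- as.integer(format(d, "%Y"))
    out$month <- as.integer(format(d, "%m"))
  } else {
    out$year <- suppressWarnings(as.integer(raw[[column_map$year]]))
    out$month <- suppressWarnings(as.integer(raw[[column_map$month]]))
  }
  out
}

#' Clean an occurrence table
#'
#' Applies the exclusion rules used for GBIF downloads: rows with a missing
#' species identification, missing or uncertain coordinates (missing, out of
#' range, or exactly (0, 0) — the canonical junk coordinate), or an unusable
#' event date are dropped; exact duplicates on
#' (species, lon, lat, year, month) are reduced to the first row in file
#' order. Each row is assigned exactly one fate, with reasons checked in the
#' fixed order: missing species, missing coordinates, out-of-range
#' coordinates, zero coordinates, missing date, duplicate.
#'
#' Cleaning never fails; it reports. The operation is idempotent.
#'
#' @param raw data.frame from [read_occurrences()].
#' @return list of class `cleaned_occurrences` with elements `records`
#'   (surviving rows) and `report` (class `cleaning_report`: named drop
#'   counts, input and survivor totals, and the coordinate-uncertainty rule
#'   applied).
#' @export
clean_occurrences <- function(raw) {
  n <- nrow(raw)
  fate <- rep(NA_character_, n)
  assign_fate <- function(cond, reason) {
    hit <- is.na(fate) & cond
    fate[hit] <<- reason
  }
  assign_fate(is.na(raw$species) | !nzchar(trimws(raw$species)), "missing_species")
  assign_fate(is.na(raw$lon) | is.na(raw$lat), "missing_coordinates")
  assign_fate(!is.na(raw$lon) & !is.na(raw$lat) &
                (abs(raw$lon) > 180 | abs(raw$lat) > 90 |
                   !is.finite(raw$lon) | !is.finite(raw$lat)),
              "out_of_range_coordinates")
  assign_fate(!is.na(raw$lon) & !is.na(raw$lat) & raw$lon == 0 & raw$lat == 0,
              "zero_coordinates")
  assign_fate(is.na(raw$year) | is.na(raw$month) |
                raw$month < 1 | raw$month > 12, "missing_date")
  key <- paste(raw$species, raw$lon, raw$lat, raw$year, raw$month, sep = "\r")
  key[!is.na(fate)] <- NA  # rows already dropped do not occupy a key
  assign_fate(!is.na(key) & duplicated(key), "duplicate")

  reasons <- c("missing_species", "missing_coordinates", "out_of_range_coordinates",
               "zero_coordinates", "missing_date", "duplicate")
  counts <- vapply(reasons, function(r) sum(fate == r, na.rm = TRUE), integer(1))
  records <- raw[is.na(fate), , drop = FALSE]
  rownames(records) <- NULL
  report <- structure(list(input_rows = n, survivors = nrow(records),
                           drops = as.list(counts),
                           coordinate_rule = "missing, |lon|>180, |lat|>90, or exactly (0,0)"),
                      class = "cleaning_report")
  structure(list(records = records, report = report), class = "cleaned_occurrences")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("cleaning_report: %d rows in, %d retained\n", x$input_rows, x$survivors))
  for (r in names(x$drops)) if (x$drops[[r]] > 0)
    cat(sprintf("  dropped %-26s %d\n", paste0(r, ":"), x$drops[[r]]))
  invisible(x)
}

#' @export
print.cleaned_occurrences <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Write a cleaning report as JSON
#' @param report a `cleaning_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
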