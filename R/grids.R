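#' Monthly lon/lat grid
#'
#' A regular longitude/latitude grid holding one environmental variable,
#' either static (elevation, harvested area) or resolved monthly over a
#' contiguous time axis (land-surface temperature, soil-moisture percentile).
#' Values are stored as an array with dimensions (lon, lat) or
#' (lon, lat, time); `NA` is the missing sentinel.
#'
#' @param variable variable name, one of `"LST_C"`, `"LST_K_SCALED"`,
#'   `"RZSM_PCT"`, `"ELEV_M"`, `"CROP_AREA"`.
#' @param lon,lat strictly increasing, regularly spaced axes of cell centers
#'   in decimal degrees.
#' @param values numeric array, `length(lon) x length(lat)` for static grids
#'   or `length(lon) x length(lat) x n_months` for monthly grids.
#' @param times `NULL` for a static grid, otherwise a data.frame with integer
#'   columns `year` and `month` forming a contiguous monthly sequence.
#' @param scale,offset linear decoding coefficients, used only for
#'   `"LST_K_SCALED"` digital numbers.
#' @return an object of class `monthly_grid`.
#' @export
monthly_grid <- function(variable, lon, lat, values, times = NULL,
                         scale = 1, offset = 0) {
  variable <- match.arg(variable,
                        c("LST_C", "LST_K_SCALED", "RZSM_PCT", "ELEV_M", "CROP_AREA"))
  check_axis(lon, "lon")
  check_axis(lat, "lat")
  if (!is.null(times)) {
    times <- as.data.frame(times)
    if (!all(c("year", "month") %in% names(times)))
      stop("times needs 'year' and 'month' columns")
    if (nrow(times) > 1) {
      idx <- times$year * 12L + (times$month - 1L)
      if (any(diff(idx) != 1L))
        stop("times must be a contiguous, strictly increasing monthly sequence")
    }
    if (any(times$month < 1L | times$month > 12L)) stop("months must be in 1..12")
    expected_dim <- c(length(lon), length(lat), nrow(times))
  } else {
    expected_dim <- c(length(lon), length(lat))
  }
  values <- array(as.numeric(values), dim = expected_dim)
  if (variable == "RZSM_PCT") {
    bad <- !is.na(values) & (values < 0 | values > 100)
    if (any(bad)) stop("RZSM_PCT values must lie in [0, 100] or be missing")
  }
  structure(list(variable = variable, lon = lon, lat = lat,
                 times = times, values = values,
                 scale = scale, offset = offset),
            class = "monthly_grid")
}

check_axis <- function(x, name) {
  if (length(x) < 1L || anyNA(x)) stop("axis '", name, "' must be non-empty and finite")
  if (length(x) > 1L) {
    d <- diff(x)
    if (any(d <= 0)) stop("axis '", name, "' must be strictly increasing")
    if (diff(range(d)) > 1e-9)
      stop("axis '", name, "' must be regular (constant spacing within 1e-9 degrees)")
  }
  invisible(x)
}

#' @export
print.monthly_grid <- function(x, ...) {
  nt <- if (is.null(x$times)) "static" else paste0(nrow(x$times), " months")
  cat(sprintf("monthly_grid '%s': %d x %d cells, %s\n",
              x$variable, length(x$lon), length(x$lat), nt))
  cat(sprintf("  lon [%g, %g], lat [%g, %g]\n",
              min(x$lon), max(x$lon), min(x$lat), max(x$lat)))
  invisible(x)
}

axis_spacing <- function(axis) if (length(axis) > 1L) axis[2] - axis[1] else 1

# Nearest cell index along one axis; ties go to the lower index, points more
# than half a cell outside the axis return NA (no extrapolation).
nearest_index <- function(axis, x) {
  s <- axis_spacing(axis)
  idx <- vapply(x, function(xi) {
    if (is.na(xi)) return(NA_integer_)
    if (xi < axis[1] - s / 2 || xi > axis[length(axis)] + s / 2) return(NA_integer_)
    which.min(abs(axis - xi))  # first minimum = lower index on exact ties
  }, integer(1))
  idx
}

time_index <- function(grid, year, month) {
  if (is.null(grid$times)) return(rep(NA_integer_, length(year)))
  y0 <- grid$times$year[1]; m0 <- grid$times$month[1]
  idx <- (year - y0) * 12L + (month - m0) + 1L
  idx[is.na(idx) | idx < 1L | idx > nrow(grid$times)] <- NA_integer_
  as.integer(idx)
}

#' Sample a grid at points
#'
#' Nearest-cell lookup (ties broken toward the lower index). Points outside
#' the grid bounds, or times outside the grid's monthly coverage, yield `NA`;
#' values are never extrapolated. A time passed to a static grid is ignored.
#'
#' @param grid a [monthly_grid].
#' @param lon,lat point coordinates in decimal degrees (vectorized).
#' @param year,month observation time; ignored for static grids.
#' @return numeric vector of sampled values with `NA` for misses.
#' @export
sample_grid <- function(grid, lon, lat, year = NULL, month = NULL) {
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  i <- nearest_index(grid$lon, lon)
  j <- nearest_index(grid$lat, lat)
  if (is.null(grid$times)) {
    out <- rep(NA_real_, n)
    ok <- !is.na(i) & !is.na(j)
    out[ok] <- grid$values[cbind(i[ok], j[ok])]
    return(out)
  }
  if (is.null(year) || is.null(month))
    stop("monthly grid '", grid$variable, "' requires year and month")
  year <- rep_len(year, n); month <- rep_len(month, n)
  k <- time_index(grid, year, month)
  out <- rep(NA_real_, n)
  ok <- !is.na(i) & !is.na(j) & !is.na(k)
  out[ok] <- grid$values[cbind(i[ok], j[ok], k[ok])]
  out
}

#' Write / read a grid as long-format CSV
#'
#' Plain-text serialization: one row per (cell, month) with columns
#' `lon, lat, year, month, value` (static grids omit year/month). Grid
#' metadata travels in a single JSON comment line prefixed `#` at the top of
#' the file.
#'
#' @param grid a [monthly_grid].
#' @param path file path.
#' @return `read_grid_csv` returns a [monthly_grid]; `write_grid_csv` its
#'   path, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  meta <- jsonlite::toJSON(list(variable = grid$variable,
                                scale = grid$scale, offset = grid$offset),
                           auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", meta), con)
  if (is.null(grid$times)) {
    df <- expand.grid(lon = grid$lon, lat = grid$lat, KEEP.OUT.ATTRS = FALSE)
    df$value <- as.vector(grid$values)
  } else {
    df <- expand.grid(lon = grid$lon, lat = grid$lat, t = seq_len(nrow(grid$times)),
                      KEEP.OUT.ATTRS = FALSE)
    df$year <- grid$times$year[df$t]
    df$month <- grid$times$month[df$t]
    df$value <- as.vector(grid$values)
    df$t <- NULL
    df <- df[, c("lon", "lat", "year", "month", "value")]
  }
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#")) stop("missing grid metadata header line")
  meta <- jsonlite::fromJSON(sub("^#", "", header))
  df <- utils::read.csv(path, comment.char = "#")
  lon <- sort(unique(df$lon)); lat <- sort(unique(df$lat))
  if (all(c("year", "month") %in% names(df))) {
    tcode <- df$year * 12L + df$month
    ut <- sort(unique(tcode))
    times <- data.frame(year = (ut - 1L) %/% 12L, month = (ut - 1L) %% 12L + 1L)
    vals <- array(NA_real_, c(length(lon), length(lat), length(ut)))
    vals[cbind(match(df$lon, lon), match(df$lat, lat), match(tcode, ut))] <- df$value
  } else {
    times <- NULL
    vals <- array(NA_real_, c(length(lon), length(lat)))
    vals[cbind(match(df$lon, lon), match(df$lat, lat))] <- df$value
  }
  monthly_grid(meta$variable, lon, lat, vals, times,
               scale = meta$scale %||% 1, offset = meta$offset %||% 0)
}
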