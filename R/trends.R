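#' High-elevation indicator
#'
#' Binary montane/lowland indicator. The trend analyses use a strict cutoff
#' (elevation must exceed 1000 m); the host-crop analysis uses the inclusive
#' reading ("1000 m or higher"). Both are explicit arguments rather than a
#' silently unified rule; negative elevations (below-sea-level records are
#' valid) are simply `FALSE`.
#'
#' @param elevation_m elevation in meters (vectorized; `NA` propagates).
#' @param cutoff cutoff in meters.
#' @param strict `TRUE` for `>` (trend analyses), `FALSE` for `>=` (host
#'   analysis).
#' @return logical vector.
#' @export
high_elevation_flag <- function(elevation_m, cutoff = 1000, strict = TRUE) {
  if (strict) elevation_m > cutoff else elevation_m >= cutoff
}

#' Elevation trend of one species
#'
#' Logistic trend of the high-elevation indicator on the year of
#' observation: the model behind the per-species log-odds table. Records
#' with missing elevation are excluded. An all-one or all-zero indicator is
#' the separation-degenerate case and is flagged, not fatal.
#'
#' @param occurrences records of one species with columns `year` and
#'   `elevation_m`.
#' @param cutoff elevation cutoff in meters (strict `>`).
#' @param t0,t1 odds-summary interval; defaults to the observed year range.
#' @return list: `fit` ([fit_logit_trend()] result), `odds`
#'   ([odds_summary()]), `table_row` (species-table-shaped data.frame:
#'   log-odds estimate, SE, Z, p).
#' @export
elevation_trend <- function(occurrences, cutoff = 1000,
                            t0 = NULL, t1 = NULL) {
  ok <- !is.na(occurrences$elevation_m) & !is.na(occurrences$year)
  occ <- occurrences[ok, , drop = FALSE]
  if (length(unique(occ$year)) < 2)
    stop("need records from at least 2 distinct years")
  ind <- as.numeric(high_elevation_flag(occ$elevation_m, cutoff, strict = TRUE))
  fit <- fit_logit_trend(occ$year, ind)
  t0 <- t0 %||% min(occ$year); t1 <- t1 %||% max(occ$year)
  odds <- odds_summary(fit, t0, t1)
  row <- data.frame(log_odds_estimate = fit$slope, se = fit$se_slope,
                    z = fit$z_wald, p = fit$p_wald,
                    separation = fit$separation, n = fit$n)
  list(fit = fit, odds = odds, table_row = row)
}

#' Monthly series at one location
#'
#' Compiles the aligned monthly LST and RZSM series at the grid cell nearest
#' to a point, plus its elevation and the lag-0 monthly coupling indicator
#' (a location's month either is or is not a coupling month; the three-lag
#' window applies to occurrence-linked analysis only).
#'
#' @param lon,lat location in decimal degrees.
#' @param lst,rzsm monthly [monthly_grid]s on a shared time axis.
#' @param elev static elevation [monthly_grid].
#' @param config a [coupling_config] (thresholds only; lag-0 is used).
#' @return object of class `location_series`: `lon`, `lat`, `elevation_m`,
#'   `times`, `lst_c`, `rzsm_pct`, `coupling` (logical, `NA` where a
#'   constituent is missing).
#' @export
build_location_series <- function(lon, lat, lst, rzsm, elev,
                                  config = coupling_config()) {
  if (is.null(lst$times) || is.null(rzsm$times))
    stop("lst and rzsm must be monthly grids")
  if (!identical(lst$times, rzsm$times))
    stop("lst and rzsm must share one monthly time axis")
  i <- nearest_index(lst$lon, lon); j <- nearest_index(lst$lat, lat)
  if (is.na(i) || is.na(j)) stop("location outside grid bounds")
  lst_c <- lst$values[i, j, ]
  rzsm_pct <- rzsm$values[i, j, ]
  structure(list(lon = lon, lat = lat,
                 elevation_m = sample_grid(elev, lon, lat),
                 times = lst$times, lst_c = lst_c, rzsm_pct = rzsm_pct,
                 coupling = coupling_at_lag(lst_c, rzsm_pct, config)),
            class = "location_series")
}

#' @export
print.location_series <- function(x, ...) {
  cat(sprintf("location_series (%.3f, %.3f), %.0f m: %d months, %d coupling months\n",
              x$lon, x$lat, x$elevation_m, nrow(x$times),
              sum(x$coupling, na.rm = TRUE)))
  invisible(x)
}

#' Environmental Mann-Kendall trends at a location
#'
#' Mann-Kendall test on the monthly LST and RZSM series of a location;
#' missing months are skipped pairwise. Fewer than 24 usable months yields a
#' missing result carrying the reason.
#'
#' @param series a [build_location_series()] result.
#' @param min_months minimum usable months per variable.
#' @return list with `lst` and `rzsm`, each an `mk_result`.
#' @export
location_env_trends <- function(series, min_months = 24) {
  one <- function(x) {
    if (sum(!is.na(x)) < min_months)
      structure(list(S = NA, var_S = NA, tau = NA, z = NA, p = NA,
                     n = sum(!is.na(x)),
                     reason = sprintf("fewer than %d months of data", min_months)),
                class = "mk_result")
    else mann_kendall(x)
  }
  list(lst = one(series$lst_c), rzsm = one(series$rzsm_pct))
}

#' Coupling-frequency trend at a location
#'
#' Logistic regression of the monthly coupling indicator on time (months
#' since the series start), with the odds/probability summary over the full
#' span and an increase/decrease/none classification: `increase` requires a
#' positive slope with Wald p below `alpha`, `decrease` a negative one; a
#' separation-flagged fit (e.g. a location where coupling never occurs) is
#' classified `none`.
#'
#' @param series a [build_location_series()] result.
#' @param config a [coupling_config] (thresholds for the monthly indicator).
#' @param alpha significance gate for the classification.
#' @param min_months minimum decidable months.
#' @return list: `fit`, `odds`, `class` (one of "increase", "decrease",
#'   "none"), `slope`, `p_wald`, `n_months`.
#' @export
coupling_frequency_trend <- function(series, config = coupling_config(),
                                     alpha = 0.05, min_months = 24) {
  y <- as.numeric(coupling_at_lag(series$lst_c, series$rzsm_pct, config))
  t <- seq_along(y)
  ok <- !is.na(y)
  if (sum(ok) < min_months)
    stop("fewer than ", min_months, " decidable months at this location")
  fit <- fit_logit_trend(t[ok], y[ok])
  odds <- odds_summary(fit, min(t[ok]), max(t[ok]))
  cls <- if (fit$separation || is.na(fit$p_wald)) "none"
  else if (fit$p_wald < alpha && fit$slope > 0) "increase"
  else if (fit$p_wald < alpha && fit$slope < 0) "decrease"
  else "none"
  list(fit = fit, odds = odds, class = cls,
       slope = fit$slope, p_wald = fit$p_wald, n_months = sum(ok))
}

#' Classify coupling trends across locations, stratified by elevation
#'
#' Runs [coupling_frequency_trend()] at every location and reports the
#' percentage of locations classified increase/decrease within the strata
#' above and below the elevation cutoff (strict `>` above). The remainder of
#' each stratum is implicitly "none"; an empty stratum is reported with
#' missing percentages.
#'
#' @param locations list of [build_location_series()] results.
#' @param cutoff elevation cutoff in meters.
#' @param alpha significance gate.
#' @param config a [coupling_config].
#' @return list: `per_location` (data.frame lon, lat, elevation_m, slope,
#'   p_wald, class), `above` and `below` (each `n`, `pct_increase`,
#'   `pct_decrease`).
#' @export
classify_all_locations <- function(locations, cutoff = 1000, alpha = 0.05,
                                   config = coupling_config()) {
  per <- do.call(rbind, lapply(locations, function(s) {
    tr <- coupling_frequency_trend(s, config, alpha)
    data.frame(lon = s$lon, lat = s$lat, elevation_m = s$elevation_m,
               slope = tr$slope, p_wald = tr$p_wald, class = tr$class)
  }))
  stratum <- function(rows) {
    if (!nrow(rows)) return(list(n = 0L, pct_increase = NA_real_,
                                 pct_decrease = NA_real_))
    list(n = nrow(rows),
         pct_increase = 100 * mean(rows$class == "increase"),
         pct_decrease = 100 * mean(rows$class == "decrease"))
  }
  above <- per[high_elevation_flag(per$elevation_m, cutoff, strict = TRUE), , drop = FALSE]
  below <- per[!high_elevation_flag(per$elevation_m, cutoff, strict = TRUE), , drop = FALSE]
  list(per_location = per, above = stratum(above), below = stratum(below),
       cutoff = cutoff, alpha = alpha)
}

#' Time-windowed PCA of one species' environment
#'
#' [pca_3var()] on (elevation, lag-1 LST, lag-1 RZSM) restricted to records
#' whose observation year falls inside the window. A window covering all
#' data reproduces the unwindowed PCA.
#'
#' @param enriched records of one species from [enrich_occurrences()].
#' @param years length-2 year range (inclusive).
#' @return a `pca3` object.
#' @export
windowed_pca <- function(enriched, years = range(enriched$year)) {
  sel <- enriched$year >= years[1] & enriched$year <= years[2]
  x <- enriched[sel, c("elevation_m", "lst_c_lag1", "rzsm_pct_lag1")]
  n_complete <- sum(stats::complete.cases(x))
  if (n_complete < 3)
    stop("window ", years[1], "-", years[2], " has only ", n_complete,
         " complete records (need >= 3)")
  pca_3var(x, var_names = c("elevation", "lst", "rzsm"))
}
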