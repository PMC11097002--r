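#' Convert scaled Kelvin digital numbers to Celsius
#'
#' Satellite LST products store temperature as scaled integers; the decoded
#' Kelvin value is `dn * scale + offset`, and `celsius = kelvin - 273.15`.
#' With `scale = 1, offset = 0` the input is treated as plain Kelvin.
#' Missing values propagate.
#'
#' @param dn digital numbers or Kelvin values (vectorized).
#' @param scale,offset linear decoding coefficients; `scale` must be > 0.
#' @return temperatures in degrees Celsius.
#' @export
kelvin_to_celsius <- function(dn, scale = 1, offset = 0) {
  check_finite_scalar(scale, "scale"); check_finite_scalar(offset, "offset")
  if (scale <= 0) stop("scale must be > 0")
  (dn * scale + offset) - 273.15
}

#' Calendar-correct month lag
#'
#' Subtracts `k` months from (year, month), crossing year boundaries
#' correctly: lag 2 from (y, 1) is (y-1, 11).
#'
#' @param year,month calendar time (vectorized); `month` must be in 1..12.
#' @param k non-negative integer number of months to go back.
#' @return list with elements `year` and `month`.
#' @export
lag_month <- function(year, month, k) {
  if (any(is.na(month)) || any(month < 1 | month > 12))
    stop("month must be in 1..12")
  if (length(k) != 1L || is.na(k) || k < 0 || k != round(k))
    stop("k must be a single non-negative integer")
  idx <- year * 12L + (month - 1L) - k
  list(year = idx %/% 12L, month = idx %% 12L + 1L)
}

#' Percentile rank within a reference series
#'
#' `100 * (# reference values <= value) / (# non-missing reference values)`.
#' The inclusive convention means a value equal to the reference maximum —
#' and any value in an all-tied reference — ranks at 100.
#'
#' @param value query values (vectorized).
#' @param reference numeric reference series; must contain at least one
#'   non-missing value, otherwise all ranks are `NA`.
#' @return percentiles in [0, 100], `NA` where `value` is missing.
#' @export
percentile_rank <- function(value, reference) {
  ref <- reference[!is.na(reference)]
  if (!length(ref)) return(rep(NA_real_, length(value)))
  ref <- sort(ref)
  out <- 100 * findInterval(value, ref) / length(ref)
  out[is.na(value)] <- NA_real_
  out
}

#' Attach lagged environmental values to occurrence records
#'
#' For each cleaned occurrence, extracts LST and RZSM at lags 0, 1, 2 months
#' (nearest grid cell, calendar-correct lag arithmetic), the percentile of
#' the lag-1 and lag-2 LST within the cell's climatology, and the static
#' elevation. Per-analysis completeness flags are set so each downstream
#' stage excludes exactly its own incomplete records: a record missing RZSM
#' is excluded from the moisture and coupling analyses but not from the
#' temperature analysis.
#'
#' @param occurrences data.frame with columns `species`, `lon`, `lat`,
#'   `year`, `month` (e.g. `clean_occurrences(...)$records`).
#' @param lst,rzsm monthly [monthly_grid]s on overlapping time spans.
#' @param elev static elevation [monthly_grid].
#' @param climatology `"all"` (default) ranks LST against the cell's full
#'   monthly record; `"month"` against the same calendar month only.
#' @return the input data.frame with added columns `lst_c_lag0..2`,
#'   `rzsm_pct_lag0..2`, `lst_pctile_lag1`, `lst_pctile_lag2`,
#'   `elevation_m`, and logical flags `complete_temp`, `complete_moist`,
#'   `complete_coupling`.
#' @export
enrich_occurrences <- function(occurrences, lst, rzsm, elev,
                               climatology = c("all", "month")) {
  climatology <- match.arg(climatology)
  if (is.null(lst$times) || is.null(rzsm$times))
    stop("lst and rzsm must be monthly grids")
  lst_code <- lst$times$year * 12L + lst$times$month
  rzsm_code <- rzsm$times$year * 12L + rzsm$times$month
  if (max(lst_code[1], rzsm_code[1]) > min(lst_code[length(lst_code)],
                                           rzsm_code[length(rzsm_code)]))
    stop("lst and rzsm grids have disjoint time coverage")

  out <- occurrences
  for (k in 0:2) {
    lag <- lag_month(out$year, out$month, k)
    out[[paste0("lst_c_lag", k)]] <-
      sample_grid(lst, out$lon, out$lat, lag$year, lag$month)
    out[[paste0("rzsm_pct_lag", k)]] <-
      sample_grid(rzsm, out$lon, out$lat, lag$year, lag$month)
  }
  out$elevation_m <- sample_grid(elev, out$lon, out$lat)

  # LST percentile of lag-1/lag-2 values against the occurrence cell's climatology
  ci <- nearest_index(lst$lon, out$lon)
  cj <- nearest_index(lst$lat, out$lat)
  cell_key <- paste(ci, cj)
  for (k in 1:2) {
    lag <- lag_month(out$year, out$month, k)
    val <- out[[paste0("lst_c_lag", k)]]
    pct <- rep(NA_real_, nrow(out))
    for (ck in unique(cell_key[!is.na(ci) & !is.na(cj)])) {
      rows <- which(cell_key == ck & !is.na(ci) & !is.na(cj))
      series <- lst$values[ci[rows[1]], cj[rows[1]], ]
      if (climatology == "month") {
        pct[rows] <- vapply(rows, function(r) {
          ref <- series[lst$times$month == lag$month[r]]
          percentile_rank(val[r], ref)
        }, numeric(1))
      } else {
        pct[rows] <- percentile_rank(val[rows], series)
      }
    }
    out[[paste0("lst_pctile_lag", k)]] <- pct
  }

  out$complete_temp <- !is.na(out$lst_c_lag1) & !is.na(out$lst_c_lag2)
  out$complete_moist <- !is.na(out$rzsm_pct_lag1) & !is.na(out$rzsm_pct_lag2)
  out$complete_coupling <- !is.na(out$lst_c_lag0) & !is.na(out$lst_c_lag1) &
    !is.na(out$lst_c_lag2) & !is.na(out$rzsm_pct_lag0) &
    !is.na(out$rzsm_pct_lag1) & !is.na(out$rzsm_pct_lag2)
  out
}
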