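#' Heat-moisture coupling configuration
#'
#' A heat-moisture coupling event is a month in which the land-surface
#' temperature and the soil-moisture percentile are simultaneously at or
#' above their thresholds. Defaults follow the study definition: LST >= 25
#' degC and RZSM percentile >= 70, assessed in the observation month or
#' either of the two preceding months (lags 0, 1, 2).
#'
#' @param temp_threshold LST threshold in degC (inclusive).
#' @param moisture_pctile_threshold RZSM percentile threshold (inclusive).
#' @param lags month offsets to scan, a non-empty subset of `c(0, 1, 2)`.
#' @return object of class `coupling_config`.
#' @export
coupling_config <- function(temp_threshold = 25,
                            moisture_pctile_threshold = 70,
                            lags = c(0, 1, 2)) {
  check_finite_scalar(temp_threshold, "temp_threshold")
  check_finite_scalar(moisture_pctile_threshold, "moisture_pctile_threshold")
  if (!length(lags) || !all(lags %in% c(0, 1, 2)))
    stop("lags must be a non-empty subset of {0, 1, 2}")
  structure(list(temp_threshold = temp_threshold,
                 moisture_pctile_threshold = moisture_pctile_threshold,
                 lags = sort(unique(as.integer(lags)))),
            class = "coupling_config")
}

#' Coupling flag for one month
#'
#' `TRUE` iff `lst_c >= temp_threshold` AND
#' `rzsm_pct >= moisture_pctile_threshold`, inclusive at both boundaries;
#' both values must come from the same month. A missing constituent gives
#' `NA`, not `FALSE`.
#'
#' @param lst_c LST in degC (vectorized).
#' @param rzsm_pct RZSM percentile (vectorized).
#' @param config a [coupling_config].
#' @return logical vector with `NA` for undecidable months.
#' @export
coupling_at_lag <- function(lst_c, rzsm_pct, config = coupling_config()) {
  out <- lst_c >= config$temp_threshold &
    rzsm_pct >= config$moisture_pctile_threshold
  # R would decide NA & FALSE as FALSE; the contract is strict missingness
  out[is.na(lst_c) | is.na(rzsm_pct)] <- NA
  out
}

#' Coupling flag over the lag window
#'
#' `TRUE` iff the per-month conjunction holds at one or more configured lags
#' (both variables from the same lagged month). If no lag is `TRUE` and at
#' least one configured lag is undecidable, the result is `NA`
#' (conservative: such records are excluded downstream); a decided `TRUE`
#' short-circuits missing lags.
#'
#' @param enriched data.frame with columns `lst_c_lag<k>` and
#'   `rzsm_pct_lag<k>` for the configured lags (see [enrich_occurrences()]).
#' @param config a [coupling_config].
#' @return logical vector, one flag (or `NA`) per row.
#' @export
coupling_any <- function(enriched, config = coupling_config()) {
  if (nrow(enriched) == 0) return(logical(0))
  flags <- sapply(config$lags, function(k)
    coupling_at_lag(enriched[[paste0("lst_c_lag", k)]],
                    enriched[[paste0("rzsm_pct_lag", k)]], config))
  flags <- matrix(flags, ncol = length(config$lags))
  any_true <- apply(flags, 1, function(r) any(r %in% TRUE))
  any_na <- apply(flags, 1, anyNA)
  out <- any_true
  out[!any_true & any_na] <- NA
  out
}

#' Per-species coupling association
#'
#' For each species, the percentage of decidable (coupling-complete)
#' occurrence records preceded by a heat-moisture coupling event within the
#' configured lag window. Records whose coupling status is undecidable are
#' excluded from both numerator and denominator; a species with no decidable
#' records is reported with a missing percentage.
#'
#' @param enriched data.frame from [enrich_occurrences()] with a `species`
#'   column.
#' @param config a [coupling_config].
#' @return data.frame ordered by species name: `species`, `n_complete`,
#'   `n_coupled`, `pct_coupled`, plus the threshold configuration echoed as
#'   attributes `temp_threshold`, `moisture_pctile_threshold`, `lags`.
#' @export
species_association <- function(enriched, config = coupling_config()) {
  coupled <- coupling_any(enriched, config)
  species <- sort(unique(enriched$species))
  out <- data.frame(species = species,
                    n_complete = NA_integer_, n_coupled = NA_integer_,
                    pct_coupled = NA_real_)
  for (i in seq_along(species)) {
    c_sp <- coupled[enriched$species == species[i]]
    dec <- c_sp[!is.na(c_sp)]
    out$n_complete[i] <- length(dec)
    out$n_coupled[i] <- sum(dec)
    out$pct_coupled[i] <- if (length(dec)) 100 * sum(dec) / length(dec) else NA_real_
  }
  attr(out, "temp_threshold") <- config$temp_threshold
  attr(out, "moisture_pctile_threshold") <- config$moisture_pctile_threshold
  attr(out, "lags") <- config$lags
  out
}
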