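#' Generate synthetic environmental grids
#'
#' Builds the monthly land-surface temperature (LST, degC) and root-zone
#' soil-moisture percentile (RZSM, 0-100) stacks plus the static elevation
#' grid of a synthetic scenario.
#'
#' Each LST cell series is
#' `baseline(lat) - lapse_rate * elev/1000 + seasonal sinusoid + trend * t + noise`,
#' where the seasonal sinusoid peaks in July north of the equator and in
#' January south of it, and the linear trend applies at designated trend
#' cells only. RZSM is generated directly on the percentile scale as
#' `baseline(lat) + trend * t + noise`, clipped to [0, 100], with the trend
#' again confined to designated cells. Identical seeds give bit-identical
#' grids.
#'
#' @param config a [scenario_config].
#' @return list with elements `lst`, `rzsm` (monthly [monthly_grid]s),
#'   `elev` (static), and `trend_mask` (logical nlon x nlat matrix of
#'   designated cells).
#' @export
generate_env_grids <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  ax <- scenario_axes(config)
  times <- scenario_times(config)
  elev <- scenario_elevation(config)
  mask <- trend_cell_mask(config, elev)
  tr <- config$env_trends
  nt <- nrow(times)
  nx <- config$grid_nx; ny <- config$grid_ny
  t_years <- (seq_len(nt) - 1) / 12  # years since the first month

  # deterministic structure, broadcast to (lon, lat, time)
  base_lst <- outer(ax$lon, ax$lat, function(lon, lat)
    tr$lst_base_c - tr$lat_gradient_c_per_deg * (lat - config$lat_min)) -
    tr$lapse_rate_c_per_km * elev$values / 1000
  base_rzsm <- outer(ax$lon, ax$lat, function(lon, lat)
    tr$rzsm_base_pct - tr$rzsm_lat_gradient_pct_per_deg * (lat - config$lat_min))

  # seasonal phase: peak month 7 for lat >= 0, month 1 for lat < 0
  season <- array(0, c(nx, ny, nt))
  for (j in seq_len(ny)) {
    peak <- if (ax$lat[j] < 0) 1 else 7
    season[, j, ] <- rep(tr$seasonal_amplitude_c *
                           cos(2 * pi * (times$month - peak) / 12),
                         each = nx)
  }

  trend_lst <- array(0, c(nx, ny, nt))
  trend_rzsm <- array(0, c(nx, ny, nt))
  for (k in seq_len(nt)) {
    trend_lst[, , k] <- ifelse(mask, tr$lst_trend_c_per_year * t_years[k], 0)
    trend_rzsm[, , k] <- ifelse(mask, tr$rzsm_trend_pct_per_year * t_years[k], 0)
  }

  with_seed(substream_seed(config$seed, "env"), {
    lst_vals <- array(rep(base_lst, nt), c(nx, ny, nt)) + season + trend_lst +
      array(stats::rnorm(nx * ny * nt, sd = tr$noise_sd_lst), c(nx, ny, nt))
    rzsm_vals <- array(rep(base_rzsm, nt), c(nx, ny, nt)) + trend_rzsm +
      array(stats::rnorm(nx * ny * nt, sd = tr$noise_sd_rzsm), c(nx, ny, nt))
  })
  rzsm_vals <- pmin(pmax(rzsm_vals, 0), 100)

  list(lst = monthly_grid("LST_C", ax$lon, ax$lat, lst_vals, times),
       rzsm = monthly_grid("RZSM_PCT", ax$lon, ax$lat, rzsm_vals, times),
       elev = elev,
       trend_mask = mask)
}

#' Generate synthetic harvested-area crop grids for two epochs
#'
#' Produces one static harvested-area grid per crop per epoch. Epoch "2015"
#' starts as a copy of epoch "2000" (host persistence), after which each
#' `crop_withdrawal` entry zeroes the named crop above its elevation cutoff
#' in the named epoch only.
#'
#' @param config a [scenario_config].
#' @param elev static elevation [monthly_grid] from the same config.
#' @param crops character vector of crop names; defaults to the union of the
#'   study host lists.
#' @param absence_fraction fraction of cells per crop set to zero harvested
#'   area before withdrawal (patchy cultivation).
#' @return named list `epoch -> named list crop -> monthly_grid("CROP_AREA")`.
#' @export
generate_crop_grids <- function(config, elev,
                                crops = c("beans", "peas", "lentils",
                                          "maize", "sorghum", "millet", "rice"),
                                absence_fraction = 0.12) {
  stopifnot(inherits(config, "scenario_config"))
  cw <- config$crop_withdrawal
  if (nrow(cw) && !all(cw$crop %in% crops))
    stop("crop_withdrawal names unknown crop(s): ",
         paste(setdiff(cw$crop, crops), collapse = ", "))
  nx <- config$grid_nx; ny <- config$grid_ny
  epoch1 <- with_seed(substream_seed(config$seed, "crops"), {
    out <- list()
    for (cr in crops) {
      area <- matrix(stats::rgamma(nx * ny, shape = 1.5, scale = 0.2), nx, ny)
      off <- sample.int(nx * ny, size = round(absence_fraction * nx * ny))
      area[off] <- 0
      out[[cr]] <- monthly_grid("CROP_AREA", elev$lon, elev$lat, area)
    }
    out
  })
  grids <- list("2000" = epoch1, "2015" = epoch1)
  for (r in seq_len(nrow(cw))) {
    ep <- as.character(cw$epoch[r]); cr <- cw$crop[r]
    if (!ep %in% names(grids)) stop("withdrawal names unknown epoch: ", ep)
    g <- grids[[ep]][[cr]]
    g$values[elev$values > cw$elevation_cutoff_m[r]] <- 0
    grids[[ep]][[cr]] <- g
  }
  grids
}
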