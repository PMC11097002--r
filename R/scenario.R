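#' Synthetic scenario configuration
#'
#' Full parameterization of the synthetic world used to validate the
#' pipeline: a regular lon/lat grid, a monthly time axis, per-species
#' environmental niches, planted environmental trends at designated cells,
#' and host-crop withdrawal between two harvested-area epochs.
#'
#' The default world spans a latitudinal climate gradient (hot tropics in the
#' south, cool mid-latitudes in the north) with one smooth high-elevation
#' massif in the tropics. Heat and moisture trends are planted at designated
#' high-elevation cells so that the monthly probability of a heat-moisture
#' coupling event (LST >= 25 degC and RZSM percentile >= 70 in the same
#' month) rises from a few percent to several tens of percent over the study
#' span, while all other cells stay stationary.
#'
#' @param grid_nx,grid_ny cell counts along longitude and latitude.
#' @param lon_min,lon_max,lat_min,lat_max domain bounds in decimal degrees.
#' @param start_year,end_year calendar span of the monthly axis (inclusive).
#' @param species_niches data.frame with one row per species: columns
#'   `species`, `lst_mean`, `lst_sd` (degC), `rzsm_mean`, `rzsm_sd`
#'   (percentile points), `elev_pref_m`, `elev_sd_m`, `n_occurrences`,
#'   `elev_trend_per_year` (m/yr drift of the preferred elevation).
#' @param env_trends list with `lst_trend_c_per_year` and
#'   `rzsm_trend_pct_per_year` (applied at designated trend cells only),
#'   `seasonal_amplitude_c`, `lapse_rate_c_per_km`, `lst_base_c` (sea-level
#'   baseline at the southern edge), `lat_gradient_c_per_deg` (cooling per
#'   degree of northward latitude), `rzsm_base_pct` (baseline percentile at
#'   the southern edge), `rzsm_lat_gradient_pct_per_deg`, `noise_sd_lst`,
#'   `noise_sd_rzsm`.
#' @param trend_cells `NULL` to designate every cell above
#'   `trend_cell_min_elev_m`, or a two-column matrix/data.frame of (i, j)
#'   grid indices.
#' @param trend_cell_min_elev_m,trend_cell_max_elev_m elevation band used
#'   when `trend_cells` is `NULL` (default 1100-1700 m: the flank of the
#'   tropical massif, where the baseline climate keeps the temperature
#'   threshold within reach so the planted trend can raise the monthly
#'   coupling probability from a few percent to roughly one half).
#' @param crop_withdrawal data.frame with columns `crop`, `epoch`,
#'   `elevation_cutoff_m`; each row zeroes that crop above the cutoff in that
#'   epoch only.
#' @param missing_fraction,duplicate_fraction fractions of extra defective
#'   rows (missing coordinates / duplicates) appended to the occurrence table
#'   to exercise cleaning.
#' @param seed master integer seed; three named substreams (env, occurrences,
#'   crops) are derived from it so modules can be regenerated independently.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(grid_nx = 24, grid_ny = 40,
                            lon_min = 10, lon_max = 34,
                            lat_min = -10, lat_max = 40,
                            start_year = 2006, end_year = 2022,
                            species_niches = default_species_niches(),
                            env_trends = default_env_trends(),
                            trend_cells = NULL,
                            trend_cell_min_elev_m = 1100,
                            trend_cell_max_elev_m = 1700,
                            crop_withdrawal = default_crop_withdrawal(),
                            missing_fraction = 0.02,
                            duplicate_fraction = 0.02,
                            seed = 1L) {
  for (nm in c("grid_nx", "grid_ny", "lon_min", "lon_max", "lat_min", "lat_max",
               "start_year", "end_year", "trend_cell_min_elev_m",
               "trend_cell_max_elev_m",
               "missing_fraction", "duplicate_fraction", "seed"))
    check_finite_scalar(get(nm), nm)
  if (end_year < start_year) stop("end_year must be >= start_year")
  if (lon_max <= lon_min || lat_max <= lat_min) stop("degenerate domain bounds")
  species_niches <- as.data.frame(species_niches)
  needed <- c("species", "lst_mean", "lst_sd", "rzsm_mean", "rzsm_sd",
              "elev_pref_m", "elev_sd_m", "n_occurrences", "elev_trend_per_year")
  miss <- setdiff(needed, names(species_niches))
  if (length(miss)) stop("species_niches missing columns: ", paste(miss, collapse = ", "))
  num_cols <- setdiff(needed, "species")
  for (nm in num_cols)
    if (any(!is.finite(species_niches[[nm]])))
      stop("field '", nm, "' contains non-finite values")
  if (any(species_niches$lst_sd <= 0) || any(species_niches$rzsm_sd <= 0) ||
      any(species_niches$elev_sd_m <= 0))
    stop("all niche SDs must be > 0")
  if (any(species_niches$n_occurrences <= 0)) stop("n_occurrences must be > 0 per species")
  for (nm in names(env_trends)) check_finite_scalar(env_trends[[nm]], nm)
  if (!is.null(trend_cells)) {
    trend_cells <- as.matrix(trend_cells)
    if (ncol(trend_cells) != 2L) stop("trend_cells must have two columns (i, j)")
    if (any(trend_cells[, 1] < 1 | trend_cells[, 1] > grid_nx |
            trend_cells[, 2] < 1 | trend_cells[, 2] > grid_ny))
      stop("designated trend cells must be a subset of grid cells")
  }
  cw <- as.data.frame(crop_withdrawal)
  if (nrow(cw) && !all(c("crop", "epoch", "elevation_cutoff_m") %in% names(cw)))
    stop("crop_withdrawal needs columns crop, epoch, elevation_cutoff_m")
  structure(list(grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
                 lon_min = lon_min, lon_max = lon_max,
                 lat_min = lat_min, lat_max = lat_max,
                 start_year = as.integer(start_year), end_year = as.integer(end_year),
                 species_niches = species_niches, env_trends = env_trends,
                 trend_cells = trend_cells,
                 trend_cell_min_elev_m = trend_cell_min_elev_m,
                 trend_cell_max_elev_m = trend_cell_max_elev_m,
                 crop_withdrawal = cw,
                 missing_fraction = missing_fraction,
                 duplicate_fraction = duplicate_fraction,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("scenario_config: %dx%d grid, %d-%d, %d species, seed %d\n",
              x$grid_nx, x$grid_ny, x$start_year, x$end_year,
              nrow(x$species_niches), x$seed))
  invisible(x)
}

#' Default species niches
#'
#' Eight Orobanchaceae species with contrasting temperature, moisture and
#' elevation niches: *Striga* species hot and moisture-associated (the
#' *S. asiatica* and *S. gesnerioides* niches drift upslope over the study
#' span), *Orobanche crenata*/*O. minor* cool and comparatively dry,
#' *Phelipanche aegyptiaca* hot but dry (so essentially never preceded by a
#' heat-moisture coupling).
#'
#' @return data.frame accepted by [scenario_config()].
#' @export
default_species_niches <- function() {
  data.frame(
    species = c("Orobanche crenata", "Orobanche cumana", "Orobanche minor",
                "Phelipanche aegyptiaca", "Phelipanche ramosa",
                "Striga asiatica", "Striga gesnerioides", "Striga hermonthica"),
    lst_mean = c(18, 27, 19.5, 29, 22, 29, 30, 30),
    lst_sd   = c(5, 4, 4, 4, 4, 3, 3, 3),
    rzsm_mean = c(40, 35, 38, 22, 50, 68, 70, 74),
    rzsm_sd   = c(12, 12, 12, 8, 12, 10, 10, 10),
    elev_pref_m = c(900, 300, 260, 260, 250, 600, 700, 400),
    elev_sd_m   = c(300, 300, 300, 300, 300, 350, 350, 300),
    n_occurrences = c(250, 200, 250, 150, 200, 300, 200, 200),
    elev_trend_per_year = c(-30, 0, 0, 0, 0, 25, 20, 0)
  )
}

#' @rdname default_species_niches
#' @export
default_env_trends <- function() {
  list(lst_trend_c_per_year = 0.2, rzsm_trend_pct_per_year = 2,
       seasonal_amplitude_c = 3, lapse_rate_c_per_km = 6.5,
       lst_base_c = 33, lat_gradient_c_per_deg = 0.35,
       rzsm_base_pct = 58, rzsm_lat_gradient_pct_per_deg = 0.45,
       noise_sd_lst = 1.5, noise_sd_rzsm = 10)
}

#' @rdname default_species_niches
#' @export
default_crop_withdrawal <- function() {
  data.frame(crop = c("beans", "peas", "lentils"),
             epoch = "2015", elevation_cutoff_m = 1000)
}

scenario_axes <- function(config) {
  dx <- (config$lon_max - config$lon_min) / config$grid_nx
  dy <- (config$lat_max - config$lat_min) / config$grid_ny
  list(lon = config$lon_min + dx * (seq_len(config$grid_nx) - 0.5),
       lat = config$lat_min + dy * (seq_len(config$grid_ny) - 0.5))
}

scenario_times <- function(config) {
  years <- config$start_year:config$end_year
  data.frame(year = rep(years, each = 12L), month = rep(1:12, length(years)))
}

# Smooth deterministic elevation surface: gentle northward ramp plus two
# massifs exceeding 1000 m — a tall tropical one (Striga habitat) and a
# lower mid-latitude one (cool-climate Orobanche habitat).
scenario_elevation <- function(config) {
  ax <- scenario_axes(config)
  W <- config$lon_max - config$lon_min
  H <- config$lat_max - config$lat_min
  hill <- function(lon, lat, fx, fy, frx, fry, peak) {
    cx <- config$lon_min + fx * W; cy <- config$lat_min + fy * H
    peak * exp(-((lon - cx)^2 / (2 * (frx * W)^2) +
                   (lat - cy)^2 / (2 * (fry * H)^2)))
  }
  f <- outer(ax$lon, ax$lat, function(lon, lat) {
    150 + 4 * (lat - config$lat_min) +
      hill(lon, lat, 0.72, 0.12, 0.30, 0.14, 1900) +
      hill(lon, lat, 0.30, 0.78, 0.25, 0.12, 1200)
  })
  monthly_grid("ELEV_M", ax$lon, ax$lat, f)
}

# Logical nlon x nlat mask of designated trend cells. The default rule
# confines the planted heat/moisture trends to the 1100-1700 m flank of the
# tropical massif (lat < 15): above it, and on the cold mid-latitude massif,
# the temperature threshold is out of reach and a planted coupling-frequency
# rise could not express, so those cells are left stationary.
trend_cell_mask <- function(config, elev) {
  if (!is.null(config$trend_cells)) {
    m <- matrix(FALSE, config$grid_nx, config$grid_ny)
    m[config$trend_cells] <- TRUE
    return(m)
  }
  high <- elev$values > config$trend_cell_min_elev_m &
    elev$values <= config$trend_cell_max_elev_m
  ax <- scenario_axes(config)
  tropical <- matrix(rep(ax$lat < 15, each = config$grid_nx),
                     config$grid_nx, config$grid_ny)
  high & tropical
}
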