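# Shared fixtures, built in code at test time.

# Reduced synthetic world for unit tests (the full default scenario is
# exercised in the end-to-end tests).
small_scenario <- function(seed = 11, ...) {
  niches <- default_species_niches()
  niches$n_occurrences <- pmax(40, niches$n_occurrences %/% 5)
  scenario_config(grid_nx = 16, grid_ny = 24,
                  start_year = 2008, end_year = 2018,
                  species_niches = niches, seed = seed, ...)
}

# Tiny handcrafted monthly grid: values = f(i, j, t) over a known axis, for
# closed-form extraction checks.
tiny_grid <- function(variable = "LST_C", nx = 3, ny = 2,
                      years = 2019:2020, f = function(i, j, t) 10 * i + j + t / 100) {
  times <- data.frame(year = rep(years, each = 12L), month = rep(1:12, length(years)))
  vals <- array(0, c(nx, ny, nrow(times)))
  for (i in 1:nx) for (j in 1:ny) for (t in seq_len(nrow(times)))
    vals[i, j, t] <- f(i, j, t)
  monthly_grid(variable, lon = as.numeric(1:nx), lat = as.numeric(10 + 1:ny),
               values = vals, times = times)
}

static_grid <- function(values, variable = "ELEV_M") {
  nx <- nrow(values); ny <- ncol(values)
  monthly_grid(variable, lon = as.numeric(1:nx), lat = as.numeric(10 + 1:ny),
               values = values)
}

# Write an occurrence data.frame to a temp CSV and read it back raw.
roundtrip_raw <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  read_occurrences(path)
}

# Brute-force Mann-Kendall S by explicit double loop.
brute_S <- function(x) {
  n <- length(x); S <- 0
  if (n < 2) return(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) S <- S + sign(x[j] - x[i])
  S
}

# Brute-force three-month double-threshold coupling scan with explicit
# missing propagation, independent of the vectorized implementation.
brute_coupling_any <- function(lst, rzsm, temp = 25, moist = 70, lags = 0:2) {
  decided_true <- FALSE; undecidable <- FALSE
  for (k in lags) {
    l <- lst[k + 1]; r <- rzsm[k + 1]
    if (is.na(l) || is.na(r)) { undecidable <- TRUE; next }
    if (l >= temp && r >= moist) decided_true <- TRUE
  }
  if (decided_true) TRUE else if (undecidable) NA else FALSE
}
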