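test_that("Kelvin conversion handles plain Kelvin and scaled digital numbers", {
  expect_equal(kelvin_to_celsius(273.15), 0)
  expect_equal(kelvin_to_celsius(300), 26.85)
  expect_equal(kelvin_to_celsius(14825, scale = 0.02), 23.35)
  expect_true(is.na(kelvin_to_celsius(NA)))
  expect_error(kelvin_to_celsius(300, scale = -1), "scale")
})

test_that("month lag arithmetic crosses year boundaries correctly", {
  expect_equal(lag_month(2020, 3, 1), list(year = 2020, month = 2))
  expect_equal(lag_month(2020, 1, 2), list(year = 2019, month = 11))
  expect_equal(lag_month(2006, 2, 2), list(year = 2005, month = 12))
  expect_equal(lag_month(2020, 7, 0), list(year = 2020, month = 7))
  expect_error(lag_month(2020, 13, 1), "month")
  # vectorized, and composing lags is additive
  l1 <- lag_month(c(2020, 2021), c(1, 12), 2)
  expect_equal(l1$year, c(2019, 2021))
  expect_equal(l1$month, c(11, 10))
})

test_that("percentile rank uses the inclusive convention times 100", {
  expect_equal(percentile_rank(70, 1:100), 70)
  expect_equal(percentile_rank(100, 1:100), 100)   # equal to the maximum
  expect_equal(percentile_rank(5, rep(5, 8)), 100)  # all-tied reference
  expect_equal(percentile_rank(0.5, 1:100), 0)
  expect_true(is.na(percentile_rank(3, c(NA, NA))))
  expect_equal(percentile_rank(c(2, NA), 1:4), c(50, NA))
})

test_that("enrichment attaches closed-form lag values when noise is zero", {
  tr <- default_env_trends()
  tr$noise_sd_lst <- 0; tr$noise_sd_rzsm <- 0
  tr$lst_trend_c_per_year <- 0; tr$rzsm_trend_pct_per_year <- 0
  sc <- small_scenario(env_trends = tr, seed = 3)
  env <- generate_env_grids(sc)
  occ <- data.frame(record_id = "r1", species = "Striga asiatica",
                    lon = env$lst$lon[4], lat = env$lst$lat[5],
                    year = 2010L, month = 1L)
  enr <- enrich_occurrences(occ, env$lst, env$rzsm, env$elev)
  elev <- env$elev$values[4, 5]
  lat <- env$lst$lat[5]
  closed_form <- function(month) {
    peak <- if (lat < 0) 1 else 7
    tr$lst_base_c - tr$lat_gradient_c_per_deg * (lat - sc$lat_min) -
      tr$lapse_rate_c_per_km * elev / 1000 +
      tr$seasonal_amplitude_c * cos(2 * pi * (month - peak) / 12)
  }
  expect_equal(enr$lst_c_lag0, closed_form(1))
  expect_equal(enr$lst_c_lag1, closed_form(12))  # December of 2009
  expect_equal(enr$lst_c_lag2, closed_form(11))
  expect_equal(enr$elevation_m, elev)
})

test_that("a constant grid gives identical lags and percentile 100", {
  lst <- tiny_grid(f = function(i, j, t) 20)
  rzsm <- tiny_grid("RZSM_PCT", f = function(i, j, t) 50)
  elev <- static_grid(matrix(100, 3, 2))
  occ <- data.frame(record_id = "r1", species = "x", lon = 2, lat = 11,
                    year = 2020L, month = 6L)
  enr <- enrich_occurrences(occ, lst, rzsm, elev)
  expect_equal(unlist(enr[, c("lst_c_lag0", "lst_c_lag1", "lst_c_lag2")]),
               c(lst_c_lag0 = 20, lst_c_lag1 = 20, lst_c_lag2 = 20))
  expect_equal(enr$lst_pctile_lag1, 100)  # degenerate climatology, <= convention
  expect_equal(enr$lst_pctile_lag2, 100)
})

test_that("completeness flags are per analysis", {
  lst <- tiny_grid()
  rzsm <- tiny_grid("RZSM_PCT", f = function(i, j, t) 50)
  elev <- static_grid(matrix(100, 3, 2))
  # record in Feb of the first grid year: lag-2 (Dec of prior year) is off-axis
  occ <- data.frame(record_id = c("r1", "r2"), species = "x", lon = 2,
                    lat = 11, year = c(2019L, 2020L), month = c(2L, 6L))
  enr <- enrich_occurrences(occ, lst, rzsm, elev)
  expect_false(enr$complete_coupling[1])
  expect_false(enr$complete_temp[1])   # temperature analysis needs lag 2 too
  expect_true(all(unlist(enr[2, c("complete_temp", "complete_moist",
                                  "complete_coupling")])))

  # record outside the moisture grid only: excluded from moisture/coupling,
  # kept for temperature
  rzsm_small <- monthly_grid("RZSM_PCT", lon = 1, lat = 11,
                             values = array(50, c(1, 1, nrow(lst$times))),
                             times = lst$times)
  enr2 <- enrich_occurrences(occ[2, ], lst, rzsm_small, elev)
  expect_true(enr2$complete_temp)
  expect_false(enr2$complete_moist)
  expect_false(enr2$complete_coupling)
})

test_that("enrichment is pure and fails fast on disjoint grid time spans", {
  sc <- small_scenario(seed = 5)
  env <- generate_env_grids(sc)
  occ <- generate_occurrences(sc, env)
  cleaned <- clean_occurrences(roundtrip_raw(occ))
  a <- enrich_occurrences(cleaned$records, env$lst, env$rzsm, env$elev)
  b <- enrich_occurrences(cleaned$records, env$lst, env$rzsm, env$elev)
  expect_identical(a, b)

  shifted <- tiny_grid("RZSM_PCT", years = 1990:1991)
  expect_error(enrich_occurrences(cleaned$records, env$lst, shifted, env$elev),
               "disjoint")
})
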