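test_that("scenario config rejects invalid fields by name", {
  expect_error(scenario_config(start_year = 2020, end_year = 2010),
               "end_year")
  expect_error(scenario_config(seed = NaN), "seed")
  niches <- default_species_niches()
  niches$lst_sd[2] <- 0
  expect_error(scenario_config(species_niches = niches), "SDs must be > 0")
  niches <- default_species_niches()
  niches$rzsm_mean[1] <- Inf
  expect_error(scenario_config(species_niches = niches), "rzsm_mean")
  niches <- default_species_niches()
  niches$n_occurrences[3] <- 0
  expect_error(scenario_config(species_niches = niches), "n_occurrences")
  expect_error(scenario_config(trend_cells = cbind(100, 1)),
               "subset of grid cells")
})

test_that("identical seed gives bit-identical grids, occurrences and crops", {
  sc <- small_scenario(seed = 23)
  a <- generate_env_grids(sc); b <- generate_env_grids(sc)
  expect_identical(a$lst$values, b$lst$values)
  expect_identical(a$rzsm$values, b$rzsm$values)
  expect_identical(a$elev$values, b$elev$values)
  oa <- generate_occurrences(sc, a); ob <- generate_occurrences(sc, b)
  expect_identical(oa, ob)
  ca <- generate_crop_grids(sc, a$elev); cb <- generate_crop_grids(sc, b$elev)
  expect_identical(ca, cb)
  # and generation does not disturb the caller's RNG stream
  set.seed(5); before <- rnorm(1)
  set.seed(5); invisible(generate_env_grids(sc)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("degenerate generator settings give time-constant LST series", {
  tr <- default_env_trends()
  tr$noise_sd_lst <- 0; tr$noise_sd_rzsm <- 0
  tr$lst_trend_c_per_year <- 0; tr$rzsm_trend_pct_per_year <- 0
  tr$seasonal_amplitude_c <- 0
  sc <- small_scenario(env_trends = tr)
  env <- generate_env_grids(sc)
  ranges <- apply(env$lst$values, c(1, 2), function(s) diff(range(s)))
  expect_equal(max(ranges), 0)
})

test_that("generated values respect physical ranges", {
  env <- generate_env_grids(small_scenario(seed = 31))
  expect_true(all(env$rzsm$values >= 0 & env$rzsm$values <= 100))
  crops <- generate_crop_grids(small_scenario(seed = 31), env$elev)
  for (ep in crops) for (g in ep) expect_true(all(g$values >= 0))
})

test_that("a planted RZSM trend is recovered by least squares within 3 SE", {
  # designate one low-baseline cell so the series stays away from the
  # percentile clip; planted trend +2.0 percentile points per year
  tr <- default_env_trends()
  tr$rzsm_trend_pct_per_year <- 2.0
  sc <- scenario_config(grid_nx = 8, grid_ny = 8, lat_min = 20, lat_max = 40,
                        start_year = 2006, end_year = 2022,
                        env_trends = tr, trend_cells = cbind(3, 3), seed = 17)
  env <- generate_env_grids(sc)
  series <- env$rzsm$values[3, 3, ]
  t_years <- (seq_along(series) - 1) / 12
  fit <- summary(stats::lm(series ~ t_years))$coefficients
  expect_lt(abs(fit["t_years", "Estimate"] - 2.0), 3 * fit["t_years", "Std. Error"])
  # a non-designated cell stays trend-free (slope within 3 SE of zero)
  null_series <- env$rzsm$values[6, 6, ]
  nf <- summary(stats::lm(null_series ~ t_years))$coefficients
  expect_lt(abs(nf["t_years", "Estimate"]), 3 * nf["t_years", "Std. Error"])
})

test_that("occurrence sampling follows the planted niches", {
  sc <- small_scenario(seed = 41)
  env <- generate_env_grids(sc)
  occ <- generate_occurrences(sc, env)
  occ <- occ[!is.na(occ$decimalLongitude), ]
  lag1 <- lag_month(occ$year, occ$month, 1)
  rzsm1 <- sample_grid(env$rzsm, occ$decimalLongitude, occ$decimalLatitude,
                       lag1$year, lag1$month)
  lst1 <- sample_grid(env$lst, occ$decimalLongitude, occ$decimalLatitude,
                      lag1$year, lag1$month)
  wet_hot <- occ$species == "Striga hermonthica"   # niche rzsm 74, lst 30
  dry_cool <- occ$species == "Orobanche minor"     # niche rzsm 38, lst 19.5
  expect_gt(mean(rzsm1[wet_hot], na.rm = TRUE), mean(rzsm1[dry_cool], na.rm = TRUE))
  expect_gt(mean(lst1[wet_hot], na.rm = TRUE), mean(lst1[dry_cool], na.rm = TRUE))
  expect_true(all(occ$month %in% 1:12))
})

test_that("an impossible niche fails naming the species", {
  niches <- default_species_niches()[1, ]
  niches$lst_mean <- 500; niches$lst_sd <- 0.01
  sc <- small_scenario()
  sc$species_niches <- niches
  env <- generate_env_grids(sc)
  expect_error(generate_occurrences(sc, env), "Orobanche crenata")
})

test_that("zero defect fractions yield an already-clean table", {
  sc <- small_scenario(seed = 47, missing_fraction = 0, duplicate_fraction = 0)
  env <- generate_env_grids(sc)
  occ <- generate_occurrences(sc, env)
  cleaned <- clean_occurrences(roundtrip_raw(occ))
  expect_equal(cleaned$report$survivors, nrow(occ))
  expect_equal(sum(unlist(cleaned$report$drops)), 0)
})

test_that("crop withdrawal zeroes the named crop above the cutoff in one epoch only", {
  sc <- small_scenario(seed = 53)
  env <- generate_env_grids(sc)
  crops <- generate_crop_grids(sc, env$elev)
  high <- env$elev$values > 1000
  expect_gt(sum(high), 0)
  for (cr in c("beans", "peas", "lentils")) {
    expect_true(all(crops[["2015"]][[cr]]$values[high] == 0))
    expect_gt(sum(crops[["2000"]][[cr]]$values[high] > 0), 0)  # untouched epoch
  }
  expect_identical(crops[["2000"]][["maize"]], crops[["2015"]][["maize"]])

  # no withdrawal entries -> epochs identical
  sc0 <- small_scenario(seed = 53, crop_withdrawal = data.frame())
  crops0 <- generate_crop_grids(sc0, env$elev)
  expect_identical(crops0[["2000"]], crops0[["2015"]])

  expect_error(generate_crop_grids(
    small_scenario(crop_withdrawal = data.frame(crop = "durian", epoch = "2015",
                                                elevation_cutoff_m = 500)),
    env$elev), "durian")
})
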