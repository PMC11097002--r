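test_that("the montane indicator honors strict and inclusive cutoffs", {
  expect_false(high_elevation_flag(1000.0))
  expect_true(high_elevation_flag(1000.1))
  expect_false(high_elevation_flag(-223))           # below-sea-level is valid
  expect_true(high_elevation_flag(1000, strict = FALSE))
  expect_true(is.na(high_elevation_flag(NA)))
})

test_that("elevation trend flags constant indicators instead of crashing", {
  occ <- data.frame(year = rep(2006:2022, each = 4),
                    elevation_m = runif(68, 0, 500))
  tr <- elevation_trend(occ)          # indicator constant 0
  expect_true(tr$fit$separation)
  expect_true(tr$table_row$separation)
  # lowering the cutoff below min(elevation) makes the indicator all-true:
  # the separation path, never a crash
  tr2 <- elevation_trend(occ, cutoff = min(occ$elevation_m) - 1)
  expect_true(tr2$fit$separation)
})

test_that("a planted upslope drift yields a significant positive trend in most replicates", {
  # single drifting species, modest replicate count; the planted effect is
  # +25 m/yr against a 350 m niche SD
  niches <- default_species_niches()
  niches <- niches[niches$species == "Striga asiatica", ]
  niches$n_occurrences <- 200
  hits <- 0
  n_reps <- 25
  for (r in seq_len(n_reps)) {
    sc <- scenario_config(grid_nx = 16, grid_ny = 24,
                          species_niches = niches, seed = 6000 + r)
    env_r <- generate_env_grids(sc)
    occ <- generate_occurrences(sc, env_r)
    occ <- occ[!is.na(occ$decimalLongitude), ]
    occ <- occ[!duplicated(occ[, -1]), ]
    occ$elevation_m <- sample_grid(env_r$elev, occ$decimalLongitude,
                                   occ$decimalLatitude)
    tr <- elevation_trend(occ)
    if (!tr$fit$separation && tr$fit$slope > 0 && tr$fit$p_wald < 0.05)
      hits <- hits + 1
  }
  expect_gte(hits / n_reps, 0.8)
})

test_that("shuffling years against the indicator is significant at the nominal rate", {
  sc <- small_scenario(seed = 71)
  env <- generate_env_grids(sc)
  occ <- generate_occurrences(sc, env)
  occ <- occ[occ$species == "Striga asiatica" & !is.na(occ$decimalLongitude), ]
  elev <- sample_grid(env$elev, occ$decimalLongitude, occ$decimalLatitude)
  ind <- as.numeric(high_elevation_flag(elev))
  set.seed(72)
  n_perm <- 400
  hits <- 0
  for (i in seq_len(n_perm)) {
    f <- fit_logit_trend(sample(occ$year), ind)
    if (!f$separation && f$p_wald < 0.05) hits <- hits + 1
  }
  rate <- hits / n_perm
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("location series align both variables on one monthly axis", {
  sc <- small_scenario(seed = 73)
  env <- generate_env_grids(sc)
  s <- build_location_series(env$lst$lon[3], env$lst$lat[4],
                             env$lst, env$rzsm, env$elev)
  expect_equal(length(s$lst_c), nrow(s$times))
  expect_equal(length(s$coupling), length(s$lst_c))
  expect_equal(s$elevation_m, env$elev$values[3, 4])
  expect_error(build_location_series(999, 0, env$lst, env$rzsm, env$elev),
               "outside grid")
})

test_that("environmental Mann-Kendall trends behave at ramps, noise and planted cells", {
  times <- data.frame(year = rep(2006:2016, each = 12), month = rep(1:12, 11))
  nt <- nrow(times)
  ramp <- monthly_grid("LST_C", 1, 10, array(seq_len(nt), c(1, 1, nt)), times)
  flat_rzsm <- monthly_grid("RZSM_PCT", 1, 10, array(50, c(1, 1, nt)), times)
  elev <- monthly_grid("ELEV_M", 1, 10, array(100, c(1, 1)))
  s <- build_location_series(1, 10, ramp, flat_rzsm, elev)
  tr <- location_env_trends(s)
  expect_equal(tr$lst$tau, 1)
  expect_lt(tr$lst$p, 1e-10)

  # iid noise: the statistic matches brute-force pair enumeration
  set.seed(74)
  noise <- rnorm(30)
  noisy <- monthly_grid("LST_C", 1, 10,
                        array(noise, c(1, 1, 30)), times[1:30, ])
  s2 <- build_location_series(1, 10, noisy,
                              monthly_grid("RZSM_PCT", 1, 10,
                                           array(50, c(1, 1, 30)), times[1:30, ]),
                              elev)
  expect_equal(location_env_trends(s2)$lst$S, as.integer(brute_S(noise)))

  # under 24 months -> missing result with reason
  short <- location_env_trends(s2, min_months = 31)
  expect_true(is.na(short$lst$tau))
  expect_match(short$lst$reason, "fewer than 31")

  # planted moisture trend at a designated cell, no temperature trend
  trcfg <- default_env_trends()
  trcfg$lst_trend_c_per_year <- 0
  sc <- scenario_config(grid_nx = 8, grid_ny = 8, lat_min = 20, lat_max = 40,
                        env_trends = trcfg, trend_cells = cbind(3, 3), seed = 75)
  env <- generate_env_grids(sc)
  s3 <- build_location_series(env$lst$lon[3], env$lst$lat[3],
                              env$lst, env$rzsm, env$elev)
  tr3 <- location_env_trends(s3)
  expect_gt(tr3$rzsm$tau, 0)
  expect_lt(tr3$rzsm$p, 0.05)
  expect_gt(tr3$lst$p, 0.05)   # no planted temperature trend
})

test_that("a coupling probability rising 0.05 to 0.5 is classified as increase", {
  # direct synthetic monthly binary series, 17 years
  set.seed(76)
  n <- 204
  p <- seq(0.05, 0.5, length.out = n)
  hits <- 0
  n_reps <- 40
  for (r in seq_len(n_reps)) {
    y <- rbinom(n, 1, p)
    fit <- fit_logit_trend(seq_len(n), y)
    if (!fit$separation && fit$slope > 0 && fit$p_wald < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_reps, 0.8)

  # stationary probability 0.2 -> classified none in most replicates
  none <- 0
  for (r in seq_len(n_reps)) {
    y <- rbinom(n, 1, 0.2)
    fit <- fit_logit_trend(seq_len(n), y)
    if (fit$separation || fit$p_wald >= 0.05) none <- none + 1
  }
  expect_gte(none / n_reps, 0.85)
})

test_that("coupling-frequency trend classification and odds summary are consistent", {
  sc <- small_scenario(seed = 77)
  env <- generate_env_grids(sc)
  idx <- which(env$trend_mask, arr.ind = TRUE)
  s <- build_location_series(env$lst$lon[idx[1, 1]], env$lst$lat[idx[1, 2]],
                             env$lst, env$rzsm, env$elev)
  tr <- coupling_frequency_trend(s)
  expect_true(tr$class %in% c("increase", "decrease", "none"))
  if (tr$class == "increase") {
    expect_gt(tr$slope, 0)
    expect_lt(tr$p_wald, 0.05)
    expect_gt(tr$odds$odds_ratio_total, 1)
  }
  # a location where coupling never occurs: separation -> class none
  cold <- s
  cold$lst_c <- rep(10, length(cold$lst_c))
  tr0 <- coupling_frequency_trend(cold)
  expect_true(tr0$fit$separation)
  expect_equal(tr0$class, "none")
})

test_that("stratified classification percentages partition each stratum", {
  sc <- small_scenario(seed = 79)
  env <- generate_env_grids(sc)
  pick <- rbind(which(env$trend_mask, arr.ind = TRUE)[1:4, ],
                which(!env$trend_mask, arr.ind = TRUE)[c(1, 50, 100, 200), ])
  locs <- lapply(seq_len(nrow(pick)), function(r)
    build_location_series(env$lst$lon[pick[r, 1]], env$lst$lat[pick[r, 2]],
                          env$lst, env$rzsm, env$elev))
  cls <- classify_all_locations(locs)
  for (st in list(cls$above, cls$below)) {
    if (st$n > 0) {
      pct_none <- 100 - st$pct_increase - st$pct_decrease
      expect_gte(pct_none, -1e-9)
      expect_lte(pct_none, 100 + 1e-9)
    }
  }
  expect_equal(cls$above$n + cls$below$n, length(locs))
  # alpha = 0 silences every classification
  cls0 <- classify_all_locations(locs, alpha = 0)
  expect_equal(cls0$above$pct_increase, 0)
  expect_equal(cls0$below$pct_increase, 0)
  expect_equal(cls0$below$pct_decrease, 0)
})

test_that("windowed PCA equals unwindowed on the full range and fails on empty windows", {
  sc <- small_scenario(seed = 81)
  env <- generate_env_grids(sc)
  occ <- generate_occurrences(sc, env)
  cleaned <- clean_occurrences(roundtrip_raw(occ))
  enr <- enrich_occurrences(cleaned$records, env$lst, env$rzsm, env$elev)
  sa <- enr[enr$species == "Striga asiatica", ]
  full <- windowed_pca(sa)
  explicit <- windowed_pca(sa, range(sa$year))
  expect_identical(full$loadings, explicit$loadings)
  expect_identical(full$explained, explicit$explained)
  expect_error(windowed_pca(sa, c(1900, 1901)), "complete records")
})
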