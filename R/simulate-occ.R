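#' Generate synthetic occurrence records
#'
#' Places each species' records by importance sampling over (cell, month)
#' candidates: weights are Gaussian niche densities around the species'
#' temperature and moisture optima evaluated on the lag-1 (previous month)
#' environment, times a Gaussian elevation preference whose center drifts by
#' `elev_trend_per_year`. Records therefore inherit the planted structure of
#' the grids: moisture-loving species land on wet cells, drifting species
#' move upslope over the years.
#'
#' A configurable fraction of additional defective rows (missing coordinates,
#' exact duplicates) is appended to exercise the cleaning stage; with both
#' fractions at zero the table is already clean.
#'
#' @param config a [scenario_config].
#' @param env grids from [generate_env_grids()] run on the same config.
#' @return data.frame with columns `record_id`, `species`,
#'   `decimalLongitude`, `decimalLatitude`, `year`, `month`.
#' @export
generate_occurrences <- function(config, env) {
  stopifnot(inherits(config, "scenario_config"))
  lst <- env$lst; rzsm <- env$rzsm; elev <- env$elev
  nx <- config$grid_nx; ny <- config$grid_ny
  times <- lst$times
  years <- config$start_year:config$end_year
  dx <- axis_spacing(lst$lon); dy <- axis_spacing(lst$lat)
  elev_vec <- as.vector(elev$values)  # cell-major (lon fastest)

  with_seed(substream_seed(config$seed, "occurrences"), {
    rows <- list()
    for (s in seq_len(nrow(config$species_niches))) {
      ni <- config$species_niches[s, ]
      # spread n_occurrences evenly over years (remainder to early years)
      n_per_year <- diff(round(seq(0, ni$n_occurrences, length.out = length(years) + 1)))
      for (yi in seq_along(years)) {
        if (n_per_year[yi] == 0) next
        y <- years[yi]
        # candidate months: those whose lag-1 month is inside the grid span
        cand_months <- 1:12
        if (y == config$start_year && times$month[1] == 1) cand_months <- 2:12
        w_all <- numeric(0); cell_all <- integer(0); month_all <- integer(0)
        elev_center <- ni$elev_pref_m + ni$elev_trend_per_year * (y - config$start_year)
        w_elev <- stats::dnorm(elev_vec, elev_center, ni$elev_sd_m)
        for (m in cand_months) {
          lm <- lag_month(y, m, 1)
          k <- time_index(lst, lm[[1]], lm[[2]])
          if (is.na(k)) next
          lst1 <- as.vector(lst$values[, , k])
          rzsm1 <- as.vector(rzsm$values[, , k])
          w <- stats::dnorm(lst1, ni$lst_mean, ni$lst_sd) *
            stats::dnorm(rzsm1, ni$rzsm_mean, ni$rzsm_sd) * w_elev
          w[is.na(w)] <- 0
          w_all <- c(w_all, w)
          cell_all <- c(cell_all, seq_len(nx * ny))
          month_all <- c(month_all, rep.int(m, nx * ny))
        }
        if (!length(w_all) || sum(w_all) <= 0)
          stop("niche of species '", ni$species,
               "' is incompatible with the generated grids (empty candidate set)")
        pick <- sample.int(length(w_all), n_per_year[yi], replace = TRUE, prob = w_all)
        ci <- (cell_all[pick] - 1L) %% nx + 1L
        cj <- (cell_all[pick] - 1L) %/% nx + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          species = ni$species,
          decimalLongitude = lst$lon[ci] + stats::runif(length(pick), -0.2, 0.2) * dx,
          decimalLatitude = lst$lat[cj] + stats::runif(length(pick), -0.2, 0.2) * dy,
          year = y, month = month_all[pick])
      }
    }
    occ <- do.call(rbind, rows)

    # planted defects: extra rows with missing coordinates, exact duplicates
    n <- nrow(occ)
    n_miss <- round(config$missing_fraction * n)
    n_dup <- round(config$duplicate_fraction * n)
    if (n_miss > 0) {
      bad <- occ[sample.int(n, n_miss, replace = TRUE), ]
      bad$decimalLongitude <- NA_real_
      bad$decimalLatitude <- NA_real_
      occ <- rbind(occ, bad)
    }
    if (n_dup > 0)
      occ <- rbind(occ, occ[sample.int(n, n_dup, replace = TRUE), ])
    occ <- occ[sample.int(nrow(occ)), ]  # shuffle so defects are interleaved
  })
  occ$record_id <- sprintf("r%06d", seq_len(nrow(occ)))
  rownames(occ) <- NULL
  occ[, c("record_id", "species", "decimalLongitude", "decimalLatitude",
          "year", "month")]
}
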