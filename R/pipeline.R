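#' Pipeline run configuration
#'
#' Parameters for an end-to-end run. In simulate mode (`scenario` given) the
#' synthetic world is generated in-memory and written alongside the results;
#' otherwise paths to an occurrence table and grid CSVs must be supplied and
#' are checked before any computation (fail fast).
#'
#' @param output_dir directory for all artifacts (created if needed).
#' @param scenario a [scenario_config()] for simulate mode, or `NULL`.
#' @param occurrence_path,lst_path,rzsm_path,elev_path input files for
#'   ingest mode (long-format grid CSVs, see [read_grid_csv()]).
#' @param coupling a [coupling_config()].
#' @param elevation_cutoff_trend strict cutoff (m) for the trend analyses.
#' @param elevation_cutoff_host inclusive cutoff (m) for the host analysis.
#' @param alpha significance gate for trend classification.
#' @param pca_windows list of two year ranges for the windowed PCA
#'   comparison.
#' @param pca_species,location_species focal species for the windowed PCA
#'   and the per-location trend analysis.
#' @param seed integer seed for any randomness in the run.
#' @return object of class `run_config`.
#' @export
run_config <- function(output_dir,
                       scenario = NULL,
                       occurrence_path = NULL, lst_path = NULL,
                       rzsm_path = NULL, elev_path = NULL,
                       coupling = coupling_config(),
                       elevation_cutoff_trend = 1000,
                       elevation_cutoff_host = 1000,
                       alpha = 0.05,
                       pca_windows = NULL,
                       pca_species = "Striga asiatica",
                       location_species = "Striga asiatica",
                       seed = 1L) {
  if (is.null(scenario)) {
    paths <- c(occurrence_path, lst_path, rzsm_path, elev_path)
    if (length(paths) < 4)
      stop("config error: need either a scenario or all four input paths")
    missing_paths <- paths[!file.exists(paths)]
    if (length(missing_paths))
      stop("config error: missing input file(s): ",
           paste(missing_paths, collapse = ", "))
  } else stopifnot(inherits(scenario, "scenario_config"))
  structure(list(output_dir = output_dir, scenario = scenario,
                 occurrence_path = occurrence_path, lst_path = lst_path,
                 rzsm_path = rzsm_path, elev_path = elev_path,
                 coupling = coupling,
                 elevation_cutoff_trend = elevation_cutoff_trend,
                 elevation_cutoff_host = elevation_cutoff_host,
                 alpha = alpha, pca_windows = pca_windows,
                 pca_species = pca_species,
                 location_species = location_species,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order — simulate (optional), ingest, clean,
#' enrich, per-species environmental summaries with compact letters,
#' per-species high-elevation logistic trends, coupling association,
#' per-location environmental and coupling-frequency trends with stratified
#' classification, host-crop presence across epochs, and windowed PCA — and
#' writes one artifact per stage plus a manifest recording configuration,
#' thresholds and row counts. Deterministic given the seed: a rerun with the
#' same config produces byte-identical numeric outputs. Any stage failure
#' aborts with the stage name.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage log lines.
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, msg) if (!quiet)
    message(sprintf("[%s] %s", stage, msg))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  manifest <- list(config = list(
    coupling = unclass(config$coupling),
    elevation_cutoff_trend = config$elevation_cutoff_trend,
    elevation_cutoff_host = config$elevation_cutoff_host,
    alpha = config$alpha, seed = config$seed,
    simulate = !is.null(config$scenario)))
  counts <- list()

  # -- simulate or ingest ----------------------------------------------------
  if (!is.null(config$scenario)) {
    sc <- config$scenario
    env <- stage("simulate", generate_env_grids(sc))
    occ_raw_df <- stage("simulate", generate_occurrences(sc, env))
    crops <- stage("simulate", generate_crop_grids(sc, env$elev))
    occ_path <- file.path(config$output_dir, "occurrences_raw.csv")
    write_csv_plain(occ_raw_df, occ_path)
    say("simulate", sprintf("%d raw records, %dx%d grid",
                            nrow(occ_raw_df), sc$grid_nx, sc$grid_ny))
  } else {
    env <- stage("ingest", list(lst = read_grid_csv(config$lst_path),
                                rzsm = read_grid_csv(config$rzsm_path),
                                elev = read_grid_csv(config$elev_path)))
    crops <- NULL
    occ_path <- config$occurrence_path
  }
  raw <- stage("ingest", read_occurrences(occ_path))
  counts$raw_rows <- nrow(raw)

  # -- clean -----------------------------------------------------------------
  cleaned <- stage("clean", clean_occurrences(raw))
  write_cleaning_report(cleaned$report,
                        file.path(config$output_dir, "cleaning_report.json"))
  write_csv_plain(cleaned$records,
                  file.path(config$output_dir, "occurrences_clean.csv"))
  counts$clean_rows <- cleaned$report$survivors
  counts$dropped <- cleaned$report$drops
  say("clean", sprintf("%d -> %d records", nrow(raw), counts$clean_rows))

  # -- enrich ----------------------------------------------------------------
  enriched <- stage("enrich", enrich_occurrences(cleaned$records,
                                                 env$lst, env$rzsm, env$elev))
  write_csv_plain(enriched, file.path(config$output_dir, "enriched.csv"))
  counts$enriched_rows <- nrow(enriched)
  counts$complete_temp <- sum(enriched$complete_temp)
  counts$complete_moist <- sum(enriched$complete_moist)
  counts$complete_coupling <- sum(enriched$complete_coupling)
  say("enrich", sprintf("%d records, %d coupling-complete",
                        nrow(enriched), counts$complete_coupling))

  # -- per-species environmental summaries with letters ----------------------
  summaries <- stage("summarize", {
    rows <- list()
    for (v in c("lst_c_lag1", "lst_c_lag2", "lst_pctile_lag1",
                "lst_pctile_lag2", "rzsm_pct_lag1", "rzsm_pct_lag2",
                "elevation_m")) {
      groups <- split(enriched[[v]], enriched$species)
      groups <- lapply(groups, function(g) g[!is.na(g)])
      groups <- groups[vapply(groups, length, integer(1)) >= 2]
      if (length(groups) < 2) next
      res <- anova_tukey_letters(groups, config$alpha)
      s <- res$summary
      s$variable <- v
      s$F <- res$F; s$p_anova <- res$p
      rows[[v]] <- s
    }
    do.call(rbind, rows)
  })
  rownames(summaries) <- NULL
  write_csv_plain(summaries, file.path(config$output_dir, "species_summaries.csv"))

  # -- per-species high-elevation trends -------------------------------------
  trend_rows <- stage("trends", {
    rows <- list()
    for (sp in sort(unique(enriched$species))) {
      occ <- enriched[enriched$species == sp, ]
      row <- tryCatch({
        tr <- elevation_trend(occ, cutoff = config$elevation_cutoff_trend)
        cbind(data.frame(species = sp), tr$table_row,
              odds_ratio_total = tr$odds$odds_ratio_total,
              delta_probability = tr$odds$delta_probability)
      }, error = function(e) NULL)
      if (!is.null(row)) rows[[sp]] <- row
    }
    do.call(rbind, rows)
  })
  rownames(trend_rows) <- NULL
  write_csv_plain(trend_rows, file.path(config$output_dir, "elevation_trends.csv"))
  say("trends", sprintf("%d species fitted", nrow(trend_rows)))

  # -- coupling association --------------------------------------------------
  assoc <- stage("coupling", species_association(enriched, config$coupling))
  write_csv_plain(assoc, file.path(config$output_dir, "coupling_association.csv"))

  # -- per-location trends + stratified classification -----------------------
  loc_results <- stage("locations", {
    occ <- enriched[enriched$species == config$location_species &
                      !is.na(enriched$lon) & !is.na(enriched$lat), ]
    if (!nrow(occ)) stop("no records for location species '",
                         config$location_species, "'")
    ci <- nearest_index(env$lst$lon, occ$lon)
    cj <- nearest_index(env$lst$lat, occ$lat)
    cells <- unique(stats::na.omit(data.frame(i = ci, j = cj)))
    locs <- lapply(seq_len(nrow(cells)), function(r)
      build_location_series(env$lst$lon[cells$i[r]], env$lst$lat[cells$j[r]],
                            env$lst, env$rzsm, env$elev, config$coupling))
    cls <- classify_all_locations(locs, config$elevation_cutoff_trend,
                                  config$alpha, config$coupling)
    mk <- do.call(rbind, lapply(locs, function(s) {
      tr <- location_env_trends(s)
      data.frame(lon = s$lon, lat = s$lat, elevation_m = s$elevation_m,
                 tau_lst = tr$lst$tau, p_lst = tr$lst$p,
                 tau_rzsm = tr$rzsm$tau, p_rzsm = tr$rzsm$p)
    }))
    per <- merge(mk, cls$per_location, by = c("lon", "lat", "elevation_m"))
    per <- per[order(per$lon, per$lat), ]
    list(per_location = per, above = cls$above, below = cls$below)
  })
  write_csv_plain(loc_results$per_location,
                  file.path(config$output_dir, "location_trends.csv"))
  jsonlite::write_json(list(above = loc_results$above, below = loc_results$below,
                            cutoff = config$elevation_cutoff_trend,
                            alpha = config$alpha),
                       file.path(config$output_dir, "trend_classification.json"),
                       auto_unbox = TRUE, digits = NA)
  counts$locations <- nrow(loc_results$per_location)
  say("locations", sprintf("%d locations classified", counts$locations))

  # -- host presence ---------------------------------------------------------
  hosts <- NULL
  if (!is.null(crops)) {
    hosts <- stage("hosts", presence_report(enriched, crops,
                                            cutoff = config$elevation_cutoff_host))
    write_csv_plain(hosts, file.path(config$output_dir, "host_presence.csv"))
  }

  # -- windowed PCA ----------------------------------------------------------
  pca_out <- stage("pca", {
    occ <- enriched[enriched$species == config$pca_species, ]
    windows <- config$pca_windows
    if (is.null(windows)) {
      yr <- range(occ$year)
      split_at <- floor(yr[1] + 0.7 * (yr[2] - yr[1]))
      windows <- list(c(yr[1], split_at), c(split_at + 1, yr[2]))
    }
    lapply(windows, function(w) {
      p <- windowed_pca(occ, w)
      list(years = w, loadings = p$loadings, explained = p$explained, n = p$n)
    })
  })
  jsonlite::write_json(pca_out, file.path(config$output_dir, "pca_windows.json"),
                       auto_unbox = TRUE, digits = NA)

  # -- manifest --------------------------------------------------------------
  manifest$counts <- counts
  manifest$reconciliation <- list(
    clean = counts$raw_rows == counts$clean_rows +
      sum(unlist(counts$dropped)),
    enrich = counts$enriched_rows == counts$clean_rows)
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done", sprintf("artifacts in %s", config$output_dir))
  invisible(list(env = env, enriched = enriched, summaries = summaries,
                 trend_rows = trend_rows, association = assoc,
                 locations = loc_results, hosts = hosts, pca = pca_out,
                 manifest = manifest))
}
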