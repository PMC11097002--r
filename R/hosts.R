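#' Study host map
#'
#' Host crops of the two focal parasites: *Orobanche crenata* parasitizes
#' grain legumes (beans, peas, lentils); *Striga asiatica* parasitizes
#' cereals (maize, sorghum, millet, rice; millet is a single layer).
#'
#' @return named list mapping species to host crop name vectors.
#' @export
default_host_map <- function() {
  list("Orobanche crenata" = c("beans", "peas", "lentils"),
       "Striga asiatica" = c("maize", "sorghum", "millet", "rice"))
}

#' Host presence at a point
#'
#' `TRUE` iff at least one of the species' host crops has harvested area
#' strictly greater than zero at the nearest grid cell (a conservative
#' presence/absence check, no area threshold). Points outside the grids are
#' `NA`; an empty host list is vacuously `FALSE`.
#'
#' @param lon,lat point coordinates (vectorized).
#' @param species species name; must be listed in `hostmap`.
#' @param epoch_grids named list `crop -> monthly_grid("CROP_AREA")` for one
#'   epoch.
#' @param hostmap named list from [default_host_map()].
#' @return logical vector with `NA` for undecidable points.
#' @export
host_present <- function(lon, lat, species, epoch_grids,
                         hostmap = default_host_map()) {
  if (!species %in% names(hostmap))
    stop("species '", species, "' is not in the host map")
  crops <- hostmap[[species]]
  if (!length(crops)) return(rep(FALSE, length(lon)))
  missing_layers <- setdiff(crops, names(epoch_grids))
  if (length(missing_layers))
    stop("epoch grids lack host crop layer(s): ",
         paste(missing_layers, collapse = ", "))
  vals <- vapply(crops, function(cr) sample_grid(epoch_grids[[cr]], lon, lat),
                 numeric(length(lon)))
  vals <- matrix(vals, nrow = length(lon))
  any_pos <- apply(vals, 1, function(r) any(r > 0, na.rm = TRUE))
  all_na <- apply(vals, 1, function(r) all(is.na(r)))
  out <- any_pos
  out[!any_pos & all_na] <- NA
  out
}

#' Host-presence report across epochs
#'
#' Cross-references parasite occurrences with the harvested-area grids of
#' both epochs, evaluated on the same occurrence set: percentage of
#' decidable records with at least one host present, over all locations and
#' over high-elevation locations (inclusive cutoff, "1000 m or higher").
#'
#' @param occurrences enriched records with `species`, `lon`, `lat`,
#'   `elevation_m`.
#' @param epochs named list `epoch -> named list crop -> grid` (e.g. from
#'   [generate_crop_grids()]).
#' @param hostmap named list from [default_host_map()].
#' @param cutoff high-elevation cutoff in meters (inclusive `>=`).
#' @return data.frame with one row per species x epoch: `species`, `epoch`,
#'   `n_all`, `pct_all`, `n_high_elev`, `pct_high_elev`.
#' @export
presence_report <- function(occurrences, epochs, hostmap = default_host_map(),
                            cutoff = 1000) {
  rows <- list()
  for (sp in names(hostmap)) {
    occ <- occurrences[occurrences$species == sp, , drop = FALSE]
    for (ep in names(epochs)) {
      pres <- if (nrow(occ)) host_present(occ$lon, occ$lat, sp, epochs[[ep]],
                                          hostmap) else logical(0)
      dec <- !is.na(pres)
      high <- dec & !is.na(occ$elevation_m) &
        high_elevation_flag(occ$elevation_m, cutoff, strict = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, epoch = ep,
        n_all = sum(dec),
        pct_all = if (sum(dec)) 100 * mean(pres[dec]) else NA_real_,
        n_high_elev = sum(high),
        pct_high_elev = if (sum(high)) 100 * mean(pres[high]) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
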