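#' Band area under a local chord baseline
#'
#' Trapezoidal integral of the spectrum over the band window after
#' subtracting the linear chord joining the intensities at the window
#' endpoints. The chord makes the area robust to residual baseline
#' curvature left after global correction (standard band-integration
#' practice); a pure linear ramp integrates to exactly zero. The area can
#' be negative on noise-only windows and is flagged rather than clamped
#' here.
#'
#' @param spectrum A baseline-corrected [raman_spectrum()].
#' @param band A [band_definition()]; its window must lie inside the grid.
#' @return List with `band`, `area` (intensity * cm-1) and `negative_flag`.
#' @export
band_area <- function(spectrum, band) {
  stopifnot(inherits(band, "band_definition"))
  w <- spectrum$wavenumber; y <- spectrum$intensity
  if (band$lo < min(w) || band$hi > max(w))
    stop(sprintf("band window [%g, %g] outside grid [%g, %g]",
                 band$lo, band$hi, min(w), max(w)))
  sel <- which(w >= band$lo & w <= band$hi)
  if (length(sel) < 3) stop("band window covers fewer than 3 grid points")
  ws <- w[sel]; ys <- y[sel]
  chord <- ys[1] + (ys[length(ys)] - ys[1]) * (ws - ws[1]) / (ws[length(ws)] - ws[1])
  area <- pracma::trapz(ws, ys - chord)
  if (!is.finite(area)) stop("band area is not finite")
  list(band = band, area = area, negative_flag = area < 0)
}

#' Lipid unsaturation ratio of a spectrum
#'
#' Ratio of the C=C stretch band area (~1654 cm-1) to the CH2 scissoring
#' band area (~1441 cm-1), the standard Raman measure of the unsaturated
#' fraction of lipids in the probed volume. A negative C=C area (noise
#' only) is clamped to zero for the ratio; the raw areas are returned. A
#' CH2 area at or below the floor `ch2_floor` marks the spectrum as
#' non-lipid: its ratio is NA and it is excluded from droplet statistics.
#'
#' @param spectrum A baseline-corrected, non-mean-centred
#'   [raman_spectrum()].
#' @param bands Band pair from [ratio_bands()].
#' @param ch2_floor Minimum admissible CH2 band area; for datasets use
#'   [ch2_floor_for()] (5% of the dataset median CH2 area).
#' @return List with `value`, `a_cc`, `a_ch2`, `non_lipid`.
#' @export
unsaturation_ratio <- function(spectrum, bands = ratio_bands(), ch2_floor = 0) {
  a_cc <- band_area(spectrum, bands$cc)
  a_ch2 <- band_area(spectrum, bands$ch2)
  if (a_ch2$area <= ch2_floor || a_ch2$area <= 0)
    return(list(value = NA_real_, a_cc = a_cc$area, a_ch2 = a_ch2$area,
                non_lipid = TRUE))
  list(value = max(0, a_cc$area) / a_ch2$area,
       a_cc = a_cc$area, a_ch2 = a_ch2$area, non_lipid = FALSE)
}

#' CH2 floor for a dataset
#'
#' The non-lipid floor used to exclude spectra with no appreciable CH2
#' signal: 5% of the dataset-median CH2 band area (the analogue of
#' zero-score non-lipid pixels in score maps).
#'
#' @param dataset A baseline-corrected [spectra_dataset()].
#' @param bands Band pair from [ratio_bands()].
#' @param fraction Fraction of the median (default 0.05).
#' @return Scalar floor value.
#' @export
ch2_floor_for <- function(dataset, bands = ratio_bands(), fraction = 0.05) {
  areas <- apply(dataset$intensities, 1, function(y)
    band_area(raman_spectrum(dataset$grid, y), bands$ch2)$area)
  fraction * stats::median(areas)
}

check_scoreable <- function(dataset) {
  if (!has_step(dataset, "baseline_correct"))
    stop("dataset must be baseline-corrected before scoring")
  if (has_step(dataset, "mean_center"))
    stop("mean-centred data cannot be scored (band areas lose positivity)")
}

# ratio on the mean spectrum of the given rows; the averaging rule used
# wherever per-droplet or per-adipocyte scores are reported
score_rows <- function(dataset, rows, bands, ch2_floor) {
  m <- colMeans(dataset$intensities[rows, , drop = FALSE])
  unsaturation_ratio(raman_spectrum(dataset$grid, m), bands, ch2_floor)
}

#' Score droplets and adipocytes of a population
#'
#' Computes the unsaturation score of every droplet (ratio on the mean of
#' its member spectra, not the mean of ratios) and of every adipocyte
#' (ratio on the mean of all its lipid spectra). The per-adipocyte mean of
#' droplet scores is reported as a secondary statistic, never substituted
#' for the averaged-spectrum score. Spectra whose CH2 area falls at or
#' below the dataset floor are excluded and counted.
#'
#' @param dataset A preprocessed (baseline-corrected, normalized, not
#'   mean-centred) [spectra_dataset()].
#' @param manifest Data frame with `spectrum_id`, `droplet_id`,
#'   `adipocyte_id`, `condition` and `diameter_um` columns, one row per
#'   spectrum in `dataset`.
#' @param bands Band pair from [ratio_bands()].
#' @return List with `droplets` and `adipocytes` data frames,
#'   `ch2_floor`, and `n_non_lipid` (excluded spectra count).
#' @export
score_population <- function(dataset, manifest, bands = ratio_bands()) {
  check_scoreable(dataset)
  stopifnot(nrow(manifest) == nrow(dataset$intensities))
  floor_val <- ch2_floor_for(dataset, bands)
  per_spec <- vapply(seq_len(nrow(dataset$intensities)), function(i) {
    r <- unsaturation_ratio(raman_spectrum(dataset$grid,
                                           dataset$intensities[i, ]),
                            bands, floor_val)
    c(r$value, r$non_lipid)
  }, numeric(2))
  spec_ratio <- per_spec[1, ]
  lipid <- per_spec[2, ] == 0
  n_non_lipid <- sum(!lipid)

  drop_rows <- split(seq_len(nrow(manifest)), manifest$droplet_id)
  droplets <- do.call(rbind, lapply(names(drop_rows), function(id) {
    rows <- drop_rows[[id]]
    keep <- rows[lipid[rows]]
    if (!length(keep)) return(NULL)            # all members non-lipid
    sc <- score_rows(dataset, keep, bands, floor_val)
    data.frame(droplet_id = id,
               adipocyte_id = manifest$adipocyte_id[rows[1]],
               condition = manifest$condition[rows[1]],
               diameter_um = manifest$diameter_um[rows[1]],
               n_spectra = length(keep),
               unsaturation_ratio = sc$value,
               stringsAsFactors = FALSE)
  }))
  rownames(droplets) <- NULL

  adip_rows <- split(seq_len(nrow(manifest)), manifest$adipocyte_id)
  adipocytes <- do.call(rbind, lapply(names(adip_rows), function(id) {
    rows <- adip_rows[[id]]
    keep <- rows[lipid[rows]]
    if (!length(keep)) return(NULL)
    sc <- score_rows(dataset, keep, bands, floor_val)
    dsc <- droplets$unsaturation_ratio[droplets$adipocyte_id == id]
    data.frame(adipocyte_id = id,
               condition = manifest$condition[rows[1]],
               n_spectra = length(keep),
               n_droplets = length(dsc),
               unsaturation_ratio = sc$value,
               mean_droplet_score = mean(dsc),
               stringsAsFactors = FALSE)
  }))
  rownames(adipocytes) <- NULL

  list(droplets = droplets, adipocytes = adipocytes,
       ch2_floor = floor_val, n_non_lipid = n_non_lipid)
}
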