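#' Default wavenumber grid
#'
#' Uniform grid over the 400-1800 cm-1 fingerprint region at 4 cm-1
#' spectral resolution (351 points), matching the acquisition settings the
#' pipeline models.
#'
#' @param from,to,by Grid limits and step in cm-1.
#' @return Numeric vector of wavenumbers.
#' @export
default_grid <- function(from = 400, to = 1800, by = 4) {
  seq(from, to, by = by)
}

# Run expr with a private RNG stream; restores the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Default saturated/unsaturated endmember pair
#'
#' Builds the two idealized pure-component ("endmember") lipid spectra from
#' which mixtures are synthesized, as sums of Gaussian bands:
#'
#' * saturated: 1061, 1129, 1296 cm-1 C-C skeletal markers plus the shared
#'   CH2 band at 1441 cm-1 (heights 0.6, 0.6, 0.8, 1.0; FWHM 12, 12, 14, 18);
#' * unsaturated: 1080 and 1267 cm-1 markers, the CH2 band at 1441 cm-1 and
#'   the C=C stretch at 1655 cm-1 (heights 0.5, 0.7, 0.8, 0.9;
#'   FWHM 16, 14, 18, 16).
#'
#' The saturated endmember carries no C=C band, so a pure saturated mixture
#' scores an unsaturation ratio of zero; with these defaults the pure
#' unsaturated endmember scores ~1.0 (the 1655 and 1441 band areas are
#' equal in closed form: 0.9*16 = 0.8*18).
#'
#' @param grid Wavenumber grid covering 400-1800 cm-1; every band centre
#'   must be covered to +/- 3 FWHM.
#' @return An object of class `endmember_pair` with elements `grid`,
#'   `saturated` and `unsaturated` (evaluated spectra), and the band lists.
#' @export
make_default_endmembers <- function(grid = default_grid()) {
  sat <- list(
    band_model(1061, 0.6, 12, "saturated"),
    band_model(1129, 0.6, 12, "saturated"),
    band_model(1296, 0.8, 14, "saturated"),
    band_model(1441, 1.0, 18, "shared")
  )
  uns <- list(
    band_model(1080, 0.5, 16, "unsaturated"),
    band_model(1267, 0.7, 14, "unsaturated"),
    band_model(1441, 0.8, 18, "shared"),
    band_model(1655, 0.9, 16, "unsaturated")
  )
  endmember_pair(sat, uns, grid)
}

#' Construct an endmember pair from band lists
#'
#' @param saturated_bands,unsaturated_bands Lists of [band_model()] objects.
#' @param grid Wavenumber grid; must cover each band centre +/- 3 FWHM.
#' @return An `endmember_pair` object.
#' @export
endmember_pair <- function(saturated_bands, unsaturated_bands,
                           grid = default_grid()) {
  for (b in c(saturated_bands, unsaturated_bands)) {
    if (min(grid) > b$center - 3 * b$fwhm || max(grid) < b$center + 3 * b$fwhm)
      stop(sprintf("grid does not cover band at %g cm-1 to +/- 3 FWHM", b$center))
  }
  s <- eval_bands(saturated_bands, grid)
  u <- eval_bands(unsaturated_bands, grid)
  stopifnot(all(s >= 0), all(u >= 0))
  structure(list(grid = grid, saturated = s, unsaturated = u,
                 saturated_bands = saturated_bands,
                 unsaturated_bands = unsaturated_bands),
            class = "endmember_pair")
}

# Polynomial baseline evaluated on the grid; coefficients apply to the
# wavenumber axis rescaled to [0, 1] so magnitudes are comparable to peak
# heights.
eval_baseline <- function(grid, coefficients) {
  if (length(coefficients) == 0) return(numeric(length(grid)))
  x <- (grid - min(grid)) / (max(grid) - min(grid))
  y <- numeric(length(grid))
  for (k in seq_along(coefficients)) y <- y + coefficients[k] * x^(k - 1)
  y
}

#' Simulate a single lipid droplet spectrum
#'
#' Linear two-endmember mixture with a smooth polynomial baseline and
#' additive Gaussian noise:
#' `I(nu) = (1 - f) S_sat(nu) + f S_unsat(nu) + baseline(nu) + N(0, noise_sd)`.
#'
#' @param pair An [endmember_pair()].
#' @param f Mixing fraction of the unsaturated endmember, in `[0, 1]`.
#' @param baseline Polynomial coefficients (intercept first) evaluated on
#'   the grid rescaled to `[0, 1]`; default no baseline.
#' @param noise_sd Standard deviation of the additive noise (>= 0).
#' @param seed Optional integer; when supplied the spectrum is a pure
#'   function of `(arguments, seed)`.
#' @return A [raman_spectrum()].
#' @export
simulate_ld_spectrum <- function(pair, f, baseline = 0, noise_sd = 0,
                                 seed = NULL) {
  stopifnot(inherits(pair, "endmember_pair"))
  if (!is.numeric(f) || length(f) != 1L || f < 0 || f > 1)
    stop("mixing fraction f must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  y <- (1 - f) * pair$saturated + f * pair$unsaturated +
    eval_baseline(pair$grid, baseline)
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) stats::rnorm(length(y), 0, noise_sd)
             else with_seed(seed, stats::rnorm(length(y), 0, noise_sd))
    y <- y + noise
  }
  raman_spectrum(pair$grid, y, meta = list(f_true = f))
}

# Lognormal reparameterized so that the sample mean/sd match the requested
# arithmetic mean/sd (the observable scale of droplet diameters).
rlnorm_moments <- function(n, mean, sd) {
  stopifnot(mean > 0, sd > 0)
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Beta distribution parameterized by mean and concentration (a+b).
rbeta_mean_conc <- function(n, mean, concentration) {
  stopifnot(mean > 0, mean < 1, concentration > 0)
  stats::rbeta(n, mean * concentration, (1 - mean) * concentration)
}

#' Condition specification for population simulation
#'
#' One culture condition of the simulated droplet population: how many
#' adipocytes, how many droplets (one point spectrum each) per adipocyte,
#' the Beta distribution of the unsaturated mixing fraction, and the
#' lognormal droplet diameter distribution (moment-matched to the given
#' arithmetic mean and sd, in micrometres).
#'
#' @param name Condition label.
#' @param n_adipocytes Number of adipocytes.
#' @param droplets_per_adipocyte Lipid droplets (= point spectra) per
#'   adipocyte.
#' @param f_mean Mean unsaturated mixing fraction in `(0, 1)`.
#' @param f_concentration Beta concentration (alpha + beta); larger means
#'   a tighter mixing-fraction distribution.
#' @param diameter_mean,diameter_sd Droplet diameter mean and sd, um.
#' @return A `sim_condition` list.
#' @export
sim_condition <- function(name, n_adipocytes, droplets_per_adipocyte,
                          f_mean, f_concentration = 20,
                          diameter_mean, diameter_sd) {
  stopifnot(n_adipocytes >= 0, droplets_per_adipocyte >= 1,
            f_mean > 0, f_mean < 1, diameter_mean > 0, diameter_sd > 0)
  structure(list(name = name, n_adipocytes = n_adipocytes,
                 droplets_per_adipocyte = droplets_per_adipocyte,
                 f_mean = f_mean, f_concentration = f_concentration,
                 diameter_mean = diameter_mean, diameter_sd = diameter_sd),
            class = "sim_condition")
}

#' Population simulation configuration
#'
#' Default conditions emulate the study design the pipeline targets: a
#' "spontaneous" condition with 120 adipocytes, 24 droplet spectra per
#' adipocyte, mean mixing fraction 0.40 and droplet diameters 5.24 +/-
#' 1.85 um, and an "induced" condition with 138 adipocytes, 21 spectra
#' per adipocyte, mean mixing fraction 0.55 and diameters 7.87 +/- 3.83 um.
#'
#' @param conditions List of [sim_condition()] objects.
#' @param pair Endmember pair used for all spectra.
#' @param baseline Polynomial baseline coefficients shared by all spectra.
#' @param noise_sd Additive noise sd.
#' @param seed Integer seed; fully determines the output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(conditions = list(
                         sim_condition("spontaneous", 120, 24, 0.40,
                                       diameter_mean = 5.24, diameter_sd = 1.85),
                         sim_condition("induced", 138, 21, 0.55,
                                       diameter_mean = 7.87, diameter_sd = 3.83)
                       ),
                       pair = make_default_endmembers(),
                       baseline = c(0.5, 0.3, -0.2),
                       noise_sd = 0.05,
                       seed = 1L) {
  stopifnot(length(conditions) >= 1, noise_sd >= 0)
  structure(list(conditions = conditions, pair = pair, baseline = baseline,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a droplet/adipocyte population
#'
#' Draws, per condition, adipocytes each carrying a set of lipid droplets;
#' every droplet gets a diameter from the condition's moment-matched
#' lognormal, a mixing fraction from the condition's Beta distribution, and
#' one point-mode spectrum from [simulate_ld_spectrum()]. The result is a
#' spectra dataset plus a manifest with one row per spectrum.
#'
#' @param config A [sim_config()].
#' @return List with elements `dataset` (a [spectra_dataset()]) and
#'   `manifest` (data frame: `spectrum_id`, `condition`, `adipocyte_id`,
#'   `droplet_id`, `diameter_um`, `f_true`, `acquisition_mode`).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (all(vapply(config$conditions, function(cn) cn$n_adipocytes, 0) == 0)) {
    warning("no adipocytes configured; returning empty dataset")
    return(list(dataset = spectra_dataset(config$pair$grid,
                                          matrix(0, 0, length(config$pair$grid))),
                manifest = data.frame()))
  }
  with_seed(config$seed, {
    rows <- list()
    specs <- list()
    idx <- 0L
    for (ci in seq_along(config$conditions)) {
      cn <- config$conditions[[ci]]
      if (cn$n_adipocytes == 0) next
      n_ld <- cn$n_adipocytes * cn$droplets_per_adipocyte
      diam <- rlnorm_moments(n_ld, cn$diameter_mean, cn$diameter_sd)
      f <- rbeta_mean_conc(n_ld, cn$f_mean, cn$f_concentration)
      k <- 0L
      for (a in seq_len(cn$n_adipocytes)) {
        for (d in seq_len(cn$droplets_per_adipocyte)) {
          k <- k + 1L; idx <- idx + 1L
          sp <- simulate_ld_spectrum(config$pair, f[k],
                                     baseline = config$baseline,
                                     noise_sd = config$noise_sd)
          specs[[idx]] <- sp$intensity
          rows[[idx]] <- data.frame(
            spectrum_id = sprintf("s%05d", idx),
            condition = cn$name,
            adipocyte_id = sprintf("%s_a%03d", cn$name, a),
            droplet_id = sprintf("%s_a%03d_d%03d", cn$name, a, d),
            diameter_um = diam[k],
            f_true = f[k],
            acquisition_mode = "point",
            stringsAsFactors = FALSE
          )
        }
      }
    }
    manifest <- do.call(rbind, rows)
    rownames(manifest) <- NULL
    dataset <- spectra_dataset(config$pair$grid,
                               do.call(rbind, specs), meta = manifest)
    list(dataset = dataset, manifest = manifest)
  })
}

#' Simulate a point-imaging Raman hyperspectral image
#'
#' Pixels on a 1 um XY grid. Pixels whose centre falls inside a droplet
#' circle carry that droplet's two-endmember lipid spectrum; overlapping
#' droplets are resolved nearest-centre-wins; background pixels carry only
#' baseline and noise (no lipid bands).
#'
#' @param pair Endmember pair.
#' @param droplets Data frame with columns `x`, `y`, `r` (um) and `f`
#'   (mixing fraction per droplet).
#' @param nx,ny Image extent in pixels (= um at 1 um step). Must cover all
#'   circles.
#' @param step Pixel step in um (default 1).
#' @param background Polynomial baseline coefficients for every pixel.
#' @param noise_sd Additive noise sd.
#' @param seed Integer seed.
#' @return An object of class `raman_image`: `grid`, `intensities`
#'   (n_pixels x n_wavenumbers), `pixels` data frame (`x`, `y`,
#'   `droplet` index or NA), `nx`, `ny`, `step`.
#' @export
simulate_raman_image <- function(pair, droplets, nx, ny, step = 1,
                                 background = c(0.5, 0.3, -0.2),
                                 noise_sd = 0.02, seed = 1L) {
  stopifnot(inherits(pair, "endmember_pair"),
            all(c("x", "y", "r", "f") %in% names(droplets)))
  if (any(droplets$x - droplets$r < 0) || any(droplets$x + droplets$r > nx * step) ||
      any(droplets$y - droplets$r < 0) || any(droplets$y + droplets$r > ny * step))
    stop("image extent does not cover all droplet circles")
  px <- expand.grid(x = seq_len(nx) * step - step / 2,
                    y = seq_len(ny) * step - step / 2)
  # nearest-centre-wins assignment among circles containing the pixel
  assign_px <- rep(NA_integer_, nrow(px))
  dist2 <- matrix(Inf, nrow(px), nrow(droplets))
  for (j in seq_len(nrow(droplets)))
    dist2[, j] <- (px$x - droplets$x[j])^2 + (px$y - droplets$y[j])^2
  inside <- sweep(sqrt(dist2), 2, droplets$r, `<=`)
  for (i in seq_len(nrow(px))) {
    cand <- which(inside[i, ])
    if (length(cand)) assign_px[i] <- cand[which.min(dist2[i, cand])]
  }
  base <- eval_baseline(pair$grid, background)
  with_seed(seed, {
    ints <- matrix(0, nrow(px), length(pair$grid))
    for (i in seq_len(nrow(px))) {
      y <- base
      if (!is.na(assign_px[i])) {
        f <- droplets$f[assign_px[i]]
        y <- y + (1 - f) * pair$saturated + f * pair$unsaturated
      }
      if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
      ints[i, ] <- y
    }
    structure(list(grid = pair$grid, intensities = ints,
                   pixels = data.frame(px, droplet = assign_px),
                   nx = nx, ny = ny, step = step),
              class = "raman_image")
  })
}

#' Simulate a fatty-acid quantification table
#'
#' Per-species amounts are `percent/100 * total` with multiplicative
#' lognormal noise of the given coefficient of variation. Units are
#' pmol/cm2, matching plated-culture HPLC quantification.
#'
#' @param profile Named numeric vector of species percentages (must sum to
#'   100 +/- 0.5).
#' @param total Total fatty-acid amount in pmol/cm2 (> 0).
#' @param cv Coefficient of variation of the multiplicative noise (>= 0).
#' @param sample_id,condition Labels copied into the table.
#' @param seed Integer seed.
#' @return A data frame with columns `species`, `amount`, `sample_id`,
#'   `condition`, `units`.
#' @export
simulate_fa_table <- function(profile, total, cv = 0, sample_id = "s1",
                              condition = "sim", seed = 1L) {
  if (abs(sum(profile) - 100) > 0.5)
    stop("profile percentages must sum to 100 +/- 0.5")
  if (total < 0) stop("total amount must be >= 0")
  amounts <- profile / 100 * total
  if (cv > 0) {
    s2 <- log(1 + cv^2)
    amounts <- with_seed(seed, amounts *
      stats::rlnorm(length(amounts), meanlog = -s2 / 2, sdlog = sqrt(s2)))
  }
  data.frame(species = names(profile), amount = unname(amounts),
             sample_id = sample_id, condition = condition,
             units = "pmol/cm2", stringsAsFactors = FALSE)
}

#' Default spontaneous-condition fatty-acid profile
#'
#' Percent composition used as the generator's spontaneous-culture profile:
#' 16:0 36, 16:1n-7 9, 18:0 11, 18:1n-9 26, 18:2n-6 4, 20:4n-6 5, other 9.
#'
#' @return Named numeric vector of percentages summing to 100.
#' @export
sop9_fa_profile <- function() {
  c("16:0" = 36, "16:1n-7" = 9, "18:0" = 11, "18:1n-9" = 26,
    "18:2n-6" = 4, "20:4n-6" = 5, "other" = 9)
}
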