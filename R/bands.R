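#' Gaussian band model
#'
#' A single Raman band modelled as a Gaussian line: centre position,
#' peak height and full width at half maximum, together with its
#' saturated/unsaturated assignment. These are the building blocks of the
#' synthetic endmember spectra.
#'
#' @param center Band centre in cm-1. Must lie in the 400-1800 cm-1
#'   fingerprint window used throughout.
#' @param height Peak height, arbitrary intensity units (>= 0).
#' @param fwhm Full width at half maximum in cm-1 (> 0).
#' @param assignment One of `"saturated"`, `"unsaturated"`, `"shared"`.
#' @return An object of class `band_model`.
#' @export
band_model <- function(center, height, fwhm,
                       assignment = c("shared", "saturated", "unsaturated")) {
  assignment <- match.arg(assignment)
  if (!is.numeric(center) || length(center) != 1L || center < 400 || center > 1800)
    stop("band center must be a single wavenumber in [400, 1800] cm-1")
  if (!is.numeric(height) || height < 0) stop("band height must be >= 0")
  if (!is.numeric(fwhm) || fwhm <= 0) stop("band fwhm must be > 0")
  structure(list(center = center, height = height, fwhm = fwhm,
                 assignment = assignment),
            class = "band_model")
}

#' @export
print.band_model <- function(x, ...) {
  cat(sprintf("<band %g cm-1, h = %g, fwhm = %g, %s>\n",
              x$center, x$height, x$fwhm, x$assignment))
  invisible(x)
}

# Gaussian profile evaluated on a wavenumber grid
gaussian_band <- function(nu, center, height, fwhm) {
  height * exp(-4 * log(2) * (nu - center)^2 / fwhm^2)
}

# Closed-form area of a Gaussian band: h * fwhm * sqrt(pi / (4 log 2))
gaussian_area <- function(height, fwhm) {
  height * fwhm * sqrt(pi / (4 * log(2)))
}

eval_bands <- function(bands, grid) {
  y <- numeric(length(grid))
  for (b in bands) y <- y + gaussian_band(grid, b$center, b$height, b$fwhm)
  y
}

#' Marker band table for loading interpretation
#'
#' The lipid marker bands used to read the polarity of a PCA loading:
#' C-C skeletal stretches of saturated acyl chains at 1061, 1129 and
#' 1296 cm-1, and the unsaturated markers at 1080, 1267 and 1655 cm-1
#' (the C=C stretch). Windows are +/- one typical FWHM around each centre.
#'
#' @return A data frame with columns `name`, `center`, `lo`, `hi`,
#'   `assignment`.
#' @export
marker_band_table <- function() {
  data.frame(
    name = c("1061", "1129", "1296", "1080", "1267", "1655"),
    center = c(1061, 1129, 1296, 1080, 1267, 1655),
    lo = c(1049, 1117, 1282, 1064, 1253, 1639),
    hi = c(1073, 1141, 1310, 1096, 1281, 1671),
    assignment = c("saturated", "saturated", "saturated",
                   "unsaturated", "unsaturated", "unsaturated"),
    stringsAsFactors = FALSE
  )
}

#' Band definition for area integration
#'
#' A named band with an explicit integration window. Areas are computed by
#' trapezoidal integration over the window after subtracting the local
#' linear chord between the window endpoints.
#'
#' @param name Band label.
#' @param center Nominal band centre, cm-1.
#' @param lo,hi Window bounds in cm-1 (`lo < center < hi`).
#' @param assignment Saturated/unsaturated/shared assignment.
#' @return An object of class `band_definition`.
#' @export
band_definition <- function(name, center, lo, hi,
                            assignment = c("shared", "saturated", "unsaturated")) {
  assignment <- match.arg(assignment)
  if (!(lo < center && center < hi))
    stop("band window must satisfy lo < center < hi")
  structure(list(name = name, center = center, lo = lo, hi = hi,
                 assignment = assignment),
            class = "band_definition")
}

#' Unsaturation-ratio band pair
#'
#' The two bands of the unsaturation ratio: the C=C stretch near
#' 1654 cm-1 (unsaturated marker) and the CH2 scissoring band near
#' 1441 cm-1 (present in all acyl chains). Windows are 1630-1690 and
#' 1400-1480 cm-1: wide enough to cover ~2 FWHM of typical lipid bands
#' while staying clear of the 1267 and 1296 cm-1 markers, and disjoint
#' from each other.
#'
#' @return A list with elements `cc` and `ch2`, each a [band_definition()].
#' @export
ratio_bands <- function() {
  list(
    cc = band_definition("C=C 1654", 1654, 1630, 1690, "unsaturated"),
    ch2 = band_definition("CH2 1441", 1441, 1400, 1480, "shared")
  )
}
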