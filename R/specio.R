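#' Raman spectrum object
#'
#' A single spectrum: strictly increasing wavenumber axis (cm-1), an
#' intensity vector of equal length with no NaN/Inf, and free-form metadata
#' (condition, adipocyte, droplet, acquisition mode).
#'
#' @param wavenumber Ascending numeric vector, cm-1.
#' @param intensity Numeric vector, same length, finite.
#' @param meta Named list of labels.
#' @return Object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(wavenumber, intensity, meta = list()) {
  if (length(wavenumber) != length(intensity))
    stop("wavenumber and intensity must have equal length")
  if (any(diff(wavenumber) <= 0))
    stop("wavenumbers must be strictly increasing")
  if (any(!is.finite(intensity)))
    stop("intensities must be finite (no NaN/Inf)")
  structure(list(wavenumber = as.numeric(wavenumber),
                 intensity = as.numeric(intensity), meta = meta),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum: %d points, %g-%g cm-1>\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

#' Spectra dataset on a common grid
#'
#' Rows are spectra, columns wavenumbers. The ordered list of applied
#' preprocessing steps is tracked append-only in the `steps` field, and
#' downstream stages check it: the unsaturation scorer requires baseline
#' correction and refuses mean-centred data, the chemometrics stage
#' requires the full baseline/normalize/mean-centre chain.
#'
#' @param grid Common wavenumber grid.
#' @param intensities Matrix `n_spectra x length(grid)`.
#' @param meta Optional data frame of per-spectrum labels (one row per
#'   spectrum).
#' @param steps Character vector of already-applied steps.
#' @return Object of class `spectra_dataset`.
#' @export
spectra_dataset <- function(grid, intensities, meta = NULL,
                            steps = character()) {
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != length(grid))
    stop("intensity matrix must have one column per grid point")
  if (any(!is.finite(intensities))) stop("intensities must be finite")
  if (!is.null(meta) && nrow(meta) != nrow(intensities))
    stop("meta must have one row per spectrum")
  structure(list(grid = as.numeric(grid), intensities = intensities,
                 meta = meta, steps = steps),
            class = "spectra_dataset")
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat(sprintf("<spectra_dataset: %d spectra x %d points; steps: %s>\n",
              nrow(x$intensities), length(x$grid),
              if (length(x$steps)) paste(x$steps, collapse = " -> ") else "none"))
  invisible(x)
}

has_step <- function(dataset, step) step %in% dataset$steps

#' Read a spectrum from disk
#'
#' Supports headerless two-column TSV (wavenumber, intensity) and a minimal
#' JCAMP-DX dialect with `XYDATA=(X++(Y..Y))`, honouring FIRSTX, DELTAX,
#' NPOINTS and YFACTOR. Descending wavenumber order is reversed on load
#' with a notice; non-monotone axes and non-finite intensities are
#' rejected.
#'
#' @param path File path.
#' @param format `"tsv"` or `"jcampdx"`.
#' @return A [raman_spectrum()].
#' @export
read_spectrum <- function(path, format = c("tsv", "jcampdx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    d <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("wavenumber", "intensity"))
    w <- d$wavenumber; y <- d$intensity
  } else {
    lines <- readLines(path)
    field <- function(key) {
      hit <- grep(sprintf("^##%s=", key), lines, value = TRUE)
      if (!length(hit)) return(NA_real_)
      as.numeric(sub(sprintf("^##%s=", key), "", hit[1]))
    }
    firstx <- field("FIRSTX"); deltax <- field("DELTAX")
    npoints <- field("NPOINTS"); yfactor <- field("YFACTOR")
    if (is.na(yfactor)) yfactor <- 1
    start <- grep("^##XYDATA=\\(X\\+\\+\\(Y\\.\\.Y\\)\\)", lines)
    if (!length(start)) stop("no XYDATA=(X++(Y..Y)) block in ", path)
    end <- grep("^##END=", lines)
    end <- if (length(end)) min(end[end > start[1]]) - 1L else length(lines)
    y <- numeric(0)
    for (ln in lines[(start[1] + 1L):end]) {
      vals <- as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]])
      if (!length(vals) || any(is.na(vals))) stop("unparseable XYDATA line: ", ln)
      y <- c(y, vals[-1])   # first value on each line is the line's X
    }
    if (is.na(firstx) || is.na(deltax)) stop("missing FIRSTX/DELTAX in ", path)
    if (!is.na(npoints) && length(y) != npoints)
      stop(sprintf("NPOINTS=%d but %d Y values read", npoints, length(y)))
    y <- y * yfactor
    w <- firstx + deltax * (seq_along(y) - 1)
  }
  if (all(diff(w) < 0)) {
    message("descending wavenumber axis in ", basename(path), "; reversing")
    w <- rev(w); y <- rev(y)
  }
  bad <- which(diff(w) <= 0)
  if (length(bad))
    stop(sprintf("non-monotone wavenumbers at line %d of %s", bad[1] + 1L, path))
  if (any(!is.finite(y))) stop("non-finite intensity in ", path)
  raman_spectrum(w, y)
}

#' Write a spectrum to disk
#'
#' Inverse of [read_spectrum()] for both formats; the JCAMP-DX writer emits
#' a uniform-grid `XYDATA=(X++(Y..Y))` block with YFACTOR 1.
#'
#' @param spectrum A [raman_spectrum()].
#' @param path Output path.
#' @param format `"tsv"` or `"jcampdx"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, format = c("tsv", "jcampdx")) {
  format <- match.arg(format)
  w <- spectrum$wavenumber; y <- spectrum$intensity
  if (format == "tsv") {
    utils::write.table(data.frame(w, y), path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  } else {
    dw <- diff(w)
    if (max(abs(dw - dw[1])) > 1e-9 * abs(dw[1]))
      stop("JCAMP-DX writer requires a uniform wavenumber grid")
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("##TITLE=ramanLD spectrum",
                 "##JCAMP-DX=4.24",
                 "##DATA TYPE=RAMAN SPECTRUM",
                 "##XUNITS=1/CM", "##YUNITS=ARBITRARY UNITS",
                 sprintf("##FIRSTX=%.10g", w[1]),
                 sprintf("##LASTX=%.10g", w[length(w)]),
                 sprintf("##DELTAX=%.10g", dw[1]),
                 sprintf("##NPOINTS=%d", length(w)),
                 "##YFACTOR=1",
                 "##XYDATA=(X++(Y..Y))"), con)
    per_line <- 6L
    for (i in seq(1, length(y), by = per_line)) {
      j <- min(i + per_line - 1L, length(y))
      writeLines(paste(c(sprintf("%.10g", w[i]),
                         sprintf("%.10g", y[i:j])), collapse = " "), con)
    }
    writeLines("##END=", con)
  }
  invisible(path)
}

#' Resample a spectrum onto a target grid
#'
#' Linear interpolation; extrapolation outside the source range is
#' rejected.
#'
#' @param spectrum A [raman_spectrum()].
#' @param grid Target wavenumber grid, within the source range.
#' @return A [raman_spectrum()] on `grid`.
#' @export
resample_spectrum <- function(spectrum, grid) {
  if (min(grid) < min(spectrum$wavenumber) ||
      max(grid) > max(spectrum$wavenumber))
    stop("target grid extends beyond source range (extrapolation refused)")
  if (length(grid) == length(spectrum$wavenumber) &&
      all(grid == spectrum$wavenumber)) return(spectrum)
  y <- stats::approx(spectrum$wavenumber, spectrum$intensity, xout = grid)$y
  raman_spectrum(grid, y, meta = spectrum$meta)
}
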