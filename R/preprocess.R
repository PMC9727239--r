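# Asymmetric least squares baseline (Eilers & Boelens). Smoothness penalty
# lambda on second differences; asymmetry p downweights points above the
# running baseline so peaks do not pull it up. The banded solve lives in
# compiled code (src/asls.cpp); this wrapper keeps a reference sparse-matrix
# path used to cross-check the factorization in the tests.
asls_baseline <- function(y, lambda = 1e5, p = 0.001, n_iter = 10) {
  z <- asls_baseline_cpp(y, lambda, p, as.integer(n_iter))
  list(baseline = as.numeric(z), converged = isTRUE(attr(z, "converged")))
}

# reference implementation via general sparse solves; oracle for the banded
# factorization, never the production path
asls_baseline_ref <- function(y, lambda = 1e5, p = 0.001, n_iter = 10) {
  m <- length(y)
  D <- Matrix::bandSparse(m - 2, m, k = 0:2,
                          diagonals = list(rep(1, m - 2), rep(-2, m - 2),
                                           rep(1, m - 2)))
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  converged <- FALSE
  for (i in seq_len(n_iter)) {
    z <- as.numeric(Matrix::solve(Matrix::Diagonal(m, w) + P, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (identical(w_new, w) && i > 1) { converged <- TRUE; break }
    w <- w_new
  }
  list(baseline = z, converged = converged)
}

#' Baseline-correct spectra by asymmetric least squares
#'
#' Fits a smooth baseline with asymmetric least squares (smoothness
#' `lambda`, asymmetry `p`, fixed iteration cap) and subtracts it. The
#' fitted baseline is retained for audit (`baselines` field on datasets,
#' `meta$baseline` on single spectra). Non-convergence within `n_iter`
#' returns the last iterate with a warning.
#'
#' @param x A [raman_spectrum()] or [spectra_dataset()] with >= 50 points.
#' @param lambda Smoothness penalty (default 1e5).
#' @param p Asymmetry parameter (default 0.001).
#' @param n_iter Reweighting iterations (default 10).
#' @return Same class as `x`, baseline subtracted.
#' @export
baseline_correct <- function(x, lambda = 1e5, p = 0.001, n_iter = 10) {
  UseMethod("baseline_correct")
}

#' @export
baseline_correct.raman_spectrum <- function(x, lambda = 1e5, p = 0.001,
                                            n_iter = 10) {
  if (length(x$wavenumber) < 50) stop("baseline correction needs >= 50 points")
  fit <- asls_baseline(x$intensity, lambda, p, n_iter)
  if (!fit$converged)
    warning("AsLS baseline did not converge in ", n_iter, " iterations")
  out <- raman_spectrum(x$wavenumber, x$intensity - fit$baseline, x$meta)
  out$meta$baseline <- fit$baseline
  out$meta$preprocessing <- c(x$meta$preprocessing, "baseline_correct")
  out
}

#' @export
baseline_correct.spectra_dataset <- function(x, lambda = 1e5, p = 0.001,
                                             n_iter = 10) {
  if (length(x$grid) < 50) stop("baseline correction needs >= 50 points")
  bl <- matrix(0, nrow(x$intensities), ncol(x$intensities))
  for (i in seq_len(nrow(x$intensities))) {
    fit <- asls_baseline(x$intensities[i, ], lambda, p, n_iter)
    bl[i, ] <- fit$baseline
  }
  out <- spectra_dataset(x$grid, x$intensities - bl, x$meta,
                         steps = c(x$steps, "baseline_correct"))
  out$baselines <- bl
  out
}

#' Normalize spectra
#'
#' Unit-vector (L2) normalization by default, per spectrum; a total-area
#' alternative is available. The unsaturation ratio is a ratio of areas and
#' is invariant to either choice; normalization matters only for the
#' clustering/PCA geometry, where unit-L2 is conventional.
#'
#' @param x A [raman_spectrum()] or [spectra_dataset()].
#' @param mode `"unit_vector"` (L2) or `"area"` (total trapezoid area).
#' @return Same class as `x`.
#' @export
normalize_spectra <- function(x, mode = c("unit_vector", "area")) {
  UseMethod("normalize_spectra")
}

norm_factor <- function(w, y, mode) {
  n <- switch(mode,
              unit_vector = sqrt(sum(y^2)),
              area = pracma::trapz(w, y))
  if (!is.finite(n) || abs(n) < 1e-300)
    stop("cannot normalize an all-zero spectrum")
  n
}

#' @export
normalize_spectra.raman_spectrum <- function(x, mode = c("unit_vector", "area")) {
  mode <- match.arg(mode)
  out <- raman_spectrum(x$wavenumber,
                        x$intensity / norm_factor(x$wavenumber, x$intensity, mode),
                        x$meta)
  out$meta$preprocessing <- c(x$meta$preprocessing, "normalize")
  out
}

#' @export
normalize_spectra.spectra_dataset <- function(x, mode = c("unit_vector", "area")) {
  mode <- match.arg(mode)
  ints <- x$intensities
  for (i in seq_len(nrow(ints)))
    ints[i, ] <- ints[i, ] / norm_factor(x$grid, ints[i, ], mode)
  out <- spectra_dataset(x$grid, ints, x$meta, steps = c(x$steps, "normalize"))
  out$baselines <- x$baselines
  out
}

#' Mean-centre a spectra dataset
#'
#' Subtracts the per-wavenumber mean across spectra and retains the mean
#' spectrum for PCA back-projection. Applies to the chemometrics matrix
#' only: the unsaturation scorer refuses mean-centred data because
#' centring destroys the positivity of band areas.
#'
#' @param dataset A [spectra_dataset()] with >= 2 spectra.
#' @return The centred dataset with a `mean_spectrum` field.
#' @export
mean_center <- function(dataset) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  if (nrow(dataset$intensities) < 2)
    stop("mean centring needs >= 2 spectra")
  mu <- colMeans(dataset$intensities)
  out <- spectra_dataset(dataset$grid, sweep(dataset$intensities, 2, mu),
                         dataset$meta, steps = c(dataset$steps, "mean_center"))
  out$mean_spectrum <- mu
  out
}

#' Standard preprocessing chain for scoring
#'
#' Baseline correction then unit-vector normalization, the state the
#' unsaturation scorer expects (mean centring is applied separately, and
#' only, for the multivariate stage).
#'
#' @param dataset A [spectra_dataset()].
#' @param lambda,p AsLS parameters, passed to [baseline_correct()].
#' @return Preprocessed dataset.
#' @export
preprocess <- function(dataset, lambda = 1e5, p = 0.001) {
  normalize_spectra(baseline_correct(dataset, lambda = lambda, p = p))
}
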