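#' Principal component analysis of a mean-centred spectra matrix
#'
#' Thin SVD of the mean-centred matrix. Scores are observation
#' coordinates, loadings are orthonormal per-wavenumber weights, and
#' explained fractions are the per-component shares of total variance
#' (non-increasing, summing to 1 over all components).
#'
#' @param dataset A mean-centred [spectra_dataset()] (the `mean_center`
#'   step must be present), or a plain numeric matrix with column means
#'   ~0.
#' @param n_components Number of components to keep (<= min(n, p)).
#' @return Object of class `spectra_pca`: `scores`, `loadings`,
#'   `explained_fraction`, `mean_spectrum`, `grid`.
#' @export
spectra_pca <- function(dataset, n_components = 2) {
  if (inherits(dataset, "spectra_dataset")) {
    if (!has_step(dataset, "mean_center"))
      stop("PCA requires a mean-centred dataset (run mean_center())")
    x <- dataset$intensities
    mu <- dataset$mean_spectrum
    grid <- dataset$grid
  } else {
    x <- as.matrix(dataset)
    if (max(abs(colMeans(x))) > 1e-8)
      stop("matrix is not mean-centred")
    mu <- rep(0, ncol(x))
    grid <- seq_len(ncol(x))
  }
  if (nrow(x) < 2) stop("PCA needs >= 2 observations")
  r <- min(nrow(x) - 1L, ncol(x))
  if (n_components > r)
    stop(sprintf("n_components = %d exceeds available rank %d", n_components, r))
  sv <- svd(x, nu = r, nv = r)
  var_comp <- sv$d[seq_len(r)]^2
  structure(list(
    scores = x %*% sv$v[, seq_len(n_components), drop = FALSE],
    loadings = sv$v[, seq_len(n_components), drop = FALSE],
    explained_fraction = var_comp / sum(sv$d^2),
    mean_spectrum = mu, grid = grid,
    n_components = n_components
  ), class = "spectra_pca")
}

#' Orient a PCA loading against marker bands
#'
#' Fixes the arbitrary sign of a component so that the mean loading value
#' over the saturated marker-band windows is positive (saturated peaks
#' positive, the C=C region negative), and reports per-band polarity. A
#' component with negligible weight over both band groups is flagged
#' uninterpretable.
#'
#' @param loading Numeric loading vector over `grid`.
#' @param grid Wavenumber grid.
#' @param band_table Marker bands, as from [marker_band_table()]; needs at
#'   least one saturated and one unsaturated band.
#' @param tol Mean-|loading| threshold below which a band group counts as
#'   absent.
#' @return List with `loading` (oriented), `flipped`, `uninterpretable`,
#'   and a `polarity` data frame (band, assignment, mean loading, sign).
#' @export
orient_loading <- function(loading, grid, band_table = marker_band_table(),
                           tol = 1e-6) {
  stopifnot(length(loading) == length(grid))
  if (!any(band_table$assignment == "saturated") ||
      !any(band_table$assignment == "unsaturated"))
    stop("band table needs >= 1 saturated and >= 1 unsaturated band")
  band_mean <- function(lo, hi) {
    sel <- grid >= lo & grid <= hi
    if (!any(sel)) NA_real_ else mean(loading[sel])
  }
  m <- mapply(band_mean, band_table$lo, band_table$hi)
  sat_mean <- mean(m[band_table$assignment == "saturated"], na.rm = TRUE)
  uns_mean <- mean(m[band_table$assignment == "unsaturated"], na.rm = TRUE)
  if (abs(sat_mean) < tol && abs(uns_mean) < tol) {
    return(list(loading = loading, flipped = FALSE, uninterpretable = TRUE,
                polarity = data.frame(band = band_table$name,
                                      assignment = band_table$assignment,
                                      mean_loading = m, sign = sign(m))))
  }
  flip <- sat_mean < 0
  if (flip) m <- -m
  list(loading = if (flip) -loading else loading,
       flipped = flip, uninterpretable = FALSE,
       polarity = data.frame(band = band_table$name,
                             assignment = band_table$assignment,
                             mean_loading = m, sign = sign(m)))
}

#' Ward clustering of spectra into lipid classes
#'
#' Agglomerative clustering (Ward's criterion, Euclidean distance) of
#' preprocessed spectra, cut at `k` groups; with the default `k = 3` the
#' groups are named by ranking cluster means of the unsaturation ratio:
#' `saturated_rich` < `mixture` < `unsaturated_rich`. Naming is a
#' deterministic function of the class mean ratios, so permuting input
#' order never changes labels. When between-class separation of the mean
#' ratios is below `delta` the result is flagged: three classes are still
#' returned but the generative three-class structure is absent.
#'
#' @param dataset A preprocessed [spectra_dataset()] (baseline +
#'   normalize), or a numeric matrix.
#' @param ratios Per-observation unsaturation ratios used to name classes.
#' @param k Number of classes (default 3). `k = 1` returns the degenerate
#'   single class `"mixture"`.
#' @param delta Minimum between-adjacent-class mean-ratio gap regarded as
#'   real separation (default 0.02).
#' @return Object of class `cluster_result`: `labels` (factor),
#'   `class_mean_ratios`, `linkage`, `k`, `low_separation`.
#' @export
ward_cluster <- function(dataset, ratios, k = 3, delta = 0.02) {
  x <- if (inherits(dataset, "spectra_dataset")) {
    if (!has_step(dataset, "baseline_correct") || !has_step(dataset, "normalize"))
      stop("clustering requires baseline-corrected, normalized spectra")
    dataset$intensities
  } else as.matrix(dataset)
  n <- nrow(x)
  stopifnot(length(ratios) == n)
  if (n < k) stop(sprintf("cannot form %d classes from %d spectra", k, n))
  class_names <- if (k == 3) c("saturated_rich", "mixture", "unsaturated_rich")
                 else if (k == 1) "mixture"
                 else paste0("class", seq_len(k))
  hc <- stats::hclust(stats::dist(x, method = "euclidean"), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  mean_ratio <- tapply(ratios, raw, mean)
  ord <- order(mean_ratio)                 # ascending unsaturation
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  labels <- factor(class_names[relabel[raw]], levels = class_names)
  cmr <- sort(as.numeric(mean_ratio))
  names(cmr) <- class_names
  low_sep <- k > 1 && any(diff(cmr) < delta)
  structure(list(labels = labels, class_mean_ratios = cmr,
                 linkage = "ward", k = k, low_separation = low_sep),
            class = "cluster_result")
}

#' Classify a droplet from its member-spectrum labels
#'
#' Majority vote over the labels of the droplet's member spectra; any tie
#' resolves to `"mixture"`; no labelled members gives `"unclassified"`.
#'
#' @param labels Character or factor vector of member-spectrum classes.
#' @return Single class string.
#' @export
classify_droplet <- function(labels) {
  labels <- as.character(labels)
  labels <- labels[!is.na(labels)]
  if (!length(labels)) return("unclassified")
  tab <- table(labels)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) > 1) "mixture" else winners
}

#' Per-pixel PC1 score map of a Raman image
#'
#' Preprocesses every pixel spectrum (AsLS baseline, unit-vector
#' normalization), mean-centres across the image, takes the first
#' principal component oriented against the marker bands, and returns the
#' per-pixel PC1 score. Pixels without appreciable lipid signal -- CH2
#' band area below a floor of 25% of the image maximum -- are masked to a
#' score of exactly 0 (black pixels). The floor is relative to the image
#' maximum because in-droplet CH2 areas are comparable across mixing
#' fractions while background areas are pure integration noise; 25% sits
#' several noise standard deviations above background at the generator's
#' default noise level.
#'
#' @param image A `raman_image` from [simulate_raman_image()].
#' @param bands Band pair from [ratio_bands()].
#' @param band_table Marker bands for loading orientation.
#' @param mask_fraction Lipid-mask floor as a fraction of the maximum CH2
#'   area in the image (default 0.05).
#' @return Object of class `score_map`: `scores` (ny x nx matrix),
#'   `lipid_mask` (logical matrix), `pca`, `polarity`.
#' @export
score_map <- function(image, bands = ratio_bands(),
                      band_table = marker_band_table(),
                      mask_fraction = 0.25) {
  stopifnot(inherits(image, "raman_image"))
  bc <- baseline_correct(spectra_dataset(image$grid, image$intensities))
  ch2 <- apply(bc$intensities, 1, function(y)
    band_area(raman_spectrum(bc$grid, y), bands$ch2)$area)
  mask <- ch2 > mask_fraction * max(ch2)
  if (sum(mask) < 2) stop("fewer than 2 lipid pixels in image")
  # the component is fitted on lipid pixels only: masked pixels represent
  # the absence of the component and score exactly 0
  lipid <- spectra_dataset(bc$grid, bc$intensities[mask, , drop = FALSE],
                           steps = bc$steps)
  centred <- mean_center(normalize_spectra(lipid))
  pca <- spectra_pca(centred, n_components = 1)
  ori <- orient_loading(pca$loadings[, 1], bc$grid, band_table)
  sc <- numeric(nrow(bc$intensities))
  sc[mask] <- as.numeric(centred$intensities %*% ori$loading)
  structure(list(
    scores = matrix(sc, image$ny, image$nx, byrow = TRUE),
    lipid_mask = matrix(mask, image$ny, image$nx, byrow = TRUE),
    pixel_scores = sc, pixel_mask = mask,
    pca = pca, polarity = ori$polarity
  ), class = "score_map")
}
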