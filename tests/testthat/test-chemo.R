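test_that("PCA recovers textbook geometry and conserves variance", {
  x <- rbind(c(0, 0), c(2, 2))
  xc <- scale(x, scale = FALSE)
  p <- spectra_pca(xc, n_components = 1)
  expect_equal(abs(p$loadings[, 1]), c(1, 1) / sqrt(2))
  expect_equal(p$explained_fraction[1], 1.0)

  set.seed(10)
  m <- matrix(rnorm(20 * 8), 20, 8)
  mc <- scale(m, scale = FALSE)
  p2 <- spectra_pca(mc, n_components = 8)
  expect_equal(sum(p2$explained_fraction), 1, tolerance = 1e-10)
  expect_true(all(diff(p2$explained_fraction) <= 1e-12))
  # full-rank reconstruction
  rec <- p2$scores %*% t(p2$loadings)
  expect_lt(norm(rec - mc, "F") / norm(mc, "F"), 1e-8)
  expect_error(spectra_pca(mc, n_components = 99), "exceeds")
})

test_that("noiseless two-endmember mixtures are rank one after centring", {
  pair <- make_default_endmembers()
  fs <- seq(0.1, 0.9, length.out = 12)
  m <- t(vapply(fs, function(f) simulate_ld_spectrum(pair, f)$intensity,
                numeric(length(pair$grid))))
  p <- spectra_pca(scale(m, scale = FALSE), n_components = 2)
  expect_gt(p$explained_fraction[1], 0.99)
})

test_that("loading orientation follows the saturated-positive convention", {
  pair <- make_default_endmembers()
  load_raw <- pair$saturated - pair$unsaturated
  load_raw <- load_raw - mean(load_raw)
  o <- orient_loading(load_raw, pair$grid)
  expect_false(o$uninterpretable)
  pol <- o$polarity
  expect_true(all(pol$sign[pol$assignment == "saturated"] > 0))
  expect_lt(pol$mean_loading[pol$band == "1655"], 0)

  # negated input gives the identical oriented loading
  o2 <- orient_loading(-load_raw, pair$grid)
  expect_equal(o2$loading, o$loading)
  expect_true(o2$flipped != o$flipped)

  # a loading orthogonal to both band groups is uninterpretable
  flat <- numeric(length(pair$grid))
  flat[pair$grid > 1700] <- 1
  expect_true(orient_loading(flat, pair$grid)$uninterpretable)
})

test_that("Ward clustering recovers the three-class structure", {
  pair <- make_default_endmembers()
  fs <- rep(c(0.05, 0.5, 0.95), each = 10)
  m <- t(vapply(fs, function(f) simulate_ld_spectrum(pair, f)$intensity,
                numeric(length(pair$grid))))
  ds <- normalize_spectra(baseline_correct(spectra_dataset(pair$grid, m)))
  ratios <- apply(ds$intensities, 1, function(y)
    unsaturation_ratio(raman_spectrum(ds$grid, y))$value)
  cl <- ward_cluster(ds, ratios)
  truth <- rep(c("saturated_rich", "mixture", "unsaturated_rich"), each = 10)
  expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1.0)
  expect_false(cl$low_separation)
  # class naming tracks the ratio ordering
  expect_true(all(diff(cl$class_mean_ratios) > 0))
  expect_named(cl$class_mean_ratios,
               c("saturated_rich", "mixture", "unsaturated_rich"))

  # permuting input order never changes named labels
  perm <- sample(length(fs))
  cl2 <- ward_cluster(ds$intensities[perm, ], ratios[perm])
  expect_equal(as.character(cl2$labels), as.character(cl$labels)[perm])

  # degenerate and error paths
  one <- ward_cluster(ds$intensities[1:5, ], ratios[1:5], k = 1)
  expect_true(all(one$labels == "mixture"))
  expect_error(ward_cluster(ds$intensities[1:2, ], ratios[1:2], k = 3),
               "cannot form")
})

test_that("absent three-class structure is flagged, not hidden", {
  pair <- make_default_endmembers()
  set.seed(14)
  m <- t(vapply(rep(0.5, 15), function(f)
    simulate_ld_spectrum(pair, f, noise_sd = 0.01)$intensity,
    numeric(length(pair$grid))))
  ds <- normalize_spectra(baseline_correct(spectra_dataset(pair$grid, m)))
  ratios <- apply(ds$intensities, 1, function(y)
    unsaturation_ratio(raman_spectrum(ds$grid, y))$value)
  cl <- ward_cluster(ds, ratios)
  expect_equal(nlevels(cl$labels), 3L)
  expect_true(cl$low_separation)
})

test_that("droplet classification is a majority vote with tie to mixture", {
  expect_equal(classify_droplet(c("unsaturated_rich", "unsaturated_rich",
                                  "unsaturated_rich", "mixture")),
               "unsaturated_rich")
  expect_equal(classify_droplet(c("saturated_rich", "unsaturated_rich")),
               "mixture")
  expect_equal(classify_droplet("saturated_rich"), "saturated_rich")
  expect_equal(classify_droplet(c(NA, NA)), "unclassified")
})

test_that("score maps assign lipid signal geometrically and mask background", {
  pair <- make_default_endmembers()
  drops <- data.frame(x = c(6, 14), y = c(10, 10), r = c(3.5, 3.5),
                      f = c(0.1, 0.9))
  img <- simulate_raman_image(pair, drops, nx = 20, ny = 20, noise_sd = 0,
                              seed = 5)
  # exactly the pixels with centre distance <= r carry lipid signal
  px <- img$pixels
  d1 <- sqrt((px$x - 6)^2 + (px$y - 10)^2)
  d2 <- sqrt((px$x - 14)^2 + (px$y - 10)^2)
  expect_identical(!is.na(px$droplet), d1 <= 3.5 | d2 <= 3.5)

  sm <- score_map(img)
  # background pixels score exactly zero
  expect_true(all(sm$pixel_scores[is.na(px$droplet)] == 0))
  # opposite mean in-droplet signs after orientation, saturated positive
  m1 <- mean(sm$pixel_scores[which(px$droplet == 1)])
  m2 <- mean(sm$pixel_scores[which(px$droplet == 2)])
  expect_gt(m1, 0)
  expect_lt(m2, 0)

  # uniform lipid content: all in-mask scores equal
  uni <- simulate_raman_image(pair, data.frame(x = 10, y = 10, r = 6, f = 0.5),
                              nx = 20, ny = 20, noise_sd = 0, seed = 5)
  smu <- score_map(uni)
  in_scores <- smu$pixel_scores[smu$pixel_mask]
  expect_lt(diff(range(in_scores)), 1e-8)

  # overlap resolves nearest-centre-wins
  ov <- simulate_raman_image(pair,
                             data.frame(x = c(9, 12), y = c(10, 10),
                                        r = c(3, 3), f = c(0, 1)),
                             nx = 20, ny = 20, noise_sd = 0, seed = 1)
  shared <- which(!is.na(ov$pixels$droplet))
  d_a <- (ov$pixels$x - 9)^2 + (ov$pixels$y - 10)^2
  d_b <- (ov$pixels$x - 12)^2 + (ov$pixels$y - 10)^2
  expect_true(all(ov$pixels$droplet[shared] ==
                  ifelse(d_a[shared] <= d_b[shared], 1L, 2L) |
                  d_a[shared] > 9 | d_b[shared] > 9))
  expect_error(simulate_raman_image(pair,
                                    data.frame(x = 1, y = 1, r = 5, f = 0.5),
                                    nx = 10, ny = 10), "extent")
})
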