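test_that("TSV spectra round-trip and validate", {
  path <- withr::local_tempfile(fileext = ".tsv")
  grid <- default_grid()
  writeLines(paste(grid, 1.0, sep = "\t"), path)
  s <- read_spectrum(path, "tsv")
  expect_length(s$wavenumber, 351)
  expect_true(all(s$intensity == 1))

  sp <- raman_spectrum(grid, sin(grid / 100) + 2)
  write_spectrum(sp, path, "tsv")
  back <- read_spectrum(path, "tsv")
  expect_equal(back$intensity, sp$intensity, tolerance = 1e-9)
  expect_equal(back$wavenumber, sp$wavenumber, tolerance = 1e-9)
})

test_that("JCAMP-DX round-trips and honours header fields", {
  path <- withr::local_tempfile(fileext = ".jdx")
  grid <- default_grid()
  sp <- raman_spectrum(grid, exp(-((grid - 1441) / 30)^2) + 0.1)
  write_spectrum(sp, path, "jcampdx")
  back <- read_spectrum(path, "jcampdx")
  expect_equal(back$wavenumber, sp$wavenumber, tolerance = 1e-9)
  expect_equal(back$intensity, sp$intensity, tolerance = 1e-9)

  # a hand-written block with YFACTOR and flat Y equals its TSV twin
  writeLines(c("##TITLE=x", "##FIRSTX=400", "##DELTAX=4",
               "##NPOINTS=351", "##YFACTOR=0.5",
               "##XYDATA=(X++(Y..Y))",
               vapply(seq(1, 351, 6), function(i) {
                 j <- min(i + 5, 351)
                 paste(c(400 + 4 * (i - 1), rep(2, j - i + 1)), collapse = " ")
               }, ""),
               "##END="), path)
  s2 <- read_spectrum(path, "jcampdx")
  expect_equal(s2$wavenumber, grid)
  expect_true(all(s2$intensity == 1))   # 2 * YFACTOR 0.5
})

test_that("descending axes are reversed and bad files rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(rev(default_grid()), seq(351, 1), sep = "\t"), path)
  expect_message(s <- read_spectrum(path, "tsv"), "reversing")
  expect_equal(s$intensity, seq(1, 351))

  writeLines(c("400\t1", "408\t1", "404\t1", "412\t1"), path)
  expect_error(read_spectrum(path, "tsv"), "line 3")
  writeLines(c("400\t1", "404\tNaN"), path)
  expect_error(read_spectrum(path, "tsv"), "finite")
})

test_that("resampling is exact on lines and stable for band areas", {
  grid <- default_grid()
  lin <- raman_spectrum(grid, 0.5 + 0.002 * grid)
  expect_identical(resample_spectrum(lin, grid)$intensity, lin$intensity)
  sub <- seq(600, 1600, 4)
  expect_equal(resample_spectrum(lin, sub)$intensity, 0.5 + 0.002 * sub)
  expect_error(resample_spectrum(lin, seq(300, 1700, 4)), "extrapolation")

  g <- raman_spectrum(grid, exp(-4 * log(2) * (grid - 1441)^2 / 18^2))
  g2 <- resample_spectrum(g, seq(400, 1800, 2))
  a1 <- band_area(g, ratio_bands()$ch2)$area
  a2 <- band_area(g2, ratio_bands()$ch2)$area
  expect_lt(abs(a2 / a1 - 1), 0.005)
})

test_that("AsLS baseline removes offsets and preserves band areas", {
  grid <- default_grid()
  flat <- raman_spectrum(grid, rep(5, length(grid)))
  # weights can jitter at floating-point level on an exactly flat input
  corr <- suppressWarnings(baseline_correct(flat))
  expect_lt(max(abs(corr$intensity)), 1e-3)

  # band on a linear ramp: recovered area within 2% of the ramp-free truth
  pair <- make_default_endmembers()
  clean <- simulate_ld_spectrum(pair, 0.5)
  ramped <- simulate_ld_spectrum(pair, 0.5, baseline = c(1, 2))
  corr2 <- suppressWarnings(baseline_correct(ramped))
  for (b in ratio_bands()) {
    expect_lt(abs(band_area(corr2, b)$area / band_area(clean, b)$area - 1),
              0.02)
  }

  # near-idempotence: band areas move < 1% on re-application
  corr3 <- baseline_correct(corr2)
  for (b in ratio_bands()) {
    expect_lt(abs(band_area(corr3, b)$area / band_area(corr2, b)$area - 1),
              0.01)
  }
})

test_that("banded AsLS solver agrees with the sparse-matrix reference", {
  set.seed(4)
  y <- 3 + 0.01 * (1:351) + 5 * exp(-((1:351) - 150)^2 / 40) + rnorm(351, 0, 0.05)
  fast <- ramanLD:::asls_baseline(y)
  ref <- ramanLD:::asls_baseline_ref(y)
  expect_equal(fast$baseline, ref$baseline, tolerance = 1e-6)
})

test_that("normalization is unit-norm, scale invariant and ratio neutral", {
  pair <- make_default_endmembers()
  s <- simulate_ld_spectrum(pair, 0.6)
  n1 <- normalize_spectra(s)
  expect_equal(sqrt(sum(n1$intensity^2)), 1, tolerance = 1e-12)
  s7 <- raman_spectrum(s$wavenumber, 7 * s$intensity)
  expect_equal(normalize_spectra(s7)$intensity, n1$intensity)
  expect_equal(unsaturation_ratio(n1)$value, unsaturation_ratio(s)$value,
               tolerance = 1e-12)
  expect_error(normalize_spectra(raman_spectrum(400:500, rep(0, 101))),
               "all-zero")
})

test_that("mean centring zeroes columns, is idempotent, and is tracked", {
  pair <- make_default_endmembers()
  m <- rbind(simulate_ld_spectrum(pair, 0.2)$intensity,
             simulate_ld_spectrum(pair, 0.8)$intensity)
  ds <- spectra_dataset(pair$grid, m, steps = c("baseline_correct", "normalize"))
  cen <- mean_center(ds)
  expect_lt(max(abs(colMeans(cen$intensities))), 1e-10)
  twice <- mean_center(cen)
  expect_equal(twice$intensities, cen$intensities)

  same <- spectra_dataset(pair$grid, rbind(m[1, ], m[1, ]))
  expect_true(all(mean_center(same)$intensities == 0))
  expect_error(mean_center(spectra_dataset(pair$grid, m[1, , drop = FALSE])),
               ">= 2")
  expect_equal(cen$steps, c("baseline_correct", "normalize", "mean_center"))
  # scorer refuses mean-centred data
  expect_error(score_population(cen, data.frame()), "mean-centred")
})
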