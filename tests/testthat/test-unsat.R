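test_that("band areas match zero, ramp and Gaussian oracles", {
  grid <- default_grid()
  b <- ratio_bands()
  zero <- raman_spectrum(grid, numeric(length(grid)))
  expect_equal(band_area(zero, b$ch2)$area, 0)

  ramp <- raman_spectrum(grid, 0.3 + 0.01 * grid)
  expect_equal(band_area(ramp, b$ch2)$area, 0, tolerance = 1e-10)

  gauss <- raman_spectrum(grid, exp(-4 * log(2) * (grid - 1441)^2 / 18^2))
  a <- band_area(gauss, b$ch2)
  expect_false(a$negative_flag)
  expect_equal(a$area, 19.0, tolerance = 0.3 / 19.0)

  expect_error(band_area(gauss, band_definition("x", 300, 250, 350)),
               "outside grid")
})

test_that("band_area agrees with a 0.1 cm-1 trapezoid oracle on the ratio bands", {
  pair <- make_default_endmembers()
  fun_sat <- endmember_fun(pair$saturated_bands)
  fun_uns <- endmember_fun(pair$unsaturated_bands)
  for (fun in list(fun_sat, fun_uns)) {
    for (bd in ratio_bands()) {
      oracle <- fine_trapz_band_area(fun, bd$lo, bd$hi)
      if (abs(oracle) < 0.5) next   # band absent from this endmember
      sp <- raman_spectrum(pair$grid, fun(pair$grid))
      expect_lt(abs(band_area(sp, bd)$area / oracle - 1), 0.015)
    }
  }
  # and on intermediate mixtures of the two endmembers
  for (f in c(0.25, 0.75)) {
    mix <- function(x) (1 - f) * fun_sat(x) + f * fun_uns(x)
    sp <- raman_spectrum(pair$grid, mix(pair$grid))
    for (bd in ratio_bands()) {
      oracle <- fine_trapz_band_area(mix, bd$lo, bd$hi)
      if (abs(oracle) < 0.5) next
      expect_lt(abs(band_area(sp, bd)$area / oracle - 1), 0.015)
    }
  }
})

test_that("unsaturation ratio hits the noiseless mixing anchors", {
  pair <- make_default_endmembers()
  r0 <- unsaturation_ratio(simulate_ld_spectrum(pair, 0))
  expect_equal(r0$value, 0)
  r1 <- unsaturation_ratio(simulate_ld_spectrum(pair, 1))
  expect_equal(r1$value, 1.00, tolerance = 0.02)
  r05 <- unsaturation_ratio(simulate_ld_spectrum(pair, 0.5))
  # closed form: windowed C=C area over mixture CH2 area
  expect_equal(r05$value, 0.444, tolerance = 0.01 / 0.444)
})

test_that("ratio is scale invariant and strictly increasing in f", {
  pair <- make_default_endmembers()
  s <- simulate_ld_spectrum(pair, 0.37)
  r <- unsaturation_ratio(s)$value
  for (c_ in c(0.01, 3, 1e4)) {
    sc <- raman_spectrum(s$wavenumber, c_ * s$intensity)
    expect_equal(unsaturation_ratio(sc)$value, r, tolerance = 1e-12)
  }
  fs <- seq(0, 1, by = 0.05)
  ratios <- vapply(fs, function(f)
    unsaturation_ratio(simulate_ld_spectrum(pair, f))$value, 0)
  expect_true(all(diff(ratios) > 0))
})

test_that("non-lipid spectra are excluded by the CH2 floor", {
  pair <- make_default_endmembers()
  r <- unsaturation_ratio(simulate_ld_spectrum(pair, 0.5), ch2_floor = 100)
  expect_true(r$non_lipid)
  expect_true(is.na(r$value))

  # dataset floor: 5% of the median CH2 area
  m <- rbind(simulate_ld_spectrum(pair, 0.3)$intensity,
             simulate_ld_spectrum(pair, 0.7)$intensity)
  ds <- spectra_dataset(pair$grid, m)
  fl <- ch2_floor_for(ds)
  areas <- apply(m, 1, function(y)
    band_area(raman_spectrum(pair$grid, y), ratio_bands()$ch2)$area)
  expect_equal(fl, 0.05 * stats::median(areas))
})

test_that("droplet scores use the averaged spectrum, not averaged scores", {
  pair <- make_default_endmembers()
  grid <- pair$grid
  mk_manifest <- function(n, droplet, adipocyte) data.frame(
    spectrum_id = sprintf("s%d", seq_len(n)), condition = "c",
    adipocyte_id = adipocyte, droplet_id = droplet, diameter_um = 5,
    stringsAsFactors = FALSE)

  # single-spectrum droplet equals the plain ratio
  s1 <- simulate_ld_spectrum(pair, 0.6)
  ds1 <- spectra_dataset(grid, rbind(s1$intensity),
                         steps = c("baseline_correct", "normalize"))
  sc1 <- score_population(ds1, mk_manifest(1, "d1", "a1"))
  expect_equal(sc1$droplets$unsaturation_ratio,
               unsaturation_ratio(s1)$value)
  expect_equal(sc1$adipocytes$unsaturation_ratio,
               sc1$droplets$unsaturation_ratio)

  # two identical spectra score like one
  ds2 <- spectra_dataset(grid, rbind(s1$intensity, s1$intensity),
                         steps = c("baseline_correct", "normalize"))
  sc2 <- score_population(ds2, mk_manifest(2, "d1", "a1"))
  expect_equal(sc2$droplets$unsaturation_ratio, sc1$droplets$unsaturation_ratio)
  expect_equal(sc2$droplets$n_spectra, 2L)

  # f = 0.2 and 0.8 average to the effective f = 0.5 spectrum
  m <- rbind(simulate_ld_spectrum(pair, 0.2)$intensity,
             simulate_ld_spectrum(pair, 0.8)$intensity)
  ds3 <- spectra_dataset(grid, m, steps = c("baseline_correct", "normalize"))
  sc3 <- score_population(ds3, mk_manifest(2, "d1", "a1"))
  r_eff <- unsaturation_ratio(simulate_ld_spectrum(pair, 0.5))$value
  expect_equal(sc3$droplets$unsaturation_ratio, r_eff, tolerance = 0.02)
  # and differs from the mean of the two individual ratios in general
  r_mean <- mean(c(unsaturation_ratio(simulate_ld_spectrum(pair, 0.2))$value,
                   unsaturation_ratio(simulate_ld_spectrum(pair, 0.8))$value))
  expect_false(isTRUE(all.equal(sc3$droplets$unsaturation_ratio, r_mean,
                                tolerance = 1e-4)))
})

test_that("adipocyte scores aggregate droplets and order conditions", {
  pop <- simulate_population(small_config(seed = 2, n_a = 20, n_b = 20))
  ds <- preprocess(pop$dataset)
  sc <- score_population(ds, pop$manifest)
  expect_setequal(sc$adipocytes$adipocyte_id, unique(pop$manifest$adipocyte_id))
  expect_true(all(sc$droplets$n_spectra >= 1))
  m <- tapply(sc$adipocytes$unsaturation_ratio, sc$adipocytes$condition, mean)
  expect_gt(m[["induced"]], m[["spontaneous"]])
  # secondary mean-of-droplet-scores reported alongside, not substituted
  expect_true("mean_droplet_score" %in% names(sc$adipocytes))
})
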