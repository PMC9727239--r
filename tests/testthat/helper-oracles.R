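# Independent oracles used across the suite.

# Closed-form Gaussian band area: h * fwhm * sqrt(pi / (4 log 2))
analytic_gauss_area <- function(height, fwhm) {
  height * fwhm * sqrt(pi / (4 * log(2)))
}

# Fine-grid (0.1 cm-1) trapezoid oracle for a band window, with the same
# local-chord convention, computed from first principles (no package
# integration code).
fine_trapz_band_area <- function(fun, lo, hi, step = 0.1) {
  x <- seq(lo, hi, by = step)
  y <- fun(x)
  chord <- y[1] + (y[length(y)] - y[1]) * (x - x[1]) / (x[length(x)] - x[1])
  r <- y - chord
  sum((r[-1] + r[-length(r)]) / 2 * diff(x))
}

# Evaluate a sum-of-Gaussians endmember as a plain function of wavenumber
endmember_fun <- function(bands) {
  function(x) {
    y <- numeric(length(x))
    for (b in bands)
      y <- y + b$height * exp(-4 * log(2) * (x - b$center)^2 / b$fwhm^2)
    y
  }
}

# Small fast population config for pipeline-level tests
small_config <- function(seed = 7, noise_sd = 0.05,
                         n_a = 12, n_b = 14, dpa = 3) {
  sim_config(conditions = list(
    sim_condition("spontaneous", n_a, dpa, 0.40,
                  diameter_mean = 5.24, diameter_sd = 1.85),
    sim_condition("induced", n_b, dpa, 0.55,
                  diameter_mean = 7.87, diameter_sd = 3.83)),
    noise_sd = noise_sd, seed = seed)
}

# One-spectrum-per-adipocyte config at the study's adipocyte counts,
# used for the parameter-recovery checks
recovery_config <- function(seed) {
  sim_config(conditions = list(
    sim_condition("spontaneous", 120, 1, 0.40,
                  diameter_mean = 5.24, diameter_sd = 1.85),
    sim_condition("induced", 138, 1, 0.55,
                  diameter_mean = 7.87, diameter_sd = 3.83)),
    noise_sd = 0.05, seed = seed)
}
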