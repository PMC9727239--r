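# Shared configuration for the analysis scripts: a desk-scale droplet
# population with the two culture conditions (spontaneous vs induced
# adipogenesis). Adipocyte counts are scaled to half the full design and
# droplets per adipocyte to 6 so the whole workflow runs in about a
# minute; the condition parameters themselves (mixing-fraction means,
# diameter distributions) are the full-design values.

library(ramanLD)

demo_seed <- 7L

demo_config <- function(seed = demo_seed) {
  sim_config(conditions = list(
    sim_condition("spontaneous", n_adipocytes = 60, droplets_per_adipocyte = 6,
                  f_mean = 0.40, diameter_mean = 5.24, diameter_sd = 1.85),
    sim_condition("induced", n_adipocytes = 69, droplets_per_adipocyte = 6,
                  f_mean = 0.55, diameter_mean = 7.87, diameter_sd = 3.83)),
    noise_sd = 0.05, seed = seed)
}

results_dir <- "results"
run_dir <- file.path(results_dir, "run")
dir.create(results_dir, showWarnings = FALSE)
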