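# Droplet statistics: diameter-vs-unsaturation correlation (expected
# near-zero R2 since the generator draws them independently), the 10 um
# threshold contrast, and the class-wise Kruskal-Wallis test.

source("analysis/00_config.R")

d <- read.csv(file.path(run_dir, "scores.csv"))

for (cn in unique(d$condition)) {
  r <- diameter_correlation(d, condition = cn)
  cat(sprintf("%s: ratio ~ diameter R2 = %.4f (n = %d)\n", cn, r$r_squared, r$n))
}

tc <- threshold_contrast(d, threshold = 10)
cat("\n10 um threshold strata (mean +/- sd unsaturation ratio):\n")
print(tc$strata[tc$strata$n > 0, ], row.names = FALSE)
cat(sprintf("%d pairwise Mann-Whitney tests, Bonferroni-adjusted\n", tc$m))

kw <- kruskal_wallis(split(d$unsaturation_ratio, d$class))
cat(sprintf("\nunsaturation ratio across lipid classes: Kruskal-Wallis H = %.1f, p = %.3g\n",
            kw$statistic, kw$p_value))

out <- list(diameter_correlation = lapply(
              setNames(nm = unique(d$condition)),
              function(cn) diameter_correlation(d, condition = cn)),
            threshold_strata = tc$strata,
            threshold_tests = lapply(tc$tests, unclass),
            class_test = unclass(kw))
jsonlite::write_json(out, file.path(results_dir, "droplet_stats.json"),
                     auto_unbox = TRUE, digits = NA, force = TRUE)
cat(sprintf("written to %s\n", file.path(results_dir, "droplet_stats.json")))
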