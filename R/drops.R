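test_report <- function(test_name, statistic, p_value, group_ns,
                        estimates = NULL, adjustment = "none", note = NULL) {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, group_ns = group_ns,
                 estimates = estimates, adjustment = adjustment, note = note),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("<%s: statistic = %.4g, p = %.4g, n = %s, adjustment = %s>\n",
              x$test_name, x$statistic, x$p_value,
              paste(x$group_ns, collapse = "/"), x$adjustment))
  invisible(x)
}

#' Linear correlation of unsaturation ratio with droplet diameter
#'
#' Ordinary least squares of the droplet unsaturation ratio on diameter,
#' per condition. R2 is `1 - SS_res / SS_tot`; a zero-variance predictor
#' or response yields R2 = 0 with a flag rather than NaN.
#'
#' @param records Droplet data frame with `diameter_um` and
#'   `unsaturation_ratio` (as from [score_population()]).
#' @param condition Optional condition filter.
#' @return List with `slope`, `intercept`, `r_squared`, `n`,
#'   `zero_variance`.
#' @export
diameter_correlation <- function(records, condition = NULL) {
  if (!is.null(condition)) records <- records[records$condition == condition, ]
  if (nrow(records) < 3) stop("need >= 3 droplet records")
  x <- records$diameter_um; y <- records$unsaturation_ratio
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(slope = 0, intercept = mean(y), r_squared = 0,
                n = length(y), zero_variance = TRUE))
  }
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = 1 - ss_res / ss_tot,
       n = length(y), zero_variance = FALSE)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact null enumeration when the combined sample size is <= 12 and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' correction. Identical groups (all values equal) report p = 1.
#'
#' @param group_a,group_b Numeric vectors (each n >= 1).
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return A `test_report` with the U statistic.
#' @export
mann_whitney <- function(group_a, group_b,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  if (length(unique(c(group_a, group_b))) == 1L)
    return(test_report("mann_whitney",
                       statistic = length(group_a) * length(group_b) / 2,
                       p_value = 1,
                       group_ns = c(length(group_a), length(group_b)),
                       estimates = c(median_a = stats::median(group_a),
                                     median_b = stats::median(group_b)),
                       note = "all values identical"))
  exact <- (length(group_a) + length(group_b) <= 12) &&
    !anyDuplicated(c(group_a, group_b))
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            alternative = alternative,
                                            exact = exact, correct = TRUE))
  test_report("mann_whitney", statistic = unname(wt$statistic),
              p_value = wt$p.value,
              group_ns = c(length(group_a), length(group_b)),
              estimates = c(median_a = stats::median(group_a),
                            median_b = stats::median(group_b)),
              note = if (exact) "exact enumeration" else "normal approximation")
}

#' Kruskal-Wallis rank test
#'
#' H statistic with tie correction and chi-square p-value on k - 1 degrees
#' of freedom. Identical values across all groups report H = 0, p = 1.
#'
#' @param groups List of >= 2 numeric vectors.
#' @return A `test_report`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("kruskal_wallis needs a list of >= 2 groups")
  ns <- lengths(groups)
  stopifnot(all(ns >= 1))
  values <- unlist(groups)
  if (length(unique(values)) == 1L)
    return(test_report("kruskal_wallis", statistic = 0, p_value = 1,
                       group_ns = ns, note = "all values identical"))
  kt <- stats::kruskal.test(values,
                            factor(rep(seq_along(groups), ns)))
  test_report("kruskal_wallis", statistic = unname(kt$statistic),
              p_value = kt$p.value, group_ns = ns,
              estimates = vapply(groups, stats::median, 0))
}

#' Diameter-threshold contrast of unsaturation ratios
#'
#' Stratifies droplets at a diameter threshold (default 10 um) within each
#' condition, tabulates group sizes and mean +/- sd ratios, and runs all
#' pairwise Mann-Whitney comparisons between the non-empty condition x
#' stratum groups with Bonferroni adjustment (`p_adj = min(1, m p)`, `m`
#' logged). Empty strata are reported as absent with a warning and no
#' test.
#'
#' @param records Droplet data frame (`condition`, `diameter_um`,
#'   `unsaturation_ratio`).
#' @param threshold Diameter threshold in um (default 10).
#' @return List with `strata` (data frame), `tests` (list of
#'   `test_report`s with adjusted p), and `m` (number of comparisons).
#' @export
threshold_contrast <- function(records, threshold = 10) {
  records$stratum <- ifelse(records$diameter_um > threshold,
                            sprintf(">%gum", threshold),
                            sprintf("<=%gum", threshold))
  key <- interaction(records$condition, records$stratum, drop = FALSE,
                     sep = " ")
  groups <- split(records$unsaturation_ratio, key)
  strata <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    data.frame(group = g, n = length(v),
               mean_ratio = if (length(v)) mean(v) else NA_real_,
               sd_ratio = if (length(v) > 1) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  empty <- strata$group[strata$n == 0]
  if (length(empty))
    warning("empty strata reported as absent: ", paste(empty, collapse = ", "))
  present <- names(groups)[lengths(groups) > 0]
  pairs <- if (length(present) >= 2) utils::combn(present, 2, simplify = FALSE)
           else list()
  m <- length(pairs)
  tests <- lapply(pairs, function(pr) {
    tr <- mann_whitney(groups[[pr[1]]], groups[[pr[2]]])
    tr$test_name <- sprintf("mann_whitney: %s vs %s", pr[1], pr[2])
    tr$p_value <- min(1, m * tr$p_value)
    tr$adjustment <- sprintf("bonferroni (m = %d)", m)
    tr
  })
  list(strata = strata, tests = tests, m = m, threshold = threshold)
}

#' Delta-delta-Ct fold change
#'
#' Relative expression with the reference Ct taken as the arithmetic mean
#' of housekeeping-gene Cts (equivalently, log2 of their geometric-mean
#' expression): `fold = 2^-[(Ct_t,s - mean(HKG_s)) - (Ct_t,r - mean(HKG_r))]`.
#'
#' @param target_ct_sample Target-gene Ct in the sample.
#' @param hkg_cts_sample Housekeeping-gene Cts in the sample (>= 2).
#' @param target_ct_ref Target-gene Ct in the reference.
#' @param hkg_cts_ref Housekeeping-gene Cts in the reference (>= 2).
#' @return Fold change (numeric).
#' @export
ddct_fold_change <- function(target_ct_sample, hkg_cts_sample,
                             target_ct_ref, hkg_cts_ref) {
  if (length(hkg_cts_sample) < 2 || length(hkg_cts_ref) < 2)
    stop("need >= 2 housekeeping genes in sample and reference")
  cts <- c(target_ct_sample, hkg_cts_sample, target_ct_ref, hkg_cts_ref)
  if (any(!is.finite(cts))) stop("all Ct values must be finite")
  ddct <- (target_ct_sample - mean(hkg_cts_sample)) -
          (target_ct_ref - mean(hkg_cts_ref))
  2^(-ddct)
}
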