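#' Parse a fatty-acid shorthand name
#'
#' Parses `C:D` or `C:Dn-x` nomenclature ("16:0", "16:1n-7", "20:4n-6").
#' The hyphen-less dialect "18:2n6" is accepted and normalized to "18:2n-6"
#' with a notice. An omega class on a saturated species is rejected; an
#' unsaturated species without an omega class is allowed (some shorthand
#' tables omit it, e.g. "14:1").
#'
#' @param text Species name.
#' @return List with `carbons`, `double_bonds`, `omega_class` (e.g. "n-7"
#'   or NA), `display_name` (canonical form).
#' @export
parse_fa_name <- function(text) {
  m <- regexec("^\\s*([0-9]+):([0-9]+)\\s*(?:n-?([0-9]+))?\\s*$", text)
  g <- regmatches(text, m)[[1]]
  if (!length(g)) {
    bad <- regexpr("[^0-9: n-]|^$", text)
    stop(sprintf("malformed fatty-acid name '%s' (near position %d)",
                 text, max(1L, bad[1])))
  }
  carbons <- as.integer(g[2]); db <- as.integer(g[3])
  omega <- if (nzchar(g[4])) paste0("n-", g[4]) else NA_character_
  if (carbons < 2) stop("fatty acid must have >= 2 carbons: ", text)
  if (db == 0 && !is.na(omega))
    stop("saturated species cannot carry an omega class: ", text)
  if (!is.na(omega) && !grepl("n-", text, fixed = TRUE))
    message("normalized '", text, "' to '",
            paste0(carbons, ":", db, omega), "'")
  list(carbons = carbons, double_bonds = db, omega_class = omega,
       display_name = paste0(carbons, ":", db,
                             if (!is.na(omega)) omega else ""))
}

#' Classify a fatty-acid species as SFA, MUFA or PUFA
#'
#' Zero double bonds is saturated, one is monounsaturated, two or more is
#' polyunsaturated.
#'
#' @param species A parsed species from [parse_fa_name()], or a name.
#' @return `"SFA"`, `"MUFA"` or `"PUFA"`.
#' @export
classify_species <- function(species) {
  if (is.character(species)) species <- parse_fa_name(species)
  db <- species$double_bonds
  if (db == 0) "SFA" else if (db == 1) "MUFA" else "PUFA"
}

# species that do not parse (pooled "other" rows) get class NA
safe_class <- function(name) {
  tryCatch(classify_species(name), error = function(e) NA_character_)
}

#' Convert an amount-mode fatty-acid table to percentages
#'
#' Per-sample percentages (`100 * amount / total`) plus SFA/MUFA/PUFA
#' class sums. Unparseable species names (e.g. pooled "other") keep their
#' percentage but fall outside the three classes; class sums over
#' classified species plus the unclassified remainder total 100.
#'
#' @param table Data frame with `species`, `amount`, `sample_id` columns
#'   (as from [simulate_fa_table()]).
#' @return List with `table` (percent-mode, added `percent` and `class`
#'   columns) and `class_sums` (per sample).
#' @export
percent_of_total <- function(table) {
  stopifnot(all(c("species", "amount", "sample_id") %in% names(table)))
  if (any(table$amount < 0)) stop("amounts must be >= 0")
  out <- do.call(rbind, lapply(split(table, table$sample_id), function(d) {
    total <- sum(d$amount)
    if (total <= 0) stop("zero total amount for sample ", d$sample_id[1])
    d$percent <- 100 * d$amount / total
    d$class <- vapply(d$species, safe_class, "")
    d
  }))
  rownames(out) <- NULL
  class_sums <- do.call(rbind, lapply(split(out, out$sample_id), function(d) {
    s <- tapply(d$percent, factor(d$class, levels = c("SFA", "MUFA", "PUFA")),
                sum, default = 0)
    data.frame(sample_id = d$sample_id[1], SFA = s[["SFA"]],
               MUFA = s[["MUFA"]], PUFA = s[["PUFA"]],
               other = 100 - sum(s), stringsAsFactors = FALSE)
  }))
  rownames(class_sums) <- NULL
  list(table = out, class_sums = class_sums)
}

#' Fatty-acid unsaturation ratio at a chain length
#'
#' The monounsaturated-to-saturated ratio at equal chain length: the sum
#' of all `C:1` positional isomers over the `C:0` amount (`C` = 16 or 18
#' in practice). Works on amount- or percent-mode tables (the ratio is
#' scale-free within a sample). Absent numerator gives 0; absent or zero
#' denominator is rejected.
#'
#' @param table Data frame with `species` and `amount` (or `percent`)
#'   columns for one sample.
#' @param carbons Chain length (e.g. 16 or 18).
#' @return List with `value`, `numerator_species`, `denominator_species`.
#' @export
unsaturation_ratio_fa <- function(table, carbons) {
  col <- if ("percent" %in% names(table)) "percent" else "amount"
  parsed <- lapply(table$species, function(s)
    tryCatch(parse_fa_name(s), error = function(e) NULL))
  ok <- !vapply(parsed, is.null, TRUE)
  cc <- vapply(parsed[ok], `[[`, 0L, "carbons")
  db <- vapply(parsed[ok], `[[`, 0L, "double_bonds")
  amt <- table[[col]][ok]
  sp <- table$species[ok]
  den_sel <- cc == carbons & db == 0
  if (!any(den_sel) || sum(amt[den_sel]) <= 0)
    stop(sprintf("denominator species %d:0 absent or zero", carbons))
  num_sel <- cc == carbons & db == 1
  list(value = sum(amt[num_sel]) / sum(amt[den_sel]),
       numerator_species = sp[num_sel],
       denominator_species = sp[den_sel])
}

#' Round half-up
#'
#' Decimal rounding with ties away from zero (the convention of printed
#' summary tables), unlike R's banker's rounding.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Constitutive-to-regulated contrast
#'
#' Quotient of a constitutive-site unsaturation ratio over the matched
#' regulated-site ratio, rounded half-up to one decimal for table
#' reproduction; the unrounded quotient is kept in the `"raw"` attribute.
#'
#' @param ratio_constitutive,ratio_regulated Per-site ratios
#'   (`ratio_regulated > 0`).
#' @return Rounded contrast with attribute `raw`.
#' @export
cr_contrast <- function(ratio_constitutive, ratio_regulated) {
  if (ratio_regulated <= 0) stop("regulated ratio must be > 0")
  raw <- ratio_constitutive / ratio_regulated
  structure(round_half_up(raw, 1), raw = raw)
}

#' Fold change of totals
#'
#' @param total_a,total_b Totals in the same units (`total_b > 0`).
#' @return `total_a / total_b`.
#' @export
fold_change <- function(total_a, total_b) {
  if (total_b <= 0) stop("denominator total must be > 0")
  total_a / total_b
}

#' Compiled cross-species marrow-adipocyte unsaturation ratios
#'
#' The packaged fixture of per-site 16:1/16:0 and 18:1/18:0 fatty-acid
#' unsaturation ratios for rat, rabbit, human and OP9 cultures
#' (constitutive/induced vs regulated/spontaneous sites), with the printed
#' contrast column. The OP9 16:1/16:0 row is flagged: its printed contrast
#' (1.6) is inconsistent with its own per-site ratios (0.84/0.24 = 3.5)
#' and is excluded from reproduction checks.
#'
#' @return Data frame with columns `origin`, `pair`, `ratio_constitutive`,
#'   `ratio_regulated`, `cr_printed`, `flag`.
#' @export
compiled_bmad_ratios <- function() {
  path <- system.file("extdata", "bmad_unsaturation_ratios.csv",
                      package = "ramanLD")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (any(d$flag != "" & is.na(d$cr_printed)))
    stop("fixture corrupt")
  d
}
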