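Package: ramanLD
Title: Single Lipid Droplet Raman Unsaturation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for lipid unsaturation analysis of single
    lipid droplets by Raman microspectroscopy. Simulates two-endmember lipid
    Raman spectra, droplet and adipocyte populations, and hyperspectral
    images; preprocesses spectra (asymmetric least squares baseline, unit
    vector normalization, mean centering); scores lipid unsaturation as the
    1654/1441 cm-1 band area ratio; classifies spectra into saturated-rich,
    mixture and unsaturated-rich classes by Ward clustering with PCA loading
    interpretation; and runs droplet/adipocyte statistics plus fatty-acid
    composition table arithmetic (SFA/MUFA/PUFA class sums, 16:1/16:0 and
    18:1/18:0 unsaturation ratios, constitutive-to-regulated contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    mclust,
    pracma,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
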