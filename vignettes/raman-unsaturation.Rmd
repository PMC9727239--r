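---
title: "Methods: single lipid droplet Raman unsaturation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single lipid droplet Raman unsaturation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ramanLD)
```

This vignette is the package's own account of the model it implements, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

## The measurement model

Raman microspectroscopy probes the molecular composition of a femtolitre
focal volume inside a single lipid droplet (LD). Lipid spectra in the
400–1800 cm⁻¹ fingerprint region carry two families of marker bands: C–C
skeletal stretches of saturated acyl chains at 1061, 1129 and 1296 cm⁻¹,
and unsaturated markers at 1080 and 1267 cm⁻¹ plus the C=C stretch at
~1654/1655 cm⁻¹. The CH₂ scissoring band at ~1441 cm⁻¹ is present in all
acyl chains and serves as the normalizing reference. The degree of lipid
unsaturation is scored as

$$\text{unsaturation ratio} = \frac{A(\nu_{C=C})}{A(\nu_{CH_2})}$$

the ratio of the two band areas. This ratio is scale-free: laser power,
collection efficiency and spectrum normalization all cancel.

## The synthetic-data generator

The generator replaces the microscope. Spectra are linear mixtures of two
idealized *endmember* spectra — pure saturated and pure unsaturated lipid —
each a sum of Gaussian bands on a uniform grid from 400 to 1800 cm⁻¹ at
4 cm⁻¹ steps (351 points, the acquisition resolution being emulated):

* saturated: (1061, h 0.6, FWHM 12), (1129, 0.6, 12), (1296, 0.8, 14),
  (1441, 1.0, 18);
* unsaturated: (1080, 0.5, 16), (1267, 0.7, 14), (1441, 0.8, 18),
  (1655, 0.9, 16).

Band centres are the standard lipid assignments; heights and widths are
package defaults chosen so that (i) the saturated endmember has no C=C
band, anchoring the ratio at exactly 0 for a pure saturated droplet, and
(ii) the 1655 and 1441 areas of the unsaturated endmember are equal in
closed form (0.9·16 = 0.8·18, Gaussian area = h·FWHM·√(π/4ln2)), anchoring
the ratio near 1.0 for a pure unsaturated droplet. A droplet with
unsaturated mixing fraction $f$ gets

$$I(\nu) = (1-f)\,S_{sat}(\nu) + f\,S_{unsat}(\nu) + b(\nu) + \varepsilon,$$

with $b$ a low-order polynomial baseline (coefficients on the grid
rescaled to [0, 1]; default (0.5, 0.3, −0.2), a gentle positive hump of
roughly half the main peak height) and $\varepsilon$ iid Gaussian noise
(default sd 0.05, i.e. 5% of the tallest band). Pure Gaussians were chosen
over pseudo-Voigt because their closed-form areas give exact oracles for
the integration tests.

Populations draw, per condition: a number of adipocytes, a fixed number of
droplets per adipocyte (one point-mode spectrum each, the "one spectrum is
one droplet" acquisition convention), per-droplet mixing fractions from a
Beta distribution parameterized by mean and concentration (default
concentration 20; the source data give no generative model for
composition, and a Beta is the natural bounded choice), and per-droplet
diameters from a lognormal *moment-matched* to the configured arithmetic
mean and sd — lognormal because diameters are positive and right-skewed,
moment-matched because the emulated study reports mean ± sd only. The
default conditions are the study design: "spontaneous" with 120 adipocytes
× 24 droplets, mean $f$ 0.40, diameters 5.24 ± 1.85 µm; "induced" with 138
× 21, mean $f$ 0.55, diameters 7.87 ± 3.83 µm. The mean mixing fractions
are package choices: the source reports ratio contrasts, not mixing
fractions, and 0.40 vs 0.55 places the two conditions' mean ratios in the
reported ordering with realistic overlap.

Hyperspectral images place droplet circles on a 1 µm pixel grid; pixels
inside a circle carry that droplet's lipid mixture, overlap resolves
nearest-centre-wins, and background pixels carry baseline and noise only.

What the generator does **not** emulate: cosmic-ray spikes, detector
etaloning, fluorescence photobleaching, within-droplet composition
gradients (each droplet has a single $f$), correlation between droplet
diameter and composition (the two are drawn independently, matching the
reported absence of correlation but by construction rather than by
biology), and adipocyte-level random effects on composition. Passing tests
therefore demonstrate that the pipeline recovers known structure from
spectra with realistic band geometry, baseline and noise — not that it is
robust to every artefact of real acquisitions.

## Preprocessing

The chain is baseline correction → normalization → (mean centring for the
multivariate stage only). Order is enforced through a recorded
preprocessing state: the scorer refuses mean-centred data (centring
destroys the positivity of band areas), and PCA/clustering refuse data
missing the required steps.

* **Baseline**: asymmetric least squares (Whittaker smoother with
  asymmetric weights), λ = 1e5, p = 0.001, 10 reweighting iterations. The
  emulated study names only proprietary software; AsLS is the standard
  open equivalent, and both parameters are exposed. The pentadiagonal
  normal equations are solved by a banded LDLᵀ factorization in compiled
  code; a sparse-matrix reference implementation is kept and cross-checked
  in the tests. Non-convergence within the iteration cap returns the last
  iterate with a warning.
* **Normalization**: unit-L2 per spectrum (total-area mode available).
  The unsaturation ratio is invariant to this choice; it only shapes the
  clustering/PCA geometry, where unit vectors are conventional.
  Normalization is per spectrum, not per image.
* **Mean centring** retains the mean spectrum for back-projection and is
  idempotent.

## Band integration and scoring

Band areas are trapezoidal integrals over fixed windows after subtracting
the local linear chord joining the window endpoints. The windows — C=C
1630–1690 cm⁻¹, CH₂ 1400–1480 cm⁻¹ — cover ±2 FWHM of typical lipid bands
without touching the 1267/1296 cm⁻¹ markers, and are configurable; the
1654 vs 1655 cm⁻¹ centre distinction is immaterial at 4 cm⁻¹ resolution.
The chord (applied even after global AsLS) makes the ratio robust to
residual curvature. A negative C=C area (noise-only window) is clamped to
zero in the ratio but kept raw in the band-area record. Spectra whose CH₂
area falls below a floor of 5% of the dataset-median CH₂ area are declared
non-lipid, excluded from droplet statistics and counted; in images the
floor is 25% of the image-maximum CH₂ area instead, because image
backgrounds dominate the median and the 5%-of-max line sits within one
standard deviation of the background integration noise.

Droplet scores are ratios of the *mean spectrum* of the droplet's member
spectra; adipocyte scores are ratios of the mean over all the adipocyte's
lipid spectra. The mean of droplet scores is reported as a secondary
per-adipocyte statistic and never silently substituted — the two differ
because the ratio is a nonlinear function of the spectrum.

## Chemometrics

Clustering is agglomerative with Ward's criterion on Euclidean distances
(required by Ward's variance interpretation), applied to the preprocessed
spectra directly — clustering and PCA are parallel analyses, not a
pipeline — with a fixed cut at k = 3. The three classes are named by
ranking cluster means of the unsaturation ratio (saturated_rich < mixture
< unsaturated_rich), which makes naming deterministic and order-invariant.
When the between-class gaps in mean ratio fall below δ = 0.02 the result
carries a low-separation flag: three classes are still returned, but the
generative three-class structure is absent. Droplets are classified by
majority vote of member-spectrum labels, ties resolving to mixture.

PCA is a thin SVD of the mean-centred matrix; explained fractions are
non-increasing shares of total variance. The PC1 sign is fixed by the
marker bands: flipped if needed so the mean loading over saturated band
windows is positive; a component with negligible weight over both band
groups is flagged uninterpretable. Population PCA runs on
averaged-per-adipocyte spectra; image PCA runs per image, on the
lipid-masked pixels only, so that masked pixels represent the absence of
the component and score exactly zero.

## Statistics

Condition contrasts use the Mann–Whitney test — exact enumeration when the
combined n is at most 12 with no ties (tractability cutoff), otherwise the
normal approximation with tie and continuity correction — and
Kruskal–Wallis (tie-corrected H, chi-square on k−1 df) across the three
lipid classes. Droplet-level and adipocyte-level scores are never mixed in
one test. The 10 µm diameter-threshold contrast tabulates condition ×
stratum group sizes and mean ± sd ratios and Bonferroni-adjusts the
pairwise Mann–Whitney p-values (`p_adj = min(1, m·p)`, m logged).
Diameter–ratio association is ordinary least squares with
R² = 1 − SSres/SStot, defined as 0 with a flag when either variable has
zero variance. The ΔΔCt helper uses the arithmetic mean of
housekeeping-gene Cts (log2 of their geometric-mean expression) as
reference.

## Numerical choices and degenerate inputs

* Wavenumber-to-grid lookups tolerate |Δ| ≤ 2 cm⁻¹ (half the grid step).
* Band windows partially sampled by the grid integrate over the covered
  grid points; windows outside the grid are rejected.
* Zero-adipocyte configurations return an empty dataset with a warning,
  not an error; singleton datasets are rejected for centring/PCA;
  all-identical groups give p = 1.
* Every generator call is a pure function of (configuration, seed); the
  caller's RNG state is restored afterwards.
* k = 1 clustering returns the degenerate single class "mixture".

## Problem sizes in the test suite

The suite exercises the pipeline at sizes chosen to make the
distributional checks sharp while keeping a full run in minutes: the
cluster-recovery check uses 30 spectra × 20 seeds; the condition-recovery
check uses the full adipocyte counts (120 vs 138) with one droplet per
adipocyte over 100 seeded replicates — the contrast is tested on
adipocyte-level scores, where more droplets per adipocyte would only
tighten the averaging; the null calibration of the Mann–Whitney wrapper
uses 1000 replicates of 50 vs 50 generator-scored spectra; the diameter
sampler is checked at 10⁵ draws.

## Known limitations

* The emulated study's headline numbers on its own cultures (droplet-level
  ratios 0.17 vs 0.14, PC1 at 78.20%, the specific p-values) depend on the
  deposited raw spectra and are not reproduced here; the package
  reproduces the printed fatty-acid table arithmetic exactly and the
  Raman pipeline's behaviour property-wise on synthetic data.
* Whether the original ratio was computed on raw or preprocessed
  intensities is unstated; this implementation scores after baseline
  correction, the defensible choice, which is a known deviation risk when
  comparing against deposited data.
* Point-mode droplet spectra and imaging-mode pixels are kept flagged
  separately (`acquisition_mode`); whether the original droplet statistics
  pooled both is unstated, so population statistics here use point mode
  only.
* No peak deconvolution: overlapping bands are handled by window choice,
  not fitting. No mixed-effects modelling of droplets nested in
  adipocytes.
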