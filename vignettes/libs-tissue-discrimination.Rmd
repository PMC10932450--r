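---
title: "Discriminating tissues in bone-infiltrating head and neck cancer from LIBS spectra: models and methods"
author: "libstissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating tissues from LIBS spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Laser-induced breakdown spectroscopy (LIBS) reads out the elemental
composition of a micro-volume of tissue from the optical emission of a
laser-generated plasma; one laser shot yields one spectrum. In mandibular
cross-sections infiltrated by head and neck cancer, four histologically
validated tissue classes matter for laser-surgical feedback control:
**fibrosis** (reactive stroma outside tumor boundaries), the **inferior
alveolar nerve** (running through a Ca-rich bony canal), **tumor stroma**
(supportive tissue within tumor boundaries), and **cell-rich tumor**
(predominantly neoplastic cells). The discriminating signal lives in summed
peak areas of emission bins associated with Ca (11 bins between 547.89 and
650.8 nm, the CaO/CaOH band region), K (765.86 and 770.76 nm), and Na
(589.14 and 819.42 nm; not useful for discrimination, carried along for
completeness).

This package implements the full chain — spectrum I/O, preprocessing,
electrolyte features, nonparametric group statistics, pairwise ROC with
Youden cutoffs, four-class metric scales, and reference-anchored PCA —
together with a synthetic spectrum generator calibrated to the published
per-class summaries, so every stage is testable end to end without the
original patient spectra (which are not publicly available).

## Measurement model

Per spectrum, `preprocess_all()` applies three steps:

1. **Spectrometer-baseline subtraction** (`subtract_baseline()`): one
   constant per spectrum, estimated as the 5th percentile of the intensities
   at all grid samples outside every catalog window and outside the
   reference-peak window; negatives after subtraction are clipped to 0. A
   low percentile (rather than the mean or median) is robust to line tails
   leaking out of the windows; the estimator is isolated behind one function
   so a different baseline model can be swapped in.
2. **Base-peak normalization** (`normalize_base_peak()`): division by the
   maximum intensity, so the tallest feature equals exactly 1. This removes
   the per-shot gain — plasma coupling varies strongly from shot to shot.
3. **Peak-area integration** (`integrate_bins()`): the area of a bin is the
   plain sum of normalized intensities at grid samples inside the bin's
   closed window (a discrete sample-sum, no wavelength-step factor). With
   the base peak at 1 and on the order of a hundred samples per 2 nm window,
   these dimensionless areas reach the tens-of-AU magnitudes of the
   published per-class summaries — a step-weighted integral could not, which
   is why the sample-sum convention is used. A sample-sum equals the
   trapezoidal integral divided by the step, up to the half-weight of the
   two boundary samples (tested).

`electrolyte_sums()` then collapses the per-bin areas to the three element
sums `ca_sum`, `k_sum`, `na_sum` — the scalar biomarkers behind every
downstream statistic. Element membership is carried by the catalog's tags,
never by hard-coded wavelengths.

## The synthetic cohort

`default_model()` calibrates, per class, log-normal distributions of the
summed Ca and K areas from the published median/IQR pairs via
`calibrate_lognormal()`:

$$\mu = \ln m, \qquad
  \sigma = \frac{\operatorname{asinh}\!\big(\mathrm{IQR}/(2m)\big)}{z_{0.75}},$$

which follows from $Q_{75}-Q_{25} = 2 e^{\mu} \sinh(z_{0.75}\sigma)$ for a
log-normal. The log-normal family is a deliberate choice: positive support
and right skew consistent with the large published IQRs (for cell-rich
tumor Ca the IQR is more than three times the median), and the
(median, IQR) pair identifies it in closed form.

`sample_spectrum()` renders a shot by drawing target sums (Ca, K, Na) from
the class distributions, splitting each across the element's bins (uniform
weights by default; only the sums carry calibrated information), placing a
Gaussian line of the required discrete-sum area at each bin center, and
adding a unit reference peak at 800 nm, a constant baseline (0.02), additive
Gaussian noise, and a random positive log-normal gain. Because each line's
amplitude is `area / S_b`, with `S_b` the in-window discrete sum of the unit
line profile on the actual grid, the generator is an exact inverse of the
measurement: with noise off, the preprocessing chain returns the drawn sums
to near machine precision for any gain (tested at 1e-6 relative).

Key generator defaults, and why:

* **Grid 500–850 nm at 0.02 nm** (17 501 samples). The step couples to the
  sample-sum convention: a line of area $A$ has peak amplitude
  $\approx A\,\mathrm{step} / (1.0645\,\mathrm{FWHM})$. The tumor-stroma Ca
  calibration reaches ≈ 334 AU at its upper truncation cap, i.e. ≈ 30 AU per
  bin; at 0.02 nm the worst-case amplitude is 0.58 of the reference peak,
  keeping base-peak normalization anchored to the reference line for every
  admissible draw. On a 0.1 nm grid the same draw would tower 2.9× over the
  reference peak and the measurement contract would break.
* **Line FWHM 1.0 nm**, windows ±1.0 nm: disjoint for all 15 bins (closest
  centers 4.90 nm apart) with negligible cross-talk between lines.
* **Noise sd 2e-5** (pre-gain, reference peak = 1). The percentile baseline
  estimator is biased low by ≈ 1.645·sd under Gaussian noise, and that bias
  accumulates over all in-window samples of the 11 Ca bins (≈ 1800·sd on
  `ca_sum`). The default keeps that systematic error at ≈ 0.04 AU — under
  2% of even the smallest class median — so the recovery contract is
  dominated by sampling variability, not by estimator bias. Real single-shot
  spectra are substantially noisier; see the limitations below.
* **Truncation mass 0.995, symmetric.** Draws use the inverse CDF over
  $[(1-q)/2,\,(1+q)/2]$, removing equal probability from both tails. This
  caps line amplitudes (so the reference peak stays the base peak) without
  shifting the median at all; one-sided upper truncation would bias the
  median of a wide log-normal visibly (−0.6% at σ ≈ 0.94).
* **Stratified (quantile-balanced) sampling within a class.** Target sums
  are drawn one per equal-probability stratum, in random order with a random
  position within each stratum. A cohort of a few hundred iid draws from a
  wide log-normal misses its own median by several percent (relative SE
  ≈ 1.25 σ/√n ≈ 4% for the stroma-Ca calibration at n = 821); the stratified
  cohort matches the calibrated quantiles to O(1/n). Since the generator's
  purpose is to *carry* the published per-class distributions at the study's
  class sizes, cohort-level fidelity was chosen over shot-level independence
  (shots remain independent across classes, and in their noise and gain).
* **Na and reference classes are qualitative stand-ins** (no published
  values): Na medians 6.0 / 1.5 / 2.0 / 6.0 AU for fibrosis / nerve /
  stroma / cell-rich (IQR = 0.3 median), encoding only "high Na in fibrosis
  and cell-rich tumor"; the PCA reference classes are healthy bone (Ca 80,
  K 1) and bone-infiltrating tumor (Ca 2, K 7). These are synthetic values
  and are never used as discrimination targets.

What the generator does **not** emulate: plasma physics (no Saha/Boltzmann
equilibria, self-absorption, or molecular band structure — each bin is a
single Gaussian), any correlation between Ca, K and Na within a shot (drawn
independently; no joint information was available), realistic per-bin
intensity ratios within an element (uniform split), instrument artifacts
(detector nonlinearity, wavelength drift), or realistic noise levels.
Consequently, passing tests show that the *statistical pipeline* behaves
correctly under the published class separations — not that it would achieve
the same accuracy on raw clinical spectra.

## Group statistics

`summarize_groups()` reports per-class median and IQR with the
linear-interpolation quantile rule (R type 7), pinned because IQRs depend on
it. `kruskal_wallis()` is the mid-rank, tie-corrected H statistic against
the chi-square upper tail with k−1 df (group sizes here are in the
hundreds, so the large-sample approximation is appropriate; it is checked
against a permutation oracle in the tests). `dunn_posthoc()` computes the
standard mean-rank z-tests on the pooled mid-ranks with tie correction and
Bonferroni adjustment over the six pairs — Bonferroni being the
conventional, conservative companion of Dunn's test; the adjustment is one
line and swappable.

## ROC, Youden cutoffs, and the metric scales

`auc_mann_whitney()` computes the empirical AUC from pooled mid-ranks
(identical to pair counting with ties at half weight, which is the test
oracle) and orients each comparison so AUC ≥ 0.5, reporting the direction.
The 95% CI is DeLong's structural-components interval via pROC; the p-value
tests AUC = 0.5 with the Mann–Whitney null variance. `youden_cutoff()` scans
thresholds at midpoints between adjacent distinct pooled values — a
reproducible, direction-symmetric convention — and maximizes
J = sensitivity + specificity − 1, breaking ties toward higher sensitivity,
then the lower cutoff.

`build_metric_scale()` turns the pairwise machinery into a four-class
decision rule per element: order the classes by median, compute the Youden
cutoff between each *median-adjacent* pair only, and require the three
cutoffs to ascend — the only construction under which they partition the
nonnegative axis into four ordered intervals. Boundaries belong to the upper
interval ("≥ lower bound, < upper bound"). `classify()` is then a pure
interval lookup; when Ca and K scales disagree for a shot, both calls are
reported and no fusion rule is imposed (none is defined by the study
design). Cutoff *positions* are tail-shape sensitive and are not treated as
reproduction targets; the class *orders* and cutoff monotonicity are.

## PCA with reference fixation

`fit_pca()` runs mean-centered, unscaled (covariance) PCA on the 13 Ca + K
bin areas. Covariance rather than correlation PCA is deliberate: unit
scaling all bins would preclude any element from dominating the loadings,
which is exactly the structure of interest (the K doublet dominates the
second component on calibrated data, mirroring the separation the per-bin
variances imply); `scale. = TRUE` switches to correlation PCA. "Fixation" by
reference spectra is implemented as inclusion: generated healthy-bone and
tumor reference shots enter the fitting set and anchor the axes so repeated
fits are comparably oriented. Loadings follow a deterministic sign
convention (the largest-magnitude loading of each component is positive),
and a rank < 2 input is an error — a one-dimensional cloud has no 2-D view.

## Numerical conventions and degenerate inputs

* Grids must be strictly increasing and uniform within 1e-9 relative step
  tolerance; spectra files are comma-delimited long format (UTF-8, `.`
  decimal), written deterministically (4 decimals for wavelengths, 6
  significant digits for intensities), so double writes are byte-identical.
* Catalog coverage requires ≥ 5 samples per window; coverage is monotone
  under grid extension.
* All-zero spectra have no base peak: `normalize_base_peak()` errors, and
  `preprocess_all()` skips such shots with a message (erroring only if all
  shots fail).
* All-tied group input gives H = 0, p = 1; identical constant samples admit
  no threshold and `youden_cutoff()` errors.
* A degenerate DeLong variance (perfect separation) collapses the CI to a
  flagged point interval.
* Per-class RNG substreams are derived from the seed and the class name, so
  changing one class's count never perturbs another class's draws.

## Problem sizes

The analysis drivers and the end-to-end checks run the generator at the
study class sizes (254 / 516 / 821 / 1458 spectra on the 17 501-sample
grid, about half a minute in total); unit and property tests use a small
four-bin catalog on a coarser 200 nm grid, a few hundred shots at most, and
simulation-based calibration checks (DeLong coverage, null rejection rate)
use 1000–2000 replicates of modest size. These sizes were chosen to make
the statistical assertions stable at the tolerances tested.

## Known limitations

* The baseline model is a single constant per spectrum; real spectrometer
  baselines have structure. The published processing method is proprietary,
  so the simplest model consistent with the synthetic world was chosen and
  isolated behind one interface.
* Which spectral feature served as the base peak in the original instrument
  is unknowable from the published material; the synthetic world's unit
  reference peak at 800 nm is a documented convention, not a claim about
  the instrument.
* The published 71-bin grid is not recoverable (only the 15 discriminative
  bin centers are printed); the catalog is configurable so additional bins
  can be added, and "representative spectrum" selection
  (`select_representative()`: nearest to the class median profile in bin
  space, ties broken lexically) is one reproducible reading of an ambiguous
  procedure.
* AUC reproduction under the log-normal calibration matches the published
  values to within ≈ 0.01; exact agreement is not expected, since the true
  per-class distributions are summarized only by (median, IQR).
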