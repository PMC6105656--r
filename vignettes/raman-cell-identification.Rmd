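---
title: "Identifying live lung cells from Raman micro-spectra: models and methods"
author: "RamanCellID"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying live lung cells from Raman micro-spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RamanCellID)
```

## The problem

Confocal Raman micro-spectroscopy reads out the vibrational fingerprint of
a living cell — its lipid, protein, nucleic-acid and carbohydrate content —
without labels. Given repeated 10-point line scans over tens of cells from
several human lung cell cultures (immortalized cancer and fibroblast lines
plus primary bronchial epithelial cultures), the analytical task is to
decide whether the spectra carry enough information to assign each cell to
its culture of origin, and to quantify that with per-class sensitivity,
specificity and ROC characteristics.

`RamanCellID` implements the complete analysis chain for this task:
spectral conditioning, photodamage monitoring, hyperspectral segmentation,
PCA, and PLS-DA classification with VIP-based band interpretation — plus a
synthetic spectrum generator that plants known class structure so every
stage can be validated against ground truth. No measured spectra ship
with the package, so the generator is its reference data source: the
defaults encode the reference study design (5 classes x 30 cells x 10
points, 785 nm fingerprint window), and all quantitative claims in the
test suite are claims about recovery of *planted* structure.

## Data model

A `SpectralDataset` extends `SummarizedExperiment`: the single assay
`intensity` holds wavenumbers (rows, strictly increasing, cm^-1) by
spectra (columns); `colData` records cell line, cell id, line-scan point
index, repeat scan index, excitation wavelength, exposure and
accumulations. A `HyperspectralMap` extends it with a pixel grid shape and
spatial step. Files are plain comma-separated text (axis row + one row per
spectrum, `#` comments, sidecar metadata CSV), written with 15 significant
digits so round trips are lossless.

Non-uniform axes are accepted by the containers, but grid-sensitive
operations (Savitzky-Golay filters, derivatives) require a near-uniform
grid and refuse otherwise; silent interpolation between mismatched axes is
deliberately not offered, because an interpolation policy is an analysis
choice that should be explicit.

## The synthetic forward model

Each class template is a set of Lorentzian bands (default FWHM 12 cm^-1;
Gaussian available per band) on the 19 fingerprint centres used for
discrimination of lung cells — lipids (718, 1264, 1301, 1440, 1658),
proteins (641, 1003, 1166, 1239, 1580, 1658, 1674), nucleic acids (784,
828, 1316, 1458) and carbohydrates (881, 944, 1043, 1085 cm^-1) — plus an
order-5 polynomial fluorescence baseline and optional broad quartz hump.
All five templates share the same centres; classes differ **only** in band
amplitudes: the cancer-like template has elevated lipid bands, the
fibroblast-like template an elevated 784 cm^-1 DNA band, and the three
epithelial templates differ pairwise by smaller protein/carbohydrate
offsets. Above 2700 cm^-1 (488 nm simulations only) templates add CH
stretches at 2854/2930 and the O-H water stretches near 3250/3430 cm^-1.

Variability is multiplicative lognormal on band amplitudes: one draw per
cell (between-cell, CV 0.06) and one per spectrum per band (within-cell,
CV 0.08). Noise is shot-like Gaussian, sd = 0.5 * sqrt(signal + 50)
counts, and cosmic rays arrive as Poisson(0.2)-per-spectrum positive
excursions of 1-3 grid points at 10-40x the local noise sd. The defaults
were calibrated once so that the full pipeline on the default design lands
in the performance range a well-run live-cell Raman identification study
reports (spectrum-level accuracy low 90s %, cell-level sensitivity and
specificity in the mid-90s %), and then frozen.

What the generator deliberately does **not** model: resonance effects at
488 nm, laser-induced photochemistry (trends are planted directly on
ratios, not derived from a damage mechanism), media/substrate band
structure beyond a smooth hump, instrument drift, and spatial correlation
of noise. Passing tests therefore demonstrate that the *analysis* recovers
planted structure under realistic noise — not that real cultures are this
separable.

## Preprocessing chain

* **Despiking** — modified z-score of the second difference, threshold 8;
  flagged runs of at most 3 points are replaced by linear interpolation of
  the flanking points (nearest neighbour at the ends). Wide excursions
  (real bands also have large curvature z-scores on smooth spectra) are
  deliberately left untouched by the run-length condition, and unflagged
  points are never altered.
* **Baseline** — iterative clipped polynomial (ModPoly-style): fit an
  order-5 polynomial, clip the working signal to min(signal, fit), refit,
  to convergence (tol 1e-6 of the signal range, max 100 passes). The
  corrected spectrum plus returned baseline reconstructs the input
  exactly. On band-dense Lorentzian spectra the slowly decaying tails form
  a pedestal that any polynomial baseline partially absorbs; peak heights
  are still recovered within a few percent on the fingerprint window.
* **Smoothing / derivatives** — Savitzky-Golay (default width 11, order 3
  for smoothing; a joint width-15 order-3 second-derivative step for
  classification). Derivatives are taken per cm^-1, so results are
  axis-scale invariant; edges use the edge-window polynomial fit rather
  than reflection padding, which would fabricate symmetric structure.
* **Normalisation** — area (trapezoid of |intensity| = 1) for PCA and
  qualitative comparisons; unit Euclidean norm for PLS-DA. Both are
  idempotent and scale-invariant.
* **Mean centring** — per wavenumber across a dataset; inside PLS-DA it is
  realised as the model's stored centring vectors so new spectra are
  centred by the calibration means, not their own.

The classification recipe is vector normalisation, then the joint
second-derivative smoothing step, then mean centring. The order ambiguity
between "2nd derivative" and "smoothing" is resolved by using one
Savitzky-Golay differentiation filter that smooths and differentiates
jointly; width and order are configurable.

## Photodamage monitoring

Peak intensity is the windowed maximum within +/-8 cm^-1 of the nominal
band centre — robust to a few cm^-1 of calibration drift, unlike a point
read-out; an integral would mix in neighbouring bands. Ratios such as
I(1003/1301) are tracked across repeat scans (the point spectra of each
scan are averaged first) and fitted by ordinary least squares against the
scan index; slope and intercept standard errors come from the residual
variance in closed form. A zero-variance series is flagged degenerate
rather than fitted, and R^2 is undefined there. The regressor defaults to
scan index because that is how repeat acquisitions are indexed; a
minutes-based axis can be passed explicitly and slopes then read per
minute.

## Hyperspectral segmentation

"Manhattan analysis" is interpreted as k-medians: L1 assignment with
coordinate-wise median updates (the L1-optimal centroid), L1
distance-weighted seeding, 10 seeded restarts, assignment ties broken
toward the lowest cluster index, and labels renumbered by descending size
so the background field is cluster 1. The objective is verified
non-increasing at every iteration.

The default pre-mode is a Savitzky-Golay **first derivative only**
(width 21, order 3). An earlier design also vector-normalised the
derivative spectra, but that maps structureless background pixels onto
random unit noise vectors: the background field then splits into
arbitrary noise clusters while nucleus and cytoplasm merge. The
derivative alone cancels smooth baselines while leaving absolute band
structure to dominate the L1 metric. The window is wider than the
spectral smoothing default because per-pixel dwell times make map noise
the dominant L1 mass: with narrow windows the distance-weighted seeding
concentrates in the noisy background cloud and the optimizer can settle
in partitions that split the background while merging nucleus and
cytoplasm; at width 21 planted four-region maps are recovered
essentially perfectly across noise realisations. Vector normalisation
and other widths remain available via an explicit `premode` recipe.

Cluster spectra are mean **raw** spectra, so subtracting the background
cluster removes substrate/baseline contributions exactly and recovers the
cell's band spectrum.

Line-vs-area equivalence: both averages are area-normalised before
differencing. With planted subcellular regions, the residual difference is
dominated by region-composition bias (a midline structurally overweights
the nucleus and any droplet it crosses), which does not shrink with the
number of line points; the classic observation that ~10 points suffice
reflects averaging of within-cell heterogeneity. The package's sweep test
therefore demonstrates the monotone-improvement property on a
uniform-composition cell with per-pixel amplitude heterogeneity.

## Chemometrics

**PCA** uses `stats::prcomp` on the preprocessed, column-centred data with
a deterministic sign convention (largest-|loading| element positive).
Explained-variance fractions are relative to total variance, hence
non-increasing and summing to at most 1.

**PLS-DA** is SIMPLS PLS2, authored in full: classes become indicator
columns, successive latent variables maximise residual X'Y covariance with
deflation through an orthonormalised loading basis, and scores are
normalised so the Y sum of squares captured by component *a* is
`||q_a||^2`. At full rank the predictions provably coincide with the
least-squares fit, which the tests assert against a normal-equations
oracle. Requesting more components than `min(n-1, p)` is an error; when
the covariance is numerically exhausted earlier, the remaining components
stay zero, giving a deterministic degenerate model whose argmax ties
resolve to the first class in sorted order.

**Validation** follows the reference protocol: every fourth spectrum (by
acquisition order) forms the validation set; venetian-blinds
cross-validation assigns row *i* of the calibration set to fold
`(i-1) mod 10 + 1` — no randomness, so error curves are bit-reproducible.
The "classification error average" is the mean over classes of
(false-negative rate + false-positive rate)/2; the number of latent
variables is the smallest whose calibration **and** CV error averages are
at or below the 5% target, falling back to the CV minimiser with a flag.
Splitting is at the spectrum level, matching the protocol's description;
note this lets points of one cell appear on both sides of a split, so
spectrum-level figures are technical-replicate performance, while
cell-level figures (predicting each cell's averaged line-scan spectrum)
are the biologically honest summary.

**Reporting** follows the field's standard table layout: per class, sensitivity and
specificity of the validation assignments (one-vs-rest), AUC of the
continuous one-vs-rest scores via the Mann-Whitney tie-aware rank formula,
and RMSEC/RMSECV/RMSEP as root-mean-square differences between indicator
and predicted score over the calibration, pooled-CV and validation
predictions. **VIP** scores use the standard weight formula with
`mean(VIP^2) = 1` as an enforced identity; wavenumbers with VIP > 1 are
reported as the discriminatory regions.

## Numerical and design choices

* Axis grid: 1 cm^-1 by default (instrument pixel pitch is not part of
  the model); 600-1800 cm^-1 for 785 nm, extendable past 2700 for 488 nm
  simulations.
* Cropping happens before normalisation in the pipeline, so normalisation
  constants refer to the analysed window.
* Lognormal multipliers have mean exactly 1 (meanlog = -sigma^2/2), so
  planted amplitudes are unbiased.
* Planted ratio trends are solved by a short secant iteration on the
  numerator band scale so the *windowed-max* ratio, not an idealised
  amplitude ratio, follows the planted line exactly.
* Confidence intervals for trend slopes use the exact t quantile at
  n-2 degrees of freedom: with 8-scan series a z-based 1.96·SE interval
  under-covers by construction (90.2% at 6 df), a t interval restores
  nominal 95% coverage.
* All randomness flows from a single config seed; the pipeline fans it
  out to fixed per-stage streams, so full runs are byte-identical.
* Problem sizes in the test suite are scaled to what the properties need:
  the full default design (1500 spectra) where the claim is about that
  design, and 300-500-point axes with a handful of cells where the claim
  is algebraic.

## Known limitations

* ModPoly baselines on dense Lorentzian spectra absorb part of the
  inter-band tail pedestal; alternatives (ALS, airPLS, rolling ball) are
  out of scope by design.
* The despiking statistic can flag genuinely narrow (< 4-point) real
  features on noise-free spectra; at realistic noise this does not occur,
  and the run-length guard protects bands.
* Class assignment is argmax of indicator scores; probabilistic/Bayes
  thresholds of commercial toolboxes are not reproduced.
* Venetian blinds are not cell-grouped by default (matching the
  protocol); `averageByCell` plus the cell-level report is the leakage-
  aware view.
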