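---
title: "PET asphericity and gene-signature risk stratification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PET asphericity and gene-signature risk stratification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aspstrat)
```

## What the package computes

`aspstrat` implements a combined imaging–transcriptomic prognostication
workflow for non-small cell lung cancer (NSCLC) cohorts:

1. **Delineation** of the metabolically active primary tumor in an FDG-PET
   volume by iterative adaptive thresholding with local-background
   correction.
2. **Quantitative PET parameters** of the delineated lesion: metabolic
   tumor volume (MTV, mL), SUVmax, SUVmean, total lesion glycolysis
   (TLG = MTV × SUVmean) and **asphericity** (ASP),

   $$\mathrm{ASP} = 100\left(\frac{S}{(36\pi)^{1/3}V^{2/3}} - 1\right)\,\%,$$

   the percentage excess of the tumor surface area $S$ over the surface of
   a sphere with the tumor's volume $V$. ASP is 0 for a perfect sphere and
   grows with spatial irregularity of the uptake region.
3. **Expression scoring**: gene-count filtering (total count > 1),
   median-of-ratios normalization, mean-z signature scores, and the
   29-gene extracellular-matrix-related EPPI linear risk score
   $\mathrm{EPPI}_j = \beta_0 + \sum_g \beta_g \, t(x_{gj})$ with an
   externally supplied coefficient file.
4. **Survival analysis**: endpoint derivation (PFS, OS, LRC, FFDM),
   Kaplan–Meier curves, univariate/multivariate Cox models, the
   IQR-restricted minimum-p optimal-cutpoint search, fixed-cutoff
   validation (ASP at 19.5%), and nested ASP × EPPI risk strata.
5. A **synthetic-data module** that generates PET phantoms with known
   geometry and cohorts with known hazard structure, so that every stage
   is testable end to end with exact or statistical oracles.

## Delineation model

The delineation scheme is an iterative background-corrected relative
threshold. Starting from the connected component above
`init_fraction * SUV(seed)` that contains the seed voxel, each iteration

1. estimates the local background $B$ as the mean SUV in a shell of
   voxels whose Euclidean distance (physical mm, anisotropy honored) to
   the current region lies in `[shell_inner_mm, shell_outer_mm]`
   (defaults 2–4 mm);
2. sets the threshold $T = B + f\,(\mathrm{SUV}_{\max}^{\text{region}} - B)$,
   re-evaluating the region maximum inside the current region;
3. regrows the 6-connected component containing the seed above $T$,

until the relative volume change falls below `convergence` (default 1%)
or `max_iterations` (default 20) is reached. Background-corrected
thresholds near 40% of the lesion peak are the established family of PET
delineation methods for FDG lesions; the default `f = 0.41` is a
calibrated representative of that family, not a reproduction of any
proprietary implementation, and every constant is exposed in
`delineation_params()`. On a two-valued image the scheme is a fixed point
after one background estimate, which the test suite asserts exactly.
Distances to the region are voxel-center-to-center, the unambiguous
discrete reading of "distance to the region". If the region sequence
alternates between two states, the smaller region is returned and the
mask flagged, keeping the result deterministic and conservative.
Externally supplied masks (`apply_override()`) replace the automatic
result with provenance `"override"`, mirroring the manual-correction
step of clinical workflows without interactive editing.

## Surface estimation and the asphericity scale

ASP inherits its scale from the surface estimator, so the estimator is
the critical numerical choice:

* **Voxel-face counting** overestimates smooth surfaces by ≈ 50%
  (the staircase effect; the test suite pins the factor at 1.5 ± 0.05 for
  digitized spheres). It is retained only as a `voxel_faces` diagnostic.
* The **default mesh estimator** smooths the binary mask with a one-voxel
  Gaussian and triangulates the 0.5-level isosurface by marching
  tetrahedra (each grid cell split into 6 tetrahedra; watertight and
  consistent across cells; physical coordinates, no resampling of
  anisotropic grids). Smoothing removes the staircase bias but pulls the
  half-level surface inward by approximately $\sigma^2 H$ ($H$ the local
  mean curvature), which would bias ASP of a 10-voxel-radius sphere by
  about −2 percentage points. The estimator therefore measures the
  surface-averaged curvature from the slope of triangulated area across
  nearby iso-levels (0.35/0.65) and inflates the level-0.5 area by
  $2(\sigma \bar H)^2$.

With this correction the digitized-sphere ASP error is +0.6 pp at
r = 10 voxels and +0.5 pp at r = 20 (measured by the test suite; the
residual is the metrication bias of tetrahedral triangulation), inside
the documented bands |ASP| ≤ 5 pp at r = 10 and ≤ 2 pp at r = 20, and
never below the isoperimetric floor of −0.5 pp (`eps_mesh`). The ASP
denominator uses the voxel-count volume — the same convention as MTV —
so the two reported quantities are mutually consistent; the difference
to the mesh-enclosed volume is covered by the convergence tolerance.
ASP is exactly invariant under isotropic spacing changes (asserted to
1e-9 relative).

## Cutpoint search and its known pathology

For marker dichotomization the package scans every unique observed value
inside the marker's interquartile range (median-unbiased type-8
quantiles, bounds inclusive — a convention fixed here for
reproducibility) and picks the cutoff minimizing the Wald p of the
binarized Cox coefficient, ties resolved toward the smaller cutoff;
the full candidate trace is kept for audit. Monotone-likelihood
candidates (separation) are excluded rather than reported as huge finite
hazard ratios.

Minimum-p scanning is anti-conservative by construction: the best of many
correlated tests is reported as if prespecified. The test suite measures
a null rejection rate of roughly 20–30% at n = 40 against the nominal 5%.
The package therefore ships `adjust = "permutation"`, which re-runs the
scan under random permutations of the marker and reports the Monte-Carlo
p of the observed minimum; the suite verifies this restores ≈ 5%. No
correction is applied inside the default scan, matching common practice
in the clinical literature; the calibrated option and the audit trace are
provided because of the inflation.

"Highest significance" is interpreted as the smallest Wald p (the
quantity reported in clinical HR tables); a log-rank-based selection
would be an easy variant but is not the default.

## Endpoint conventions

PFS counts any recurrence (loco-regional or distant) or death as an
event; OS counts death. For the cause-specific endpoints LRC and FFDM,
death without the corresponding recurrence censors at the death date —
the cause-specific convention, chosen because published endpoint
wordings typically pin down only PFS precisely. Patients without any
event are censored at last follow-up; non-positive follow-up records are
dropped with their ids logged.

## Synthetic study conditions

The simulator is the package's ground truth and its defaults are fixed
study conditions, not tuning knobs:

* ASP ~ Gamma(mean 20, sd 12) percent — a right-skewed distribution on
  the scale over which published ASP cutoffs (e.g. 19.5%) operate.
* EPPI ~ Normal(0, 1) on a unit latent scale, with a weak negative
  correlation to ASP (ρ = −0.3 by default), the qualitative feature the
  correlation screen is designed to detect.
* Planted hazards: HR 1.02 per ASP percentage point (the scale reported
  for metric ASP effects in NSCLC cohorts), HR 2 per EPPI unit, HR 1.5
  for stage III; exponential event times with baseline hazard
  0.01/month split 0.3/0.4/0.3 across loco-regional, distant and death
  processes; administrative censoring at 60 months competing with
  uniform dropout on (0, 240) months. Cox regression is
  baseline-agnostic, so the constant baseline does not limit what the
  recovery tests demonstrate.
* Expression: negative-binomial counts (dispersion 0.2), log-normal
  library sizes, and signature-gene log2 means shifted by
  0.4 × EPPI, signed like the model coefficients, which makes the
  linear score recoverable from counts alone.
* Phantoms: plateau uptake inside an analytic shape (sphere, ellipsoid,
  cuboid, or spherical-harmonic-perturbed sphere), Gaussian PSF blur,
  then additive Gaussian noise. Poisson-like count noise, scatter,
  attenuation and motion are deliberately not modeled; the additive
  model is sufficient for threshold-based delineation testing. The
  ground-truth mask uses the voxel-center-inside rule, matching the
  voxel-count volume convention.

What passing tests therefore show: the algorithms recover known geometry
and known effect sizes under idealized noise. What they do not show:
performance on real scanner data (reconstruction artifacts, heterogeneous
uptake, respiratory motion) or agreement with any specific clinical
delineation software, whose exact algorithms are unpublished.

## Numerical choices

* Reference geometry: sphere and cuboid closed forms; ellipsoid surface
  by numerical integration of the exact parametric surface element;
  perturbed-sphere surface/volume by Gauss–Legendre × trapezoid tensor
  quadrature refined until successive grids agree to < 0.01%.
* Quartiles: type 8 (median-unbiased); binarization is strict
  (`marker > cutoff` = high risk), so boundary values fall in the low
  group.
* Cox ties: Efron. Separation is flagged at |β| > 15 or on solver
  warnings instead of being reported as an estimate.
* Zero-variance genes get z-score 0 in signature scores, avoiding NaN
  contamination of signature means; the EPPI transform defaults to
  log2(x + 1) and is configurable, since published coefficient sets do
  not always document their expression scale.
* Missing data: complete-case per analysis; every reported row carries
  its n. Patients without expression keep their ASP group in combined
  strata (label "asp/NA") and are excluded only from EPPI splits.

## Problem sizes used by the test and acceptance runs

Digitized-sphere checks use radii of 10–20 voxels (grids up to 52³);
hazard-ratio recovery uses 20 replicates of n = 2000 patients; the
cutpoint calibration uses 100 null cohorts of n = 40 (99 permutations
for the adjusted variant); the correlation screen uses two cohorts of
n = 100 with 60 genes. These sizes give Monte-Carlo error comfortably
inside the asserted bands while keeping a full run in the order of a
minute per suite.

## Known limitations

* The delineation defaults are a calibrated stand-in for the class of
  background-corrected ~40% threshold methods, not a byte-level
  reproduction of any specific tool.
* The mesh estimator's residual +0.5 pp metrication bias is visible for
  near-spheres; shapes with edges and corners (cuboids) are rounded by
  the pre-smoothing and their ASP is underestimated at coarse grids,
  converging only under grid refinement.
* The shipped EPPI model is synthetic (see
  `synthetic_eppi_model()`); users must supply the published coefficient
  file to score real cohorts.
* Multi-lesion patients, competing-risks models and time-dependent
  covariates are out of scope.
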