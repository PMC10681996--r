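# aspstrat

Combined imaging–transcriptomic risk stratification for non-small cell
lung cancer (NSCLC) cohorts, built for imaging scientists and
biostatisticians who work with FDG-PET radiomics and RNA-seq prognostic
signatures.

The package covers the full analysis chain:

* **Tumor delineation** in 3-D PET volumes (SUV units, NIfTI I/O) by
  iterative adaptive thresholding with local-background correction:
  `T = B + f (SUVmax − B)` with the background `B` estimated in a shell
  around the evolving region, plus an override path for externally drawn
  masks.
* **Quantitative PET parameters**: metabolic tumor volume (MTV, mL),
  SUVmax, SUVmean, total lesion glycolysis (TLG = MTV × SUVmean) and
  **asphericity**

  ASP = 100 · ( S / ((36π)^(1/3) · V^(2/3)) − 1 ) %,

  the percentage excess of tumor surface area over a volume-matched
  sphere (0 for a sphere; 24.07% for a cube). Surfaces come from a
  curvature-corrected marching-tetrahedra mesh on the smoothed mask.
* **Expression scoring**: `> 1` total-count gene filtering,
  median-of-ratios normalization, mean-z signature scores, and the
  29-gene extracellular-matrix-related **EPPI** linear risk score from a
  user-supplied coefficient file (a clearly synthetic example model
  ships with the package).
* **Survival analysis**: endpoint derivation (PFS, OS, LRC, FFDM),
  Kaplan–Meier curves, univariate/multivariate Cox models (Efron ties,
  Wald summaries, separation flags), minimum-p **optimal cutpoints
  restricted to the marker's interquartile range** (with an audit trace
  and a permutation-calibrated p option), fixed-cutoff validation (ASP
  at 19.5%), and nested ASP × EPPI risk strata.
* **Synthetic data**: PET phantoms with analytically known geometry
  (spheres, ellipsoids, cuboids, spherical-harmonic-perturbed spheres)
  and cohorts simulated from a proportional-hazards model with known
  effect sizes plus negative-binomial expression counts coupled to the
  latent risk — so every stage is testable without external data.

## Worked example

Delineate a phantom lesion and extract its features:

```r
library(aspstrat)

ph <- make_phantom(
  shape_spec("perturbed_sphere", radius = 12, degree = 2,
             amplitudes = c(0, 1.5, 3, 0, 0)),
  grid_spec(c(44, 44, 44)),
  acquisition_spec(tumor_suv = 8, background_suv = 1.2, psf_fwhm_mm = 4,
                   noise_sd = 0.3, seed = 7))

mask <- delineate(ph$volume)
#> <tumor_mask> 44 x 44 x 44 voxels, 6778 foreground, provenance=automatic

compute_features(ph$volume, mask)
#>   mtv_ml suv_max suv_mean    tlg asp_percent surface_mm2
#> 1  6.778   9.165    7.068 47.907        1.93    1765.447
```

The lesion's 6.78 mL MTV is within 3% of the analytic shape volume, the
blurred SUVmax (9.17) stays below the 8 SUV plateau plus noise, and the
1.9% asphericity sits close to the 1.2% of the analytic surface — the
mildly perturbed sphere is, correctly, almost spherical.

Simulate a cohort with a planted HR of 1.02 per ASP percentage point,
score its expression, and fit the joint Cox model:

```r
sim <- simulate_cohort(cohort_config(n_patients = 400, rho_asp_eppi = 0,
                                     seed = 1,
                                     expression = list(n_genes = 60)))
norm <- normalize_counts(filter_genes(sim$counts))
sc <- eppi_score(norm, synthetic_eppi_model())
co <- dplyr::mutate(sim$cohort, eppi_fitted = sc$eppi)

fit <- cox_fit(dplyr::transmute(co, asp, eppi = eppi_fitted,
                                time = pfs_time, event = pfs_event),
               c("asp", "eppi"))
tidy(fit)
#>   term  estimate std_error    hr ci_low ci_high        p
#> 1 asp     0.0170   0.00554  1.02   1.01    1.03 2.22e- 3
#> 2 eppi    0.310    0.0305   1.36   1.28    1.45 3.07e-24
```

The metric ASP hazard ratio (1.02, 95% CI 1.01–1.03) recovers the
planted effect size; the EPPI score computed from the simulated counts
is strongly prognostic, as planted. Validating the fixed 19.5% ASP
cutoff on a larger simulated cohort:

```r
co2 <- simulate_cohort(cohort_config(n_patients = 2000, rho_asp_eppi = 0,
                                     seed = 2))$cohort
validate_fixed_cutoff(dplyr::transmute(co2, asp, time = pfs_time,
                                       event = pfs_event), "asp", 19.5)
#> <asp_fixed_cutoff> asp > 19.5: n(low)=1109 n(high)=891, log-rank p=8.11e-09
#>   term  estimate std_error    hr ci_low ci_high             p
#> 1 .high    0.345    0.0602  1.41   1.26    1.59 0.00000000959
```

Patients above the fixed cutoff have a 1.41-fold hazard — the
dichotomized counterpart of the planted metric effect.
`optimal_cutpoint()` performs the IQR-restricted minimum-p scan instead
(`autoplot()` shows the candidate trace), `combined_strata()` builds the
nested ASP × EPPI groups, and `run_pipeline()` drives the whole analysis
from one config and writes a CSV/JSON report bundle.

## Documentation

The methods vignette
(`vignettes/asphericity-stratification.Rmd`) documents the delineation
and surface-estimation models, the cutpoint search and its known
type-I inflation, endpoint conventions, the synthetic study conditions,
and the package's numerical choices and limitations.
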