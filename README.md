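# radphase

Reproducibility screening and batch harmonization of CT radiomic features
across contrast phases.

## What problem this solves

Handcrafted radiomic features (HRFs) computed from a segmented lesion on a
contrast-enhanced CT scan depend on *when* the scan was acquired relative
to contrast injection: the same lesion yields different feature values in
the arterial and the portal venous phase. Studies that want to pool scans
from both phases — or substitute one phase for a missing other — need to
know, feature by feature, whether values agree across phases, and whether
statistical harmonization can make them agree.

`radphase` is an R package for that analysis. It provides:

* a **167-feature extractor** in 11 families (first-order statistics,
  intensity histogram, local intensity peaks, shape, fractal, and the
  GLCM / GLRLM / GLSZM / GLDZM / NGTDM / NGLDM texture-matrix families),
  operating on NIfTI volumes + binary masks with fixed-bin-width
  discretization (default 25 HU), 3D merged-direction texture
  aggregation, all texture matrices verified against brute-force oracles;
* **Lin's concordance correlation coefficient** (CCC) screening across
  paired phases, with a CCC > 0.9 reproducibility cutoff, a
  near-zero-variance filter (modal value in ≥ 95% of observations) and a
  volume-correlation filter (|Pearson r| > 0.85);
* a from-scratch **empirical-Bayes ComBat** implementation of the
  location–scale batch model
  `Y_ij = α + βX_ij + γ_i + δ_i ε_ij`, harmonizing via
  `(Y − α̂ − β̂X − γ*_i)/δ*_i + α̂ + β̂X` with parametric EB shrinkage of
  the per-batch effects (phase as batch);
* a **synthetic paired-phase cohort generator** (61 patients / 104
  lesions by default, perturbed-superellipsoid lesions on 64³ grids,
  arterial hyperenhancement vs. venous washout, one shared mask per
  lesion) with ground-truth batch-effect injection for recovery tests;
* an **end-to-end pipeline** that classifies every feature as
  `always_reproducible`, `gained_by_combat`, `lost_by_combat`,
  `never_reproducible`, `shape_excluded_from_combat` or `nzv_removed`,
  with tidy tibble reports, `tidy()`/`glance()` methods and ggplot2
  figures.

## Worked example

```r
library(radphase)

cfg <- pipeline_config(
  cohort = cohort_config(n_patients = 8, n_lesions = 12, grid_size = 32,
                         lesion_radius_range = c(4, 10), seed = 7))
report <- run_pipeline(cfg)
#> [radphase] cohort: 8 patients, 12 lesions on a 32^3 grid
#> [radphase] extracted 167 features x 24 ROIs
#> [radphase] 29 features with CCC > 0.9 before harmonization
#> [radphase] 141 features enter ComBat (23 shape and 3 near-zero-variance features excluded)
#> [radphase] 17 features with CCC > 0.9 after harmonization

report
#> <repro_report> 167 features, 12 lesions x 2 phases
#>   always_reproducible          5
#>   gained_by_combat             12
#>   never_reproducible           124
#>   nzv_removed                  3
#>   shape_excluded_from_combat   23

summarize_delta(report)
#> # A tibble: 5 x 2
#>   band          n
#>   <chr>     <int>
#> 1 (-Inf,0)     18
#> 2 [0,0.1)      22
#> 3 [0.1,0.5)    82
#> 4 [0.5,0.6)     8
#> 5 [0.6,Inf)    11
```

Reading the output: on this small synthetic cohort, 29 of 167 features
(including the 22 geometric shape features, which are *exactly*
concordant because both phases share one mask) have CCC > 0.9 before
harmonization. ComBat with phase as batch makes 12 more features
concordant and costs none, but most texture features remain
non-reproducible — the phase effect on them is not a pure location–scale
shift. `summarize_delta()` bins the per-feature CCC change
(after − before) for the 141 harmonized features.

`write_report(report, "out/")` writes the per-feature CSV, a
human-readable summary and a CCC before/after scatter;
`autoplot(report)` returns the same figure as a ggplot object. Lower
level entry points (`extract_all()`, `screen_features()`,
`combat_fit_transform()`, `inject_batch_effects()`) expose each stage
separately, and `feature_dictionary()` documents all 167 features.

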