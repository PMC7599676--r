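# meningrisk

Risk stratification of atypical (WHO grade II) meningiomas from preoperative
MRI. Up to 60% of these tumors recur within five years of resection, yet no
established radiological criteria identify the high-risk cases. `meningrisk`
implements, as a tested and reusable R pipeline, the analysis chain that
associates imaging features of the segmented tumor with recurrence and
progression-free survival (PFS):

1. **Radiomic feature extraction** from a contrast-enhanced T1 volume and its
   binary tumor mask: isotropic resampling, fixed-bin-count gray-level
   discretization, and 13 features per filter channel — first-order
   statistics (mean, median, minimum, skewness), spherical disproportion
   *A*/(4π*R*²) with *R* = (3*V*/4π)^⅓, and texture features from the
   gray-level co-occurrence matrix (cluster prominence
   Σᵢⱼ (i + j − μᵢ − μⱼ)⁴ p(i,j), difference entropy, inverse difference
   normalized), run-length matrix (run-length non-uniformity, short-run
   low gray-level emphasis) and size-zone matrix (high-/low-intensity
   large-area and low-intensity small-area emphasis). Channels: original,
   Laplacian-of-Gaussian, and the eight subbands of a single-level 3D
   Coiflet-1 wavelet decomposition.
2. **Statistical screening**: univariate logistic regression (odds ratios
   with Wald 95% CIs) of 11 semantic imaging flags; ROC analysis
   (Mann–Whitney AUC) of continuous radiomic features with Youden-index
   dichotomization; a multivariate Cox proportional-hazards model (Efron
   ties) of the advanced features; univariate and multivariate Cox models
   of PFS; Kaplan–Meier curves with restricted mean survival times and the
   log-rank test.
3. **Synthetic data**: phantom tumor volumes (ellipsoid masks, correlated
   Gaussian texture fields, optional hypointense cystic core) and simulated
   cohorts under exponential proportional hazards, so every stage is
   testable end to end without patient data.

The package is aimed at imaging researchers who want either the feature
extractors, the screening procedure, or a fully simulated test bed for
pipelines of this design.

## Worked example

```r
library(meningrisk)

# a cystic phantom tumor and its radiomic profile
ph <- generate_phantom(phantom_spec(cystic = TRUE, seed = 7))
feats <- extract_features(ph$grid, ph$mask)
round(feats$wide[c("original__cluster_prominence",
                   "original__difference_entropy",
                   "original__spherical_disproportion")], 3)
#>      original__cluster_prominence      original__difference_entropy
#>                         31872.843                             2.716
#> original__spherical_disproportion
#>                             1.030

# a simulated 200-patient cohort at the design effect sizes
cohort <- simulate_cohort(cohort_sim_spec(n_patients = 200, seed = 1))
report <- run_screening_procedure(cohort)
report$univariate_semantic$cystic_component
#> cystic_component: OR 13.2 (95% CI 5.49-31.9), p = 8.68e-09, n = 200
report$multivariate_recurrence$cystic_component
#> cystic_component: HR 13.7 (95% CI 6.7-28.2), p = 8.59e-13, n = 200
round(report$km$rmst, 1)
#>     0     1
#> 151.9  54.2
```

The phantom's cluster prominence (≈31,900 at 32 gray levels) reflects its
bimodal intensity histogram — a hypointense cyst inside an enhancing tumor
produces co-occurrences far from the mean gray level. In the simulated
cohort the cystic component is picked up in univariate screening
(OR 13.2), advances to the multivariate Cox model (HR 13.7, CI excluding
1), and splits PFS sharply: restricted mean survival 54 vs 152 months
(log-rank p ≈ 4 × 10⁻²⁰). Absolute texture-feature values — and any
threshold derived from them — depend on the discretization; the pipeline
therefore always derives dichotomization cutoffs from the cohort at hand.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic data and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # phantoms + cohort tables
Rscript analysis/02_extract_features.R  # radiomic feature tables
Rscript analysis/03_screening.R         # screening reports (JSON + text)
Rscript analysis/04_calibration.R       # null calibration + HR recovery
```

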