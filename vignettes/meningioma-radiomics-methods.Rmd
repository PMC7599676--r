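---
title: "Radiomic and semantic risk stratification of atypical meningiomas: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic and semantic risk stratification of atypical meningiomas: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`meningrisk` implements a two-arm risk-stratification analysis for atypical
(WHO grade II) meningiomas: qualitative ("semantic") imaging flags read by a
human observer, and quantitative ("radiomic") features computed from the
segmented tumor volume, both screened for association with tumor recurrence
and progression-free survival (PFS). This vignette documents the model, its
assumptions, the tunable parameters, and the numerical and design choices
made where the problem left them open.

## The statistical model

Recurrence screening proceeds in stages:

1. Each of the 11 binary semantic flags (intra-tumoral heterogeneity,
   multifocality, midline shift, sinus invasion, necrosis/hemorrhage, mass
   effect, cystic component, bone invasion, hyperostosis, spiculation,
   edema) is tested by univariate logistic regression of the relapse flag;
   the odds ratio is `exp(beta)` with a Wald 95% CI. A flag advances at
   p < 0.05. For a binary predictor the MLE equals the 2×2 cross-product
   ratio, which the tests exploit as an oracle. Empty cells and complete
   separation are detected from the 2×2 table and reported as degenerate
   estimates (0 or Inf) with a flag, never as spuriously finite fits.
2. Each continuous radiomic feature is assessed by ROC analysis. The AUC is
   computed in the Mann–Whitney rank form with mid-rank tie correction; the
   accompanying p-value is the two-sided Wilcoxon rank-sum test. A feature
   is admitted at p ≤ 0.10 — deliberately lenient, admitting "predictive
   trends" into the joint model, where weak univariate signals can become
   informative after adjustment.
3. Admitted continuous features are dichotomized at the Youden-optimal
   threshold (maximizing J = sensitivity + specificity − 1 under the rule
   `feature > threshold`). Ties in J break toward the *lower* threshold so
   reports are deterministic. Thresholds are always derived from the cohort
   at hand: absolute texture-feature values are tied to the gray-level
   quantization and intensity scale, so a cutoff from one pipeline (or one
   scanner) is not transferable to another.
4. The advanced features enter a multivariate Cox proportional-hazards
   model of time to recurrence (Efron tie handling, Newton iterations via
   the `survival` package), reported as hazard ratios with Wald 95% CIs.
   The recurrence outcome is a time-to-event quantity, so a hazard-ratio
   model is the natural joint analysis even though the univariate screen is
   logistic; a multivariate logistic model is available as a configuration
   alternative (`screening_config(recurrence_model = "logistic")`).
5. PFS is analyzed by univariate Cox models for each clinical covariate
   (resection completeness, localization, sex, age > 65, postoperative
   radiation) and each advanced imaging feature; covariates significant at
   p < 0.05 plus resection completeness (always retained, as the
   clinically established risk factor) form the multivariate PFS model.
   Although univariate PFS associations are sometimes labeled odds ratios
   in clinical reports, a time-to-event outcome calls for hazard ratios;
   both univariate and multivariate PFS effects here are Cox HRs.
6. The leading semantic feature is summarized by Kaplan–Meier curves and
   the one-degree-of-freedom log-rank test. "Mean" PFS per group is
   reported as the restricted mean survival time — the area under the KM
   curve up to the largest observed follow-up — the convention of common
   clinical software when curves do not reach zero.

No multiple-testing adjustment is applied by default, mirroring standard
single-cohort screening practice at this scale; Benjamini–Hochberg
adjustment of the univariate p-values is available
(`screening_config(adjust_p = "BH")`).

## Radiomic features

All texture features are computed on the gray-level-discretized ROI.
Quantization uses a **fixed bin count** (`ng_levels`, default 32) over the
masked voxels only: `level(x) = min(Ng, floor((x − min)/(max − min) · Ng) + 1)`,
with a constant ROI mapping to level 1. Fixed-bin-count quantization makes
features unit-free and robust to intensity scaling, at the cost of tying
absolute feature magnitudes to `Ng` — the reason thresholds are recomputed
per dataset. Whether quantization should instead span the whole image, and
whether volumes should be resampled at all, are left configurable
(`target_spacing_mm`, masked-only quantization is the default).

* **GLCM** (co-occurrence): pairs at Chebyshev distance 1 over the 13
  unique 3D directions, both orderings (symmetric), pairs leaving the mask
  excluded, matrices *summed* over directions and normalized to total mass
  one. Summing (the "merged" strategy) reduces variance on small ROIs
  relative to per-direction feature averaging. The 26-offset set is closed
  under 90° axis-aligned rotations, making the aggregated features
  rotation-robust (verified to 1e-9 in the tests).
* **GLRLM** (run length): maximal runs of equal level along the same 13
  directions; matrices summed by default, with per-direction feature
  averaging as an alternative (`glrlm_aggregate = "mean"`). The
  conservation law Σⱼ j·r(i,j) = ROI voxel count holds per direction and is
  asserted in the tests.
* **GLSZM** (size zone): zones are 26-connected components of equal level
  (the 3D standard), computed by flood fill in C++; direction-free.
* Gray levels are 1-based in every formula (i = 1..Ng) so inverse-square
  terms 1/i² are always defined.
* **Skewness** of a constant ROI is defined as 0 (the 0/0 case), for
  continuity and test determinism.
* **Spherical disproportion** uses surface area from a marching-tetrahedra
  mesh of the occupancy field rather than voxel-face counting, which
  overestimates oblique surface area by up to ~50% and would violate the
  sphere limit. The binary mask is padded by one background voxel (so
  border-touching masks close) and smoothed with a Gaussian of 0.7 voxels
  before meshing at the 0.5 level: meshing the raw binary lattice inherits
  the staircase area (sphere error ≈ +27%), while heavy smoothing shrinks
  high-curvature shapes below their true area. At 0.7 voxels a radius-20
  digital sphere meshes to within 2% of its analytic area and a large
  digital cube to within ~2% of the closed-form cube value 1.2407.

Filter channels: the **original** image; **Laplacian of Gaussian** at
`log_sigmas_mm` (default 3 mm after 1 mm isotropic resampling; σ is
physical, converted to voxels per axis, so the grid must be isotropic);
and the 8 subbands of a single-level separable 3D **wavelet** transform.
The wavelet basis is Coiflet-1 with periodic boundary handling — a compact
orthonormal basis whose decimated subbands preserve energy exactly (the
Parseval check in the tests); subbands are upsampled back to the input
shape by nearest-neighbor repetition so the tumor mask applies unchanged.
Gaussian and Laplacian filtering use mirror (symmetric) padding to avoid
edge artifacts in masks near the volume border. Shape is reported for the
original channel only (it depends only on the mask); the other 12 features
are computed per channel. The headline screening uses the original-channel
cluster prominence; filtered-channel variants are exported for
completeness. Resampling interpolates the image linearly (separable,
equivalent to trilinear) and the mask nearest-neighbor so it stays binary.
ROIs below 27 voxels trigger a warning — texture statistics remain defined
but unstable — and are still computed.

## The synthetic-data generator

The generator defines the conditions under which the pipeline is
validated; it emulates the *statistical* structure the analysis assumes,
not MRI physics.

**Phantoms** (`generate_phantom`): an ellipsoidal tumor (default semi-axes
14 × 12 × 10 mm in a 48³ grid at 1 mm) filled with
`base + correlated field + white noise` (base 300, noise SD 15, field SD
60, arbitrary units). The correlated field is Gaussian white noise
convolved with a Gaussian kernel of width `texture_correlation_mm` — a
simple, seed-stable construction whose single parameter controls intensity
clustering monotonically; a correlation length of 0 disables the field.
Cystic phantoms place a sphere (half the smallest semi-axis) at the tumor
centroid at 30% of base intensity; central placement avoids mask-boundary
interactions confounding the texture tests. With min–max quantization a
*longer* correlation length yields smoother, diagonally concentrated
co-occurrences with heavier marginal tails and hence *higher* cluster
prominence; the end-to-end fixture therefore maps the
high-cluster-prominence phenotype to a 3 mm correlation length and the low
phenotype to 0.6 mm, a calibration at which the two phenotypes separate
without overlap across seeds (asserted in the tests). Not emulated: bias
fields, partial-volume effects, multi-sequence contrast, and the other
nine semantic features as image content (they exist only as table flags) —
so passing tests demonstrate correctness of the computational chain, not
performance on real MRI.

**Cohorts** (`simulate_cohort`): each patient draws the cystic and
high-cluster-prominence phenotypes independently — the source analysis
reported no observed correlation between the two, and no joint
distribution to emulate — with prevalences 0.16 and 0.25. Time to
recurrence is exponential with hazard
`baseline · 20.21^cystic · 5.89^highCP`: an exponential baseline is the
simplest law consistent with proportional hazards, and the two hazard
ratios are the design effect sizes the screening is meant to detect.
Administrative censoring is uniform over (3, 168) months, matching a
cohort whose follow-up ranged 3–168 months; the baseline hazard
(0.0008/month) was calibrated once so the expected relapse fraction is
≈ 22%, the reference cohort's rate. Clinical covariates (age ~ N(58.7,
13.8²) truncated to 12–81, 59.2% women, localization 59/40/1%, Simpson
grades 71/15/8/5%, 29% irradiated) and the remaining semantic flags are
drawn at fixed frequencies and carry no effect, so they calibrate the
null behavior of the screening. A continuous log-normal
cluster-prominence surrogate (shifted +0.9 log units for the high
phenotype) supports threshold-screening runs that do not extract images.

## Validation design and problem sizes

The test suite validates every stage against an independent route: texture
matrices against brute-force enumeration on 200 random ROIs up to 5×5×5
(exact integer counts); feature formulas against hand-evaluated examples;
shape against closed forms (digital sphere of radius 20, digital cube of
side 60); AUC against O(n²) pair counting; logistic ORs against
cross-product ratios; Cox fits against brute-force partial-likelihood
maximization on 4–6-subject datasets; the log-rank statistic against
explicit observed/expected summation. Calibration uses 200 null cohorts of
150 (p-value uniformity by Kolmogorov–Smirnov at α = 0.01, CI coverage in
90–99%) and 200 design-point cohorts of 500 (mean log-HR within 0.15 of
log 20.21 and log 5.89; the screening advances the cystic component with a
CI excluding 1 in ≥ 90% of replicates). These sizes keep the full suite in
the low minutes on one CPU while holding Monte-Carlo error well inside the
asserted bands. The imaging end-to-end path runs at 20–28³ voxel phantoms
with 8–20 patients; the statistical path runs imaging-free at n = 500.

## Degenerate inputs and error policy

Single-voxel ROIs have no co-occurrences (an error names this); empty
masks, one-class outcomes, constant predictors, event-free datasets and
empty group strata raise explicit errors. A constant ROI yields cluster
prominence 0, difference entropy 0, inverse difference normalized 1, and
skewness 0. Per-case extraction failures in the pipeline are logged and
skipped, not fatal, and patients without usable imaging remain in the
clinical/semantic analyses — each analysis uses its maximal available
subset and reports its n.

## Known limitations

* Proportional hazards with an exponential baseline is an idealization;
  the simulator does not generate time-varying effects, so the tests do
  not probe PH violations.
* Wald CIs can be poorly calibrated at extreme hazard ratios with few
  events; profile-likelihood intervals are not implemented.
* The feature bank is deliberately the 13-feature panel plus filter
  variants, not a full radiomics library.
* Semantic flags are simulated as observed truth; inter-rater disagreement
  is out of scope (annotations are inputs).
* DICOM import, bias-field correction, registration and automatic
  segmentation are out of scope; inputs are NIfTI-1 image/mask pairs.
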