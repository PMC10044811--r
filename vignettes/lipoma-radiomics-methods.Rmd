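---
title: "Methods: MRI radiomics for lipomatous tumor classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MRI radiomics for lipomatous tumor classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liporad)
```

## The problem and the modelling approach

Intramuscular (IM) lipomas and atypical lipomatous tumors /
well-differentiated liposarcomas (ALTs/WDLSs) look similar on T1-weighted
MRI, yet their management differs sharply. Radiological cues for
malignancy are quantitative in nature — larger size, more sphere-like
shape, thick septa producing texture heterogeneity, a histogram less
dominated by uniform fat signal, and a deeper location (closer to bone).
`liporad` turns those cues into a reproducible pipeline:

1. **Intensity normalization.** Raw T1W intensities are scanner-dependent,
   so every voxel is expressed relative to a fat-reference ROI:
   `NIV = intensity / mean(reference ROI) * 1000`. A voxel at the
   reference mean maps to exactly 1000. The reference mean is the plain
   arithmetic mean over the ROI, with no trimming.
2. **Feature extraction.** 107 radiomic features over seven families
   (18 first-order, 14 shape, 24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM,
   5 NGTDM) plus the tumor-to-bone distance, 108 in total.
3. **Reproducibility screening.** Features unstable under re-segmentation
   are discarded using ICC(2,1) — two-way random effects, absolute
   agreement, single measurement — with a strict `ICC > 0.75` cutoff.
4. **Classification.** L1-penalized (LASSO) logistic regression serves as
   both feature selector and classifier, with the penalty chosen by
   tenfold cross-validated misclassification error on a stratified 70%
   learning set, and final evaluation on the held-out 30%.
5. **Evaluation.** AUC with DeLong confidence intervals, sensitivity /
   specificity / accuracy with exact Clopper-Pearson intervals, DeLong's
   paired AUC test against readers, Cohen's kappa between readers, and
   Bonferroni-corrected Mann-Whitney per-feature contrasts.

Malignant (ALT/WDLS) is the positive class everywhere: sensitivity is the
detection rate of malignancy.

## The synthetic phantom population

No patient volumes ship with the package; a seeded generator produces 3D
phantoms carrying the class-conditional structure the analysis relies on.
Each case is a 64 mm isotropic grid (1 mm voxels) holding:

* a flat **bone slab** (3 voxels thick) at the low-x face. The study this
  emulates measured the distance from tumor to bone without reporting a
  bone segmentation procedure, so a planar slab is our stand-in: the
  simplest geometry that makes the distance feature informative.
* an **ellipsoidal tumor** with random orientation. The class parameters
  encode the clinical contrasts: benign lesions draw volume-equivalent
  radii of 6-10 mm, axis ratios 1.4-2.2 (elongated), and bone gaps of
  12-20 mm; malignant lesions draw radii 10-16 mm, ratios 1.0-1.3
  (sphere-like), and gaps 2-8 mm. Geometry is deliberately desk-scale —
  real lesions are several times larger — because only the *direction*
  and separation of the class contrasts matter for testing.
* class-conditional **intensities**. Benign tumors draw from a reflected
  gamma distribution whose shape parameter is set from the target
  skewness (`skew = -2/sqrt(shape)`), giving the negative histogram skew
  of homogeneous fat. Malignant tumors draw a symmetric base and add
  2-4 randomly oriented bright planar sheets (+100 raw units, 1.5 mm
  thick) mimicking thick septa; the sheets raise texture heterogeneity
  and pull skewness to mildly positive values, clearly above the benign
  class.
* a spherical **fat-reference ROI** (4.5 mm radius, mean 600) in the far
  corner, used by the NIV normalization.

One master seed drives everything; per-case substreams are drawn once by
case index, so any case is reproducible independently of generation
order.

What the phantoms do **not** emulate: MRI physics (bias fields, coil
profiles, partial-volume fat/water mixing), anatomical context, multi-
sequence contrast, or segmentation ambiguity beyond one-voxel morphology.
A pipeline that passes on phantoms is verified as *software* — correct
formulas, correct plumbing, recoverable planted effects — not validated
as a clinical classifier.

## Feature-engine conventions

The texture definitions leave genuine choices open; the package fixes
them as follows (all exposed or documented, all unit-tested against
brute-force oracles):

* **Discretization**: fixed bin width in NIV units (default 25),
  min-shifted: `level = floor((x - min) / width) + 1`. The emulated study
  did not report its binning; fixed width is the convention of the cited
  feature definitions. First-order Entropy and Uniformity use the same
  binning.
* **GLCM**: symmetric co-occurrence at distance 1 over the 13 unique 3D
  directions, each direction normalized separately, features averaged
  over directions with at least one pair.
* **GLRLM**: run lengths per the same 13 directions, averaged.
* **GLSZM / GLDM**: 26-connected zones; GLDM similarity tolerance
  `alpha = 0`. The dependence matrix is indexed by `dependence + 1` so
  that voxels with no qualifying neighbour occupy the first column.
* **Shape**: surface area and volume come from a marching-tetrahedra
  mesh of the binary mask. The binary field is blended with a one-pass
  3^3 box filter (weight 0.9 on the filtered field) before iso-surfacing
  at 0.5; this rounds off voxel staircase so that a digital sphere of
  radius 20 voxels scores sphericity about 0.98 instead of 0.85 for the
  raw binary surface. Structures thin enough for the smoothing to erase
  fall back to the raw binary field. Axis lengths are
  `4 * sqrt(eigenvalue)` of the voxel-centre covariance; maximum 3D/2D
  diameters use boundary voxel centres. Disconnected masks reduce to
  their largest 26-connected component; `VoxelVolume` is reported
  alongside `MeshVolume`.
* **Tumor-to-bone distance**: minimum Euclidean distance between tumor
  boundary voxel centres and bone voxel centres in physical units, zero
  for touching or overlapping masks, and *missing* (never zero) when no
  bone mask exists.
* **Degenerate inputs**: zero-variance ROIs define Skewness and Kurtosis
  as 0; single-gray-level ROIs take each texture feature's finite limit
  (e.g. GLCM Correlation and MCC are 1, Contrast 0, NGTDM Coarseness is
  capped at 1e6); a single-voxel ROI has no co-occurrence pairs and
  raises an error rather than silently producing noise.

## Reproducibility screening

Re-segmentation is emulated by eroding (intra-observer session 2) and
dilating (second observer) the tumor mask by one voxel, re-extracting
all features, and computing ICC(2,1) per feature. A feature is retained
only if it passes `ICC > 0.75` (strict inequality) in **both** screens —
equivalently, the minimum of the two ICCs must pass. Negative ICCs are
reported as computed, never clamped; they simply fail the filter.
Pearson and Spearman coefficients accompany the ICC for reference. At
phantom scale a one-voxel perturbation is proportionally much larger
than at clinical scale, so the phantom screen is harsher than the
clinical one; the retained set is correspondingly smaller.

## The classifier

`cv_lasso_logistic()` minimizes

```
(1/n) * sum log(1 + exp(-(2y-1) * eta)) + lambda * sum |beta_j|
```

with an unpenalized intercept, by iteratively reweighted least squares
with cyclic coordinate descent (active-set updates, warm starts along the
path, compiled inner loop). Solutions satisfy the KKT subgradient
conditions to 1e-6, and the unpenalized fit matches `glm()` to 1e-4;
`glmnet` is used in the test suite as an independent cross-check, never
as the implementation.

Choices that the workflow leaves open are fixed as:

* **Split**: stratified by class; the learning share of each class is
  `ceiling(0.7 * n_class)`, so 38 + 30 lesions split 48/20. Folds are
  stratified within the learning set.
* **No leakage**: standardization statistics and the LASSO selection are
  recomputed inside every training fold; selection and classification
  are one and the same fit (nonzero support).
* **Penalty grid**: 100 log-spaced values from `lambda_max` (the smallest
  penalty that zeroes every coefficient) down to `1e-4 * lambda_max`.
* **Selection rule**: minimum mean CV misclassification error; ties go to
  the larger penalty (sparser model), which also makes the choice
  deterministic.
* **Threshold**: probability 0.5, exposed in the configuration; the
  emulated workflow did not state one.
* Coefficients are reported on the standardized scale, so the importance
  ranking is simply the absolute standardized coefficient.

## Evaluation statistics

* AUC is the Mann-Whitney concordance with ties counted one half; its CI
  uses the DeLong structural-component variance with normal quantiles
  (clamped to [0, 1]). The paired AUC comparison is DeLong's test; two
  identical score vectors give p = 1 by construction.
* Binary proportions get exact Clopper-Pearson intervals.
* Reader agreement is Cohen's kappa with the asymptotic normal interval.
* Per-feature group contrasts use the Mann-Whitney test as implemented in
  `stats::wilcox.test` (exact for small tie-free samples, tie-corrected
  normal approximation otherwise) with Bonferroni adjustment
  `min(1, m * p)`.
* Demographic 2x2 tables use Pearson's chi-squared without continuity
  correction, switching to Fisher's exact test when any expected count is
  below 5; continuous covariates use Welch's t test by default. The
  no-correction default reproduces the printed two-decimal p-value of the
  emulated study's gender contrast from its published counts.

Reader calls enter as binary scored sets; their "AUC" is the single
operating point implied by the binary decision, matching how reader AUCs
are usually reported alongside model ROC curves.

## Problem sizes used by the test suite

The shipped tests exercise: texture oracles on fixtures up to 5^3 voxels;
sphere/ellipsoid meshes up to radius 20 voxels; ICC recovery at 500
lesions; the full pipeline on compact cohorts (24 lesions, 44^3 grids)
and the default 68-lesion cohort; and classifier recovery on twenty
200-lesion cohorts, requiring held-out AUC of at least 0.85 in 18 of 20
seeds with the selected features intersecting the planted discriminators.
These sizes were chosen so the whole suite runs comfortably on a laptop
while still leaving each statistical check well-powered.

## Known limitations

* The phantom generator's simplifications (planar bone, ellipsoidal
  tumors, Gaussian noise) mean passing tests certify computational
  correctness, not clinical performance.
* The feature definitions follow one widely used convention set; other
  toolkits differ in binning, aggregation and dependence indexing, and
  cross-toolkit numerical identity is not a goal.
* CI methods for sensitivity/specificity (Clopper-Pearson) and AUC
  (DeLong) are stated explicitly because published reports often omit
  theirs; interval widths may differ from reports using other methods.
* With small testing sets, the 0.5 probability threshold can make the
  single-split confusion metrics coarse; the CV error curve is the more
  stable diagnostic.
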