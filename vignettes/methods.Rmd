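---
title: "Two-level clustering of multiparametric MR/PET and genotype classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-level clustering of multiparametric MR/PET and genotype classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gliosom)
```

## The problem and the model

Diffuse gliomas split into prognostically distinct groups by IDH
(isocitrate dehydrogenase) mutation status, and several imaging phenotypes —
larger hypermetabolic volume on amino-acid PET, higher relative cerebral
blood volume, lower ADC — are enriched in IDH wild-type tumors. `gliosom`
implements a voxel-wise pipeline that turns six co-registered volumes per
subject (CE-T1WI, T2WI, FLAIR, ADC, rCBV, FDOPA-PET SUV) into a small set of
interpretable per-subject features and a genotype classifier:

1. **Normalization.** Per subject and channel, intensities are divided by
   `u = P75 + 1.5 * IQR` computed over brain-mask voxels, mapping `[0, u]`
   to `[0, 1]`. Values above `u` are retained (they map above 1): outliers
   are informative here (hypermetabolic foci *are* outliers) and are never
   clipped. Percentiles use linear interpolation between order statistics
   (R's default type 7), recorded so tests can be exact.
2. **Voxel sampling.** Training voxels are taken on a deterministic
   stride-4 lattice (one voxel in every 4 x 4 x 4 block) anchored at the
   first voxel, intersected with the brain mask, and stacked across the
   cohort into a 6 x N matrix.
3. **First-level clustering.** A 20 x 20 batch self-organizing map (SOM)
   quantizes the 6-D feature space into 400 "protoclusters". Each epoch
   assigns every vector to its best-matching unit (BMU, nearest node by
   Euclidean distance, ties to the lowest row-major node index) and replaces
   each node's weight with the Gaussian-neighborhood-weighted mean of all
   inputs. Protoclusters are local averages, so the second level is far more
   robust to outlier voxels than K-means run directly on voxels.
4. **Second-level clustering.** K-means (Lloyd, k-means++ seeding, best of
   10 restarts, empty-cluster runs re-seeded) groups the 400 weight vectors
   into K classes, K in {4, 6, 8, 10, 12, 16, 20}. Class ids are relabeled
   by decreasing class size so runs are comparable.
5. **Label-fraction features.** Every tumor-ROI voxel (full resolution, no
   stride — the ROI is the FLAIR-hyperintensity mask) is painted with its
   BMU's K-class label. For each class, `p_k` = percentage of tumor voxels
   with label k, and the classifier feature is `log10(p_k + 1e-2)`: an
   absent class maps to -2, a 0.99% class to 0, the offset matching the
   percent scale of `p`.
6. **Classification.** A linear SVM over the K log-ratio features, evaluated
   by leave-one-out cross-validation (LOOCV). The cost parameter is re-tuned
   inside every fold with a two-step grid search (coarse `2^-15 ... 2^15` in
   steps of `2^2`, then 9 log-spaced candidates spanning a factor of 4
   around the coarse winner), scored by inner 5-fold stratified CV accuracy,
   ties toward the smaller cost. Age can be appended as a feature,
   standardized with training-fold parameters only. The seven metrics (AUC,
   accuracy, sensitivity, specificity, precision, recall, F1) are computed
   from the pooled held-out decision values; AUC uses the pairwise
   concordance formula with ties counting one half.
7. **Comparison machinery.** The classifier is bootstrapped (subjects
   resampled with replacement, stratified by genotype; the same replicate
   sample feeds every K so the comparison is matched), and replicate
   AUC/accuracy/F1 are compared across K by one-way ANOVA with Tukey HSD.
   Per-label genotype differences use two-sided Mann-Whitney U tests
   (exact for small untied samples) with Benjamini-Hochberg correction at
   alpha = 0.05, applied within each K's family of label tests.

## The synthetic cohort generator

No patient data ship with the package; `generate_cohort()` produces cohorts
with the statistical structure the analysis assumes, so every stage is
testable. Defaults emulate the study composition: 62 subjects, 33 wild-type
/ 29 mutant (deterministic rounding of the class balance), 48^3 voxel
volumes. Each subject has a spherical brain mask; a spherical tumor (radius
uniform in 6-10 voxels) centered uniformly inside the eroded brain; and two
connected focus blobs inside the tumor — hypermetabolic (FDOPA-dominant,
ADC-low) and high-perfusion (rCBV-dominant) — grown as the nearest tumor
voxels around random seeds. The expected focus fractions are
class-conditional: wild-type 15% + 10%, mutant 3% + 2% of tumor voxels,
encoding the larger hypermetabolic and high-perfusion sub-volumes of
wild-type tumors. T2WI and ADC share a latent Gaussian field (SD 0.25),
reproducing their similar SOM component planes as a testable property.
Channel intensities are compartment means (normal brain, tumor bulk, two
foci; per-subject means jittered with the compartment SD) plus additive
Gaussian voxel noise (SD 0.3), clamped at zero because magnitude MRI and
SUV maps are nonnegative. Wild-type ages are drawn at 59 +/- 12 years,
mutant at 46 +/- 12.

What the generator deliberately does **not** emulate: anatomy (no gyri,
ventricles, or white/gray contrast), lesion infiltration and mass effect,
multi-focal or irregular tumors, scanner physics (bias fields, Rician
noise, partial-volume effects), registration error, or segmentation noise
in the tumor ROI. Passing tests therefore demonstrate that the pipeline's
machinery is correct and recovers planted class structure — not that the
classifier's absolute performance transfers to clinical images.

Every random quantity descends from one cohort seed through counter-based
stream splitting (`derive_seed()`), so cohorts are bit-reproducible
regardless of generation order, and the pipeline's top-level seed fans out
to per-stage streams the same way.

## Numerical and design choices

* **SOM hyperparameters** are not dictated by the problem, so the package
  uses standard batch-SOM practice and exposes everything: rectangular
  grid, weight initialization on the plane of the first two principal
  components (sign-fixed, hence fully deterministic), 50 batch epochs,
  Gaussian neighborhood radius decaying linearly from half the grid
  diagonal to 1. With the deterministic initialization, training needs no
  RNG; the stored seed is provenance only.
* **Distances** are unweighted Euclidean in the normalized 6-D space at
  both clustering levels; normalization already equalizes channel scales.
* **BMU ties** break to the lowest row-major node index; the implementation
  computes the affine score `2 x.w - |w|^2` per node, which is an exact
  monotone transform of squared distance, so the tie-break is well defined.
* **Empty K-means classes** re-seed the offending restart (bounded retries)
  rather than returning fewer than K classes, because the feature table
  needs exactly K rows.
* **Percentile support**: normalization percentiles are computed over
  brain-mask voxels only; including background zeros would let mask volume,
  not tissue, set the bounds.
* **Negative intensities** would map below 0 (no clipping anywhere in the
  normalizer); the generator never produces them, but user data are passed
  through untouched.
* **Undefined metrics** (zero denominators, e.g. no positive predictions)
  are reported as NaN, never silently as 0.
* **Grid search placement**: nested inside each LOOCV fold, so no held-out
  subject influences its own cost selection or the age standardization.
  The leakage test duplicates a held-out subject into training and checks
  that its decision value changes.
* **Bootstrap-of-LOOCV**: duplicated subjects are treated as distinct
  resampled units, which is standard but optimistic — a duplicate of the
  held-out subject can sit in training. Replicate metrics are therefore
  comparisons across K, not absolute performance estimates.

## Known limitation: pooled LOOCV decision values are anti-predictive under the null

With a balanced cohort, leaving one subject out always makes its class the
training-fold minority. A regularized linear SVM's decision function then
carries a small offset toward the majority class, and the direction fitted
from training means is slightly anti-correlated with the held-out subject
(its removal moves its own class mean away from it). Pooling one decision
value per fold into a single ROC turns these offsets into systematic
anti-concordance: on cohorts with **no** class signal, pooled LOOCV AUC
sits at or below 0.5 — at strongly regularized cost values the inversion
is deterministic (AUC 0 on a 30/30 null cohort) — and varies widely with
the seed. With genuine class structure the signal dominates and the
artifact is negligible (the default effect cohort scores AUC 1.0 at
K = 16). Interpret near-zero pooled LOOCV AUCs as "no signal", not as
inverse prediction, and prefer the permutation comparison in the tests for
null calibration.

## Problem sizes used in the shipped analyses

The `analysis/` scripts and `scripts/acceptance.R` run the full 62-subject
default cohort: roughly 40,000 stacked training voxels for the SOM, LOOCV
at K = 4 and 16 (plus age at 16), and a bootstrap comparison at 20 matched
replicates over K in {4, 16} with a thinned coarse grid (steps of `2^4`)
and 3 inner folds. The test suite exercises the same code paths on smaller
cohorts (8-12 subjects, 16^3-20^3 volumes, 4x4 to 8x8 grids) and reserves
the 60-subject, 20 x 20 configuration for the parameter-recovery check.
The 100-replicate, all-K bootstrap of the study design is a
`pipeline_config()` default away (`n_boot = 100`, `compare_k =
default_k_set()`).
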