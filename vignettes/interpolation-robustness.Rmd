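---
title: "Quantifying radiomic feature robustness to voxel-size interpolation"
author: "radstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying radiomic feature robustness to voxel-size interpolation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radstab)
```

## The problem

Radiomic modelling extracts quantitative features — shape, intensity
distribution, texture — from a tumour volume of interest (VOI) on a
clinical scan. Clinical PET reconstructions are anisotropic (the axial
step exceeds the in-plane resolution, e.g. 2.73 × 2.73 × 3.27 mm), so 3D
texture analysis first resamples scans to an isotropic grid. The choice of
isotropic voxel size and of interpolation algorithm changes feature values:
some features are essentially invariant, some drift systematically with
voxel size, and some respond unstably. A feature whose value depends
heavily on the resampling choice is a poor biomarker candidate in any
multi-centre setting where resampling is unavoidable.

`radstab` implements the full analysis chain needed to measure, categorise
and — where possible — correct this dependence:

1. **Resampling** of SUV volumes and binary tumour masks to a ladder of
   isotropic voxel sizes (default 1.5, 1.8, 2.0, 2.2, 2.5, 2.7 mm) with
   trilinear or cubic B-spline interpolation, using grid-centre alignment.
2. **Feature extraction** of a 141-feature IBSI-conformant roster:
   63 morphology / intensity features and 78 texture features from the
   GLCM, GLRLM, GLSZM, GLDZM and NGTDM families.
3. **Robustness categorisation** of every feature from two statistics
   computed across the ladder: the intraclass correlation ICC(2,1) of
   feature values (voxel sizes as raters, patients as subjects) and the
   mean Spearman rank correlation $\rho_{mean}$ of patient rankings
   against the 2.7 mm reference.
4. **Surface correction**: for features with a systematic (correctable)
   response, a least-squares surface $SM_f(f, V_s)$ links the fractional
   change to the feature value and voxel size; corrected values are
   $f_{sn} = f - SM_f(f, V_s)\, f$.
5. **Synthetic data**: a PET phantom generator and a drifted-feature-table
   generator make every stage testable without patient data.

## Categorisation model

With thresholds $t_{ICC} = 0.9$ and $t_\rho = 0.95$ (both strict
inequalities), each feature falls into one of four categories:

| ICC(2,1) > 0.9 | $\rho_{mean}$ > 0.95 | category |
|---|---|---|
| yes | yes | **R** — robust |
| yes | no  | **LR** — limited robustness (ranking degrades) |
| no  | yes | **C** — potentially correctable (systematic drift, ranks kept) |
| no  | no  | **NR** — not robust |

ICC(2,1) is the two-way, single-rater, *absolute agreement* form
(Shrout–Fleiss convention), computed from the two-way ANOVA mean squares
with 95% confidence intervals by the F-based formulas of McGraw & Wong
(1996). The *consistency* form ICC(3,1) is always computed alongside: a
feature that drifts additively with voxel size keeps ICC(3,1) high while
ICC(2,1) falls — the signature of a correctable feature. A perfectly
constant feature matrix is defined as perfectly stable (ICC = 1, CI
[1, 1]); an undefined $\rho_{mean}$ (all pairs rank-degenerate) fails the
rank test rather than passing it. Ties receive fractional (average) ranks,
the standard tie-corrected Spearman treatment.

When corrected features are re-categorised on a validation split, C is no
longer an admissible outcome: a corrected feature below the ICC threshold
is NR.

## Resampling conventions

* Target dimensions: $\lceil n\,\Delta / s \rceil$ per axis, so the source
  field of view is always covered; the world-space grid centres of source
  and target coincide (grid-centre alignment).
* Scans: trilinear (8-neighbour) or cubic B-spline interpolation. The
  B-spline uses the standard recursive prefilter (pole $\sqrt3 - 2$) with
  whole-sample mirror boundaries. Constants are reproduced everywhere;
  linear fields are reproduced in the interior, with a boundary deviation
  that decays geometrically (factor ≈ 0.27 per voxel) and is negligible
  beyond ~9 voxels from the edge.
* Out-of-grid target centres clamp to the nearest source edge value, so no
  background values are fabricated at the boundary.
* Masks are **always** resampled trilinearly regardless of the scan
  interpolator, then re-binarised at 0.5 (values ≥ 0.5 → 1). A mask that
  empties under down-sampling is flagged, not fatal; the affected record
  degrades to missing values.

## Feature extraction conventions

* Discretisation: fixed bin size, width 0.5 SUV, lower bound 0 SUV
  (bins [0, 0.5), [0.5, 1), ...). A fixed origin keeps grey levels
  comparable across voxel sizes; the lower bound is configurable.
* GLCM/GLRLM: the 13 unique 3D directions at Chebyshev distance 1,
  merged by summation before normalisation (no per-direction averaging).
  The merged run percentage is normalised by $13\,N_v$ so it stays in
  (0, 1].
* GLSZM/GLDZM zones: 26-connected components of equal level. GLDZM zone
  distance: city-block distance to the first voxel outside the
  morphological mask, border voxels at distance 1 (out-of-image counts as
  outside).
* NGTDM: 26-neighbourhood means restricted to VOI members.
* Degenerate denominators never produce infinities: GLCM correlation and
  information correlation of a single-level VOI are 0, NGTDM coarseness
  with zero denominator is $10^6$, skewness/kurtosis of a constant VOI
  are 0.
* Morphology is computed from the mask alone (plus intensities for the
  centre-of-mass shift, integrated intensity and Moran's I), so shape
  features are identical whichever scan interpolator was used.
* The roster: the 78-texture-feature set is fixed
  (25 GLCM + 16 GLRLM + 16 GLSZM + 16 GLDZM + 5 NGTDM); the 63-name
  group-1 list shipped here (22 morphology + 18 intensity statistics +
  23 intensity histogram) is a versioned package choice drawn from the
  IBSI reference set.
* A voxel-number-normalised feature variant (value / VOI voxel count,
  suffix `-Voxel-Norm`) is available for features such as run-length
  non-uniformity whose magnitude scales with voxel count by construction.

### Surface meshing

Mesh volume, surface area and the derived shape descriptors come from a
marching-tetrahedra triangulation (six tetrahedra per cell) of the 0.5
iso-surface. Meshing the raw binary grid produces a staircase whose area
overestimates a smooth boundary by tens of percent, so the occupancy grid
is first Gaussian-smoothed with $\sigma = \max(0.8\ \text{voxel},
1.5\ \text{mm})$: the level set of a smoothed half-space is unbiased, and
fixing $\sigma$ in millimetres keeps the meshed boundary the same physical
surface at every ladder size (a voxel-unit $\sigma$ would itself inject
voxel-size drift into every shape feature). The residual error is a
curvature-scale shrinkage of order $\sigma^2/R$: below 1% for a 30 mm
radius sphere, but 5–15% for lesions of 5–15 mm radius. Shape *ratios*
(sphericity ≈ 0.999 on a digital ball) are much less affected. If
smoothing erases the iso-surface entirely (masks of a few voxels), the raw
binary grid is meshed as a fallback.

## Surface correction

For a feature categorised C on the testing split, the fractional change
relative to the reference size is collected over all patients and sizes
and a surface is fitted by least squares. Choices that matter:

* **Orientation of the change.** The default is
  $d = (f - f_{ref})/f$ — relative to the *current* value — because then
  $f_{sn} = f - d\,f = f_{ref}$ exactly: a perfectly fitted surface
  inverts a noiseless drift completely. The literal alternative
  $(f - f_{ref})/f_{ref}$ is available behind a switch but makes the
  correction only approximate.
* **Family.** A bivariate polynomial on the standardised (optionally
  log-transformed) feature value × voxel size, degree 2 in value and
  **degree 3** in voxel size. Degree 3 is needed because even the simplest
  multiplicative drift $f = f_0(1+\alpha(v_{ref}-v))$ becomes the rational
  function $\alpha u/(1+\alpha u)$ in the exact-inversion orientation;
  a quadratic in $v$ leaves ~5×10⁻³ residuals on the 6-size ladder while
  a cubic reaches ~2×10⁻⁴.
* **Value axis.** Log-transformed before standardisation when all training
  values are positive and span more than a decade (non-uniformity-type
  features); the flag is stored in the model.
* **Anchoring.** The reference-size points (d = 0 by construction) are
  part of the scatter, anchoring the surface near zero at
  $V_s = 2.7$ mm.
* **Guards.** Patients with a zero denominator are excluded and counted;
  evaluation outside the stored training domain clamps to the boundary;
  surfaces are a pure function of the testing split (validation data never
  touch the fit).

## The synthetic data generators

**Phantoms.** A lesion is an ellipsoid (half-axes 10–18 mm by default) on
a 2.73 × 2.73 × 3.27 mm grid, with background SUV 0.5 and lesion SUV
4–9 — comfortably above the SUVmax ≥ 3 FDG-avidity floor that the
generator enforces as an invariant. Intra-lesion heterogeneity is a
Gaussian random field: white noise convolved with an isotropic Gaussian of
correlation length 4–9 mm, scaled to an SUV amplitude of 0.5–1.5. The
field is evaluated on a 4× supersampled grid and block-averaged to the
acquisition grid, emulating partial-volume averaging, so resampling
phantoms to different voxel sizes approximates sampling one underlying
continuous field. Everything is bit-reproducible from the seed.

What the phantoms deliberately do **not** model: scanner PSF and
reconstruction noise statistics, respiratory motion, multi-lesion
patients, non-ellipsoidal shapes. Passing tests on phantoms therefore
demonstrates correctness of the pipeline's mathematics, not clinical
generalisability of any specific category count.

**Drifted feature tables.** For correction-recovery experiments the
generator bypasses images entirely:
$\text{value}(p, v) = f_0(p)\,(1 + g_p\, d(v))\,(1 + \varepsilon)$ with
lognormal baselines $f_0$, a polynomial drift $d(v)$ in $(v_{ref} - v)$
(so $d(v_{ref}) = 0$), i.i.d. multiplicative noise $\varepsilon$, and an
optional hidden per-patient multiplier $g_p$. Defaults (drift coefficient
1/3 ⇒ 40% drift at 1.5 mm, baseline sdlog 0.3, noise 1%) realise the
correctable archetype: rankings preserved ($\rho \approx 1$) while
ICC(2,1) sits below 0.9. With $g_p \sim N(1, 1.2)$ the drift is
patient-specific: no surface in (feature value, voxel size) can represent
it, and the corrected feature stays below the ICC threshold — the
non-generalising failure mode. These parameter choices were made once as
the study conditions of the recovery experiments.

## Problem sizes used in tests and the acceptance script

The test suite runs entirely on synthetic data: texture builders are
checked against exhaustive brute-force enumeration on 200 random VOIs up
to 6×6×6 with ≤ 4 grey levels; mesh accuracy on a radius-30-voxel digital
ball; correction recovery on 50 replicates of 200-patient drifted tables
with an 80/20 split; and the end-to-end study on a 6-phantom cohort over a
3-size ladder with both interpolators. The acceptance script repeats the
main computations at slightly larger scale (a 12-phantom cohort over the
full 6-size ladder, 50 correction replicates). These sizes were chosen so
the whole suite completes in a few minutes on one core while every
statistic retains enough data to be meaningful; none of them is a
statement about the scale the pipeline supports — `runStudy` streams
patient by patient and scales linearly.

## Known limitations

* Axis-aligned NIfTI volumes only; no DICOM ingestion, no SUV computation
  from raw activity, no oblique orientations.
* Mesh-based morphology shrinks small lesions (see above); voxel-count
  volume is reported alongside as `morph-approxVolume`.
* The correction is defined only towards the 2.7 mm reference, within the
  trained voxel range, and for the discretisation it was trained with;
  correcting across bin widths or to other references is out of scope.
* Category counts on synthetic cohorts depend on the phantom parameter
  ranges and cohort size; they exercise the machinery but do not reproduce
  any particular clinical cohort's counts.

## A minimal session

```{r example, eval = FALSE}
cohort <- generateCohort(20, seed = 1)
cfg <- studyConfig(seed = 1, outDir = "study_out")
res <- runStudy(cohort, cfg)
res$categoryCounts              # R / LR / C / NR per feature group
head(res$testingReport)         # ICCs with CIs, per-size rho, category
res$validation                  # before/after correction on the held-out split
head(res$baReport)              # linear vs spline Bland-Altman, by IQR
```
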