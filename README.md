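# radstab

Robustness of PET radiomic features to isotropic voxel-size interpolation.

Radiomic models built on FDG-PET extract quantitative features (shape,
intensity statistics, texture) from a tumour volume of interest. Because
clinical PET grids are anisotropic (e.g. 2.73 × 2.73 × 3.27 mm), 3D texture
analysis requires resampling to an isotropic voxel size first — and the
choice of that size, and of the interpolation algorithm, changes feature
values. `radstab` is for imaging scientists who need to know *which*
features survive that processing step: it resamples SUV volumes and masks
to a ladder of isotropic sizes, extracts an IBSI-conformant 141-feature
set, categorises each feature's response, and fits per-feature correction
surfaces for the systematically drifting ones. A synthetic PET-phantom
generator makes the whole pipeline reproducible without patient data.

## The statistics at the core

Each feature is extracted at every voxel size of the ladder
(1.5, 1.8, 2.0, 2.2, 2.5, 2.7 mm; 2.7 mm is the reference). Two statistics
summarise its response across sizes:

* **ICC(2,1)** — two-way, single-rater, absolute-agreement intraclass
  correlation (voxel sizes as raters, patients as subjects), from the
  two-way ANOVA mean squares with McGraw–Wong 95% CIs. The consistency
  form ICC(3,1) is reported alongside.
* **ρ_mean** — the mean Spearman rank correlation between the patient
  ranking at each size and the ranking at 2.7 mm (fractional ranks for
  ties).

Strict thresholds categorise the feature: ICC > 0.9 and ρ_mean > 0.95 →
**R** (robust); ICC only → **LR** (limited robustness); ρ only → **C**
(potentially correctable); neither → **NR** (not robust).

For C features, a least-squares surface `SM_f(f, V_s)` maps (feature
value, voxel size) to the fractional change relative to the reference, and

```
f_sn = f − SM_f(f, V_s) · f
```

rescales any value back to the 2.7 mm scale. Surfaces are fitted on a
random 80% testing split and validated on the held-out 20%, where a
corrected feature below the ICC threshold is demoted to NR.

## Worked example

Correction recovery on a synthetic drifted feature (200 patients, 40%
multiplicative drift at 1.5 mm, 2% noise):

```r
library(radstab)
dt    <- generateDriftedFeatureTable(200, driftSpec(sigma = 0.02), seed = 1)
split <- splitCohort(unique(dt$table$patient), 0.8, seed = 1)
tst   <- dt$table[dt$table$patient %in% split$testing, ]
val   <- dt$table[dt$table$patient %in% split$validation, ]

robustnessReport(tst)[, c("feature", "icc21", "icc31", "rho_mean", "category")]
#>             feature icc21 icc31 rho_mean category
#> 1 synthetic-drifted 0.838 0.978    0.994        C

m <- fitSurface(pctChangeTable(tst, "synthetic-drifted"), "synthetic-drifted")
m
#> SurfaceModel for 'synthetic-drifted': degree (2, 3), 960 points, RMS 0.02146
#>   reference 2.70 mm, voxel range [1.50, 2.70] mm, log-value: FALSE

validateCorrection(list(m), val)
#>             feature icc21_before rho_mean_before category_before icc21_after
#> 1 synthetic-drifted        0.761           0.985               C       0.993
#>   rho_mean_after category_after
#> 1          0.985              R
```

Reading the output: the injected drift preserves patient rankings
(ρ_mean 0.994) but breaks absolute agreement (ICC(2,1) 0.838, while the
consistency ICC(3,1) stays at 0.978) — the signature of a systematic,
correctable response, category **C**. The fitted surface (residual RMS
0.021, the injected noise level) applied to the held-out split lifts
ICC(2,1) from 0.761 to 0.993: the feature validates as **R**.

For the image pipeline end to end:

```r
cohort <- generateCohort(20, seed = 1)             # synthetic FDG lesions
res <- runStudy(cohort, studyConfig(seed = 1, outDir = "study_out"))
res$categoryCounts     # R/LR/C/NR counts per feature group
res$baReport           # trilinear-vs-spline Bland-Altman at 2.7 mm
```

`runStudy` writes `features.csv`, `robustness_testing.csv`,
`category_counts.csv`, `validation_before_after.csv`,
`ba_interpolators.csv`, `models.json` and the resolved configuration to
the output directory. A thin command-line wrapper lives at
`inst/scripts/run_study.R`.

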