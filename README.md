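# sctcalib

Commissioning tools for MRI-only radiotherapy treatment planning with
synthetic CT (sCT), aimed at medical physicists and method developers who
need to validate an HU-to-electron-density calibration before an sCT
workflow goes clinical.

## The problem and the method

Dose engines convert CT Hounsfield units (HU) to relative electron density
(RED, water = 1) through a tabulated calibration curve, then attenuate each
beam along its water-equivalent (radiological) path length. A
bulk-assignment sCT writes one fixed HU per tissue class — air −1000,
adipose −75, soft tissue 0, inner bone 204, outer bone 1170 — while patient
CTs at 120 kVp place the same tissues near −1000, −96 ± 6.1, 37 ± 3.9,
219 ± 14 and 1000 ± 23 HU. Adipose and soft tissue fill most of the pelvis,
so class HU sitting at the wrong place on the curve mis-scales every
beamlet's effective path length and biases the dose systematically.

The package builds and validates the *cohort-optimized calibration curve*
that fixes this: anchors at

| class | HU | RED |
|---|---|---|
| air | −1000 | 0.001 |
| adipose | cohort CT mean (≈ −96) | 0.95 |
| soft tissue | cohort CT mean (≈ 37) | 1.04 |
| inner bone | 204 (sCT bulk, unmodified) | 1.1 |
| outer bone | 1170 (sCT bulk, unmodified) | 1.7 |

with piecewise-linear interpolation, against the vendor *original* curve
anchored at the bulk values. Validation is end to end on a seeded digital
pelvis phantom cohort: five-class threshold segmentation, mean-absolute-error
(MAE = N⁻¹ Σᵢ |sCT(i) − CT(i)|) HU agreement, plan recomputation with a
Siddon ray-trace exponential dose engine (arc and robotic non-isocentric
geometries), and evaluation by cumulative DVHs, the D95 coverage ratio
100·D95(sCT)/D95(CT), and the gamma index at 3%/3 mm with local dose
normalization. The phantoms reproduce the three discrepancy artifacts seen
between same-day CT/sCT pairs: rectal gas mismatch, CT-only gold fiducials,
and femoral-head mislabeling.

## Worked example

Derive the optimized curve from a ten-patient synthetic cohort:

```r
library(sctcalib)

cohort <- generate_cohort(10, phantom_spec(), jitter = 0.1, seed = 17)
stats  <- lapply(cohort, function(p) class_hu_stats(p$ct, segment_classes(p$ct)))
curve  <- derive_optimized_curve(cohort_class_stats(stats))
curve
#> <calibration_curve> (optimized), 5 anchors, linear interpolation
#>        class          hu   red
#>          air -1000.00000 0.001
#>      adipose   -95.99967 0.950
#>  soft_tissue    36.99927 1.040
#>   inner_bone   204.00000 1.100
#>   outer_bone  1170.00000 1.700
#>   below -1000 HU: constant; above 1170 HU: linear, clamped at RED 3
```

The adipose and soft-tissue anchors recover the cohort CT class means
(−96 and 37 HU) to well within their standard errors; the bone anchors stay
at the sCT bulk values. `predict(curve, hu)` evaluates the curve on scalars
or whole volumes, `plot(curve)` draws it, `write_calibration()` exports the
TPS-style two-column table with a JSON sidecar.

The full study — simulate, segment, calibrate, compare HU, plan on CT,
recompute on sCT under both curves, evaluate — is one call:

```r
study <- run_study(study_config(n_patients = 10, seed = 1))
study
#> <sct_study> 10 patients, seed 1
#>
#> Cohort CT class statistics (HU):
#>        class ct_mean_hu ct_sd_between sct_bulk_hu
#>          air    -1000.0          0.00       -1000
#>      adipose      -96.0          0.04         -75
#>  soft_tissue       37.0          0.01           0
#>   inner_bone      219.0          0.31         204
#>   outer_bone      999.9          0.74        1170
#>
#> Total MAE: original 15.9 +/- 1.3 HU, modified 3.5 +/- 0.1 HU
#>
#> Dosimetry (optimized curve gamma, D95 ratios):
#>    style gamma_mean gamma_sd gamma_min gamma_max d95_opt_mean d95_opt_sd d95_orig_mean d95_orig_sd
#>      arc        100        0       100       100        99.96      0.051         99.82       0.065
#>  robotic        100        0       100       100        99.94      0.047         99.71       0.058
```

Reading the numbers: overriding the sCT adipose/soft-tissue values to the
cohort CT means cuts the total MAE (15.9 → 3.5 HU here; phantom magnitudes
are anatomy-dependent and much smaller than clinical ones because most of
the field of view is exactly-matching air). Under the optimized curve the
recomputed sCT dose agrees with the CT dose (gamma 100%, D95 ratio within
0.1% of 100) while the original curve's adipose/soft-tissue mis-scaling
pulls the D95 ratio further from 100 for every patient and both plan
styles. A `bone_shift_mm` artifact reproduces the femoral-head-mislabeling
failure mode: the shifted bone shadows the target and drives the robotic
D95 ratio below 100 even under the optimized curve.

A thin CLI wraps the same functions
(`inst/scripts/sctcalib run --config study.yaml`, plus `simulate`,
`segment`, `calibrate`, `compare-hu`, `plan`, `dose`, `evaluate`
subcommands); volumes are NIfTI, plans YAML, curves CSV + JSON.

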