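---
title: "Methods: synthetic-CT calibration commissioning with sctcalib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic-CT calibration commissioning with sctcalib}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sctcalib)
```

## The problem

MRI-only radiotherapy planning replaces the planning CT with a synthetic CT
(sCT) derived from MRI. Dose engines do not consume Hounsfield units (HU)
directly: a calibration curve maps HU to relative electron density (RED,
water = 1), and the beam's water-equivalent path length through the patient
follows from the RED volume. A bulk-assignment sCT writes one fixed HU per
tissue class (air -1000, adipose -75, soft tissue 0, inner bone 204, outer
bone 1170), while patient CTs at 120 kVp place the same tissues near -1000,
-96 &pm; 6.1, 37 &pm; 3.9, 219 &pm; 14 and 1000 &pm; 23 HU. Converting an
image whose class HU sit at the wrong positions on the calibration curve
scales every beamlet's effective path length incorrectly — a systematic,
not random, dose error concentrated in adipose and soft tissue, the two
classes that make up most of the pelvis.

The remedy this package implements and validates is a *cohort-optimized
calibration curve*: anchor the adipose and soft-tissue points of the curve
at the mean HU of those classes measured across a local patient CT cohort
(bone anchors are left at the sCT bulk values, which already lie inside the
literature range), and pair each anchor with its tissue RED (0.95, 1.04,
1.1, 1.7). Because no real patient volumes are distributed with the
package, a seeded digital pelvis phantom cohort stands in for the patients;
everything downstream — segmentation, curve derivation, HU agreement, dose
recomputation, DVH/gamma evaluation — is the same machinery a commissioning
physicist would run on real data.

## The phantom cohort

`phantom_spec()` describes one pelvis: an elliptic-cylinder body
(semi-axes 85 x 65 mm) with a 12 mm subcutaneous adipose shell, a
pelvic-ring torus and two femoral heads (cortical outer-bone shells over
trabecular inner-bone cores), and spherical/cylindrical PTV, bladder and
rectum. The default grid is 96 x 96 x 48 voxels at 2 x 2 x 3 mm — the same
192 x 192 x 144 mm field of view as a clinical pelvis scan at half
resolution in-plane, chosen so that the full ten-patient pipeline (120
dose computations and 20 gamma maps) completes in minutes on one CPU;
clinical-resolution grids are available through `shape`/`spacing`. The
anatomy is illustrative: no published organ-size distributions back it, so
organ geometry should be read as "pelvis-like", nothing more.

The CT is drawn voxelwise as independent Gaussians with the class means
and standard deviations above; the sCT is exactly piecewise constant at
the bulk values. Noise is spatially uncorrelated because only per-class
mean &pm; sd are specified anywhere; real CT noise is correlated and
textured, so MAE-style statistics transfer but noise-power spectra do not.
HU are not clipped below -1000 (the rare sub-air draws are harmless for
every statistic computed here). Cohorts jitter the body semi-axes and
organ radii by a uniform &pm;10% per patient — enough to produce
patient-to-patient spread in the MAE table without pretending to model
anatomy. Patient *i* of a cohort uses seed `seed + i`, so extending a
cohort never reshuffles existing patients.

Three artifact types reproduce the discrepancies a same-day CT/sCT pair
actually exhibits, each independently switchable and on by default where
they are near-universal in prostate SBRT cohorts: `gas_mismatch` (an air
pocket in the rectum on the CT only; bowel filling changes between scans),
`fiducials` (small 1500 HU markers in the PTV on the CT only; gold seeds
return no MRI signal), and `bone_shift_mm` (the right femoral head rigidly
translated medially in the sCT only, emulating atlas bone mislabeling; off
by default because it was a single-patient outlier scenario). What passing
tests on these phantoms demonstrate is that the *pipeline machinery* is
correct and that the calibration mechanism behaves as described; they say
nothing about any particular scanner's HU accuracy or any vendor's sCT
algorithm.

## Segmentation and statistics

CT volumes are segmented into the five classes by interval thresholding.
The class means are separated by at least 11 standard deviations, so
threshold placement is uncritical; the defaults are the midpoints between
adjacent class means (-548, -29.5, 128, 609.5 HU) and are overridable. A
morphological opening (Euclidean ball, default radius 1 voxel) stands in
for the manual contour cleanup a physicist would do: voxels removed by the
opening become *unclassified* — excluded from class statistics, never
reassigned, and still counted in total MAE. At the coarse grids used in
unit tests (4 x 4 x 6 mm) the 3-4 mm cortical shells are thinner than the
opening ball, so coarse-grid analyses disable the opening; at the default
grid it is kept.

Per-class statistics use the population (divide-by-N) standard deviation.
Cohort aggregation is the unweighted mean of per-patient class means —
robust to body-size differences — with a voxel-pooled alternative
available; the between-patient standard error is retained because the
anchor-recovery tolerance (3 standard errors) is expressed in it.

## Calibration curves

`calibration_curve()` objects are the package's fitted-model core:
strictly increasing HU anchors, non-decreasing REDs, `predict()` for
evaluation, `coef()` for the anchor table, `plot()` for the usual curve
figure. Evaluation is piecewise linear between anchors (the standard
convention for tabulated TPS curves; only anchor points are ever
specified), constant below the lowest anchor, and linearly continued above
the highest anchor with a clamp at RED 3.0 so that metal-bright voxels
cannot acquire unphysical densities. Air RED is 0.001 — no source states
it, near-zero is physical, and exactly zero would make path-length
logarithms degenerate in diagnostics. Three curves matter:

* **original** — anchors at the sCT bulk HU (-1000, -75, 0, 204, 1170);
* **optimized** — anchors at (-1000, adipose cohort mean, soft-tissue
  cohort mean, 204, 1170), i.e. `keep_sct_bone = TRUE`;
* **CT** — all anchors at the cohort CT means (`keep_sct_bone = FALSE`);
  this is the clinically commissioned CT curve the planning CT itself is
  converted with.

## What the dose stage compares, and why

The pipeline mirrors a commissioning comparison: plans are created and
normalized on the CT density volume, then recomputed with identical
parameters on the sCT under each candidate curve. Two deliberate design
choices need stating:

1. **The dose stage uses the *modified* sCT** — the sCT whose adipose and
   soft-tissue class values have been overridden to the cohort CT means,
   exactly the override the HU-comparison stage quantifies. In a
   bulk-assignment world the unmodified sCT paired with the original curve
   is a fixed point (every class lands exactly on its own anchor), which
   would make every curve comparison vacuous. The modified sCT is the
   configuration in which the optimized curve is *exact* and the original
   curve mis-scales adipose and soft tissue — the path-length mechanism
   under study. With zero noise and no artifacts the CT (under the CT
   curve) and the modified sCT (under the optimized curve) produce
   bit-identical RED volumes, hence identical doses: the pipeline's
   self-consistency anchor.
2. **Small-metal HU are overridden on the planning CT** (voxels above
   1200 HU set to the soft-tissue mean) before density conversion. The
   dose engine is primary-only; without scatter, a 2 mm gold seed casts a
   hard shadow a collapsed-cone engine would smear out, and that engine
   artifact would contaminate D95 comparisons. Overriding high-Z voxels on
   the planning image is routine clinical practice. HU/MAE statistics keep
   the original values — fiducial discrepancies are part of what MAE is
   meant to show.

## The dose engine

The engine is an acknowledged stand-in for commercial collapsed-cone and
ray-tracing engines, built to preserve the one mechanism under test — the
sensitivity of effective path length to HU calibration — and nothing else.
For each voxel inside the body,

$$D(v) \;=\; \sum_b w_b \,\Big(\frac{d_\mathrm{ref}}{d_b(v)}\Big)^{2}
\exp\!\big(-\mu\,\mathrm{RPL}(s_b \to v)\big)\, A_b(v),$$

with RPL the exact Siddon radiological path length (sum of geometric
voxel-intersection lengths times voxel RED), inverse-square weighting
about the source, and a Gaussian-edged circular aperture (penumbra sigma
2 mm) whose radius is the PTV bounding radius plus a 5 mm margin. The
effective attenuation coefficient defaults to 0.005 per mm
water-equivalent, in the right range for a 6 MV primary beam. There is no
scatter, no heterogeneity kernel, no MLC. Two plan geometries are
provided: *arc* (36 coplanar equispaced beams at 1000 mm SAD, isocentric
at the PTV centroid — a VMAT-like arrangement) and *robotic* (48 beams at
800 mm from spherical-Fibonacci directions on a superior hemisphere, each
aimed at an independently drawn point inside the PTV — a
CyberKnife-like non-isocentric arrangement). SADs and beam counts are
conventional choices, configurable, not taken from any source. Weights
are normalized once on the planning volume so D95(PTV) equals the
prescription (default 40 Gy — the prescription is a config input; no
value is prescribed anywhere) and then frozen.

Numerical notes: Siddon traversal is exact to rounding (validated against
chord-length conservation and a dense-sampling integrator at 0.5%);
beam-order permutation changes results only at floating-point summation
order (tested at 1e-12); the aperture cut-off skips rays whose
transmission is below 1e-6, which bounds the per-beam work to the cone.

## DVH, D95 ratio and gamma

DVHs store the sorted member doses; Dx is the type-7 empirical quantile at
probability 1 - x/100 (linear interpolation between order statistics),
checked against hand-computed order statistics. The headline coverage
metric is `100 * D95(sCT dose) / D95(CT dose)` on the PTV.

The gamma index uses 3%/3 mm with *local* normalization by default: the
dose term divides by the reference voxel's own dose (that is the meaning
adopted for a "local dose" criterion; a global mode normalizing by the
prescription exists but is not the default). Three parameters no source
specifies are decided and recorded in every result: low-dose cutoff 10% of
prescription (the common clinical convention), search radius twice the
DTA, search step DTA/10. The bounded search visits candidate offsets in
order of increasing distance and stops when the distance term alone
exceeds the current best gamma — an exact, not approximate, minimization
over the search grid, verified against an exhaustive brute-force oracle on
small grids. Reference voxels whose evaluated dose is zero get gamma from
the same formula; voxels below the cutoff are `NA` in the map and excluded
from the pass rate.

## Problem sizes and runtimes

Chosen so the complete workflow stays interactive: the default study
(10 patients, 96 x 96 x 48 grid, 36 arc + 48 robotic beams, 6 dose
computations and 2 gamma maps per patient) runs in about 2.5 minutes on
one CPU. Unit tests use a 48 x 48 x 24 grid with the same field of view.
The acceptance script regenerates a ten-patient cohort and re-derives the
optimized curve in under half a minute.

## Known limitations

* The phantom's anatomy, noise model and artifact shapes are schematic;
  absolute MAE values depend on anatomy and are far below clinical values
  (most of the phantom field of view is exactly-matching air), so only
  directions and mechanisms — not magnitudes — transfer to real data.
* The dose engine is primary-only; its D95/gamma differences quantify
  path-length effects, not clinical dosimetry.
* Segmentation is threshold-only and would not survive real partial-volume
  and couch/FOV effects without the morphological cleanup and manual
  review it replaces.
* The bone-shift artifact translates a rigid sphere by whole voxels; real
  atlas failures deform.
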