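---
title: "Measuring implant migration from simulated radiostereometric scenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring implant migration from simulated radiostereometric scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctrsa)
```

## What the pipeline measures

After total hip arthroplasty (THA), the stability of the femoral stem and
acetabular cup is monitored by measuring *migration*: the change of implant
pose relative to its host bone between a baseline scan (just after surgery)
and follow-up scans. Radiostereometric analysis (RSA) and its CT-based
variant express this motion in six degrees of freedom — three translations
Tx, Ty, Tz in millimetres and three rotations Rx, Ry, Rz in degrees — at
the 0.1 mm / 0.1° scale where clinically meaningful differences live.

Raw patient scans are not available at desk scale, so the package pairs the
measurement engine with a synthetic-scene generator that produces complete
virtual follow-up studies with known ground truth. Every downstream claim
in the test suite is a statement about what the engine recovers from scenes
whose true migration is known exactly.

## The measurement chain

For one examination pair (baseline, follow-up) and one implant:

1. **Reference-bone registration.** The bone markers of the reference
   segment (femur for the stem, pelvis for the cup) are superimposed by
   least-squares orthogonal (Kabsch) fitting: the proper rotation and
   translation minimising the summed squared distances between matched
   markers, with the reflection branch rejected by a sign flip of the
   smallest singular vector. This aligns the follow-up scan into the
   baseline patient frame regardless of how the patient was repositioned.
2. **Implant pose fitting.** A parametric implant surface model is fitted
   to the observed implant point cloud in both scans by iterative closest
   point (ICP): nearest-neighbour correspondence against the model's
   surface samples alternating with a Kabsch fit, to a pose-change
   tolerance of 1e-6 mm (cap 200 iterations).
3. **Decomposition.** The relative implant transform is decomposed on the
   segment's anatomic frame: for the stem, an implant-based frame with y
   parallel to the stem long axis (shoulder − tip) and x the component of
   the neck axis orthogonal to y; for the cup, the scanner/table frame of
   the baseline scan. Rotations are Cardan angles in x-then-y-then-z
   order; the translation is that of the implant reference point (model
   centroid by default). Totals are Euclidean norms,
   Ttot = sqrt(Tx² + Ty² + Tz²) and likewise Rtot.
4. **Side convention.** Results are reported as if all hips were
   right-sided: positive translations are medial, superior, anterior;
   positive rotations anterior tilt, internal rotation, and valgus (stem)
   or decreased inclination (cup). Left-hip measurements negate Tx, Ry
   and Rz; Ty, Tz, Rx and both totals are unchanged.

### Why the mirror rule is exact here

Conjugating a rigid motion by the sagittal reflection M = diag(−1, 1, 1)
negates the x-translation and the y- and z-rotation components when the
decomposition frame's z-axis points anteriorly on both sides. For the cup
this holds automatically (table frame). For the stem the geometric frame
construction on mirrored anatomy would flip z to posterior, which would
silently change the rule to "negate Tz, Rx, Ry"; `build_stem_frame()`
therefore signs its x-axis so that z = x × y points anteriorly (the
`anterior_hint` argument). With that convention the single stated rule is
exact for both frames, and the test suite verifies it by building left
scenes as exact sagittal mirrors of right scenes and requiring equality of
the mirrored tables to 1e-9.

### Quality gates

Two standard RSA quality metrics are attached to every measurement and
*flag* records rather than drop them (exclusion is a logged, downstream
decision):

- **Condition number** (threshold < 120): ratio of largest to smallest
  singular value of the centred marker matrix — large values mean the
  markers approach a line and the rigid fit becomes unstable. Planar and
  3-marker configurations have an infinite condition number in this
  3-D definition yet still admit a well-posed rigid fit; `fit_rigid()`
  errors only on genuinely collinear sets.
- **Mean error of rigid body fitting** (threshold < 0.35 mm): RMS residual
  after superposition of the same markers across two examinations; values
  above the threshold indicate marker instability. RMS was chosen over the
  mean absolute residual (the published analyses name the metric without
  defining it); the alternative is a one-line change.

### ICP initialisation and local minima

ICP is a local optimiser. Each simulated examination carries a coarse
implant pose (the truth composed with a bounded random perturbation,
≤ 3° / 4 mm), standing in for the rough localisation an upstream
segmentation stage would provide; when no initial pose is given a
principal-axes alignment with a four-way proper-rotation sign search is
used. Discretely sampled surfaces add lattice local minima — ring-to-ring
tilts and slides along the stem shaft, pole rotations of the cup — so the
models are sampled with irregular ring spacing and ring-size-dependent
azimuth counts, and `fit_model_pose()` finishes with a deterministic set of
perturbed restarts (tilts, pole rotations, axial slides), keeping the pose
with the lowest RMS nearest-neighbour distance. The zero-noise test suite
requires < 1e-6 recovery of arbitrary injected migrations across 100
random scenes, both sides, any patient pose.

## The synthetic study

`study_config()` defaults describe the emulated cohort: 26 subjects
(12 right / 14 left), visits at 0, 3, 12 and 24 months, 9 bone markers per
segment placed uniformly in an ellipsoidal shell (semi-axes scaled by
`marker_spread_mm`, default 40 mm), a duplicated 3-month visit with a
random rigid repositioning (≤ 15°, ≤ 50 mm) between the two scans, and two
measurement methods: CT-based RSA and model-based RSA, the former less
noisy. Which visit carried the double examinations is not stated in the
published design; 3 months — the first visit both methods share — is the
package's choice. Ground-truth migration per subject, segment and DOF is
piecewise linear with a breakpoint at 3 months (fast settling, then
near-plateau), zero at surgery and continuous at the breakpoint, with
per-subject Gaussian slope deviations (`subject_sd`, default 0.02
units/month on the early slope, one tenth of that late). Default
population slopes are set so the 24-month truth matches the reported
2-year cohort migrations: stem subsidence −0.11 mm and retroversion
−0.54°, cup proximal migration +0.31 mm and inclination decrease +0.50°,
accrued almost entirely before 3 months.

**Measurement noise acts on the DOF scale.** Each observation perturbs the
implant's true pose by a small random rigid transform whose six components
are independent N(0, σ²) draws on the respective axes (translations in mm,
rotations in degrees), with per-method σ vectors. The defaults are the
published double-examination difference SDs divided by √2 (so a simulated
double-exam difference reproduces the printed SD scale). The alternative —
iid Gaussian jitter on every surface point — attenuates by roughly the
square root of the point count once the rigid fit averages over the cloud,
which would disconnect the configured σ from the precision the pipeline
measures; it remains available as `point_jitter_sd` (default 0) for
studying fit residuals. Pose-level noise keeps the calibration identity
exact: the SD of double-exam differences converges to σ√2, and the
precision statistic to t·σ√2, which the acceptance suite checks to within
10% over 500 simulated subjects.

Marker instability (`marker_instability_prob`) displaces individual
markers at follow-up visits by N(0, 0.5 mm) per coordinate, exercising the
mean-error gate. Planned-vs-used implant sizes are categorical draws with
match probabilities defaulting to the published proportions (25/26 cup,
23/26 stem size, 16/26 exact stem).

What the generator does **not** emulate: CT imaging physics, segmentation
error structure (noise here is isotropic and independent across visits),
anatomy-correlated marker placement, bone remodelling, or wear. Passing
tests therefore demonstrate the correctness of the measurement and
statistics chain under the stated noise model, not the clinical accuracy
of any imaging product.

## The statistics layer

- **Precision** (`precision_table()`): SD of double-exam differences × the
  two-sided t critical value at α = 0.05 with df based on the number of
  double examinations. The df convention is not universal; the default is
  n − 1 with `df_rule = "n"` available, and the published-table cells used
  as frozen test values were chosen to be invariant to that choice and to
  SD rounding.
- **Bland–Altman** (`bland_altman()`): bias = mean of paired differences,
  limits of agreement bias ± 1.96·SD. The three follow-up visits of each
  patient contribute three pooled comparisons, matching the published
  construction; a repeated-measures LoA variant is deliberately out of
  scope.
- **LS-means** (`lsmeans_by_timepoint()`): repeated-measures model
  `value ~ method × timepoint + (1 | subject)` via lme4, least-square
  means and method differences with 95% CIs per visit through emmeans.
- **Piecewise LME** (`fit_piecewise_lme()`): REML fit of
  `value ~ t + hinge + (1 | subject)` with hinge = max(0, t − 3). The
  random effect is an intercept per subject — the literal published
  specification — with random slopes behind a flag; slope tests use
  Satterthwaite degrees of freedom (lmerTest), the standard approximation
  available here, since the published analysis does not state its df
  method. Requiring two timepoints on each side of the breakpoint means
  migration tables (which start at 3 months) need the definitional zero at
  t = 0 added, as the analysis drivers do.
- **Concordance** (`clopper_pearson()`): exact binomial intervals from
  beta quantiles — lower = qbeta(α/2; k, n−k+1), upper =
  qbeta(1−α/2; k+1, n−k), with the k = 0 and k = n boundaries pinned to 0
  and 1. The beta formulation is validated in tests against the defining
  binomial tail-sum equations to 1e-10 and against `binom.test()`.
  Percentages are rounded half-up to integers only at report time.

## Numerical choices and degenerate inputs

- Cardan order x-then-y-then-z; at the sub-2° magnitudes of migration the
  ordering effect is below reporting precision (the first-order agreement
  test quantifies it: < 0.01° at 1°, < 0.04° at 2°).
- The translation reference point is the implant model centroid,
  configurable in principle to the head centre (stem) or cup centre; which
  point published translations refer to is not stated, and the choice only
  matters when rotations are non-zero.
- Rigid fits error on < 3 points or collinear configurations; ICP errors
  on empty or non-finite clouds; non-converged poses are flagged, and a
  warning names the subject.
- Strictly increasing visit times starting at 0, non-negative SDs, and
  probability bounds are validated before any scene is built; identical
  config and seed give byte-identical serialized studies.

## Problem sizes in the checks

The test suite exercises the full chain at the scale the claims need while
staying desk-sized: 100 random zero-noise scenes (both sides, arbitrary
patient pose) for the < 1e-6 end-to-end recovery property; 500 simulated
subjects for the precision calibration; 200 replicates of 25 subjects for
the mixed-model slope recovery. The analysis drivers under `analysis/`
run the full 26-subject virtual cohort end to end in about a minute.

## Known limitations

- The commercial rigid-alignment objective behind CT-RSA products is
  unpublished; point-based superposition is a stand-in with the same
  output semantics.
- The cup's scanner-frame decomposition assumes the baseline scan pose
  defines the anatomical table frame (the recorded scan pose is undone
  before decomposition); a pelvic anatomic frame at follow-up is not
  modelled.
- Bland–Altman pooling ignores within-subject correlation of the three
  comparisons, as in the published analysis.
- Parametric stand-in implants, not manufacturer CAD geometry: pose
  identifiability of the cup relies on modelled rim screw-hole features.
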