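---
title: "Volumetric shear wave elastography of the patellar tendon: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric shear wave elastography of the patellar tendon: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tendonswe)
```

## The problem

Shear wave elastography (SWE) maps the propagation speed of induced shear
waves — the shear wave velocity (SWV, m/s) — onto the ultrasound B-mode
image; SWV increases with tissue stiffness. A single 2D SWE frame has a
limited field of view and is strongly position dependent, which is a real
limitation for a long structure such as the patellar tendon, where
adaptation and pathology are regionally confined. Tracking the transducer
pose during a freehand sweep and compounding the 2D frames into a 3D
voxel volume removes the position dependence and allows off-line analysis
of distinct tendon regions: proximal, mid-portion and distal, separated by
two cuts placed 10 mm from the insertion landmarks (patellar apex,
tibial tuberosity).

`tendonswe` implements that chain end to end on simulated data: a digital
tendon phantom with a known regional SWV field, a pose-tracked sweep
simulator, the weighted-average compounding step, the landmark-based
regional analysis, a subject-level cohort simulator, and the statistical
inference layer (OLS with exhaustive best-subset selection, t tests, and
regional-delta comparisons). Because the motivating study's raw data are
access-restricted, the package's validation strategy is parameter
recovery: generate data from known ground truth — with the packaged
defaults set to the study's published summaries — and verify that every
stage recovers it.

## The phantom and the sweep simulator

The phantom (`tendon_phantom()`) is an elliptical-cross-section tube
around the straight segment between the two insertion landmarks; a single
`bow` parameter can bend the centerline into a shallow arc. Its true SWV
field is piecewise constant per axial region, with cuts at 10 mm from
each landmark — deliberately the same geometry the regional analysis
uses, so every downstream stage can be checked against an analytic ground
truth. Defaults: landmark separation 46 mm (a typical patellar tendon),
semi-axes 12 × 2.5 mm (width × thickness), regional SWV
(10, 9, 11) m/s — distinct plateaus within the physiological range — and
background 2.0 m/s, distinctly softer than tendon so that any mask
leakage pulls regional means visibly toward it.

`simulate_sweep()` renders 2D frames at poses of a nominal trajectory
(by default a linear out-of-plane sweep through the tendon thickness)
perturbed by Gaussian pose jitter (degrees / mm). Pixel `(r, c)` of a
frame maps to world coordinates as
`R %*% c(c*Δ, r*Δ, 0) + t` with pixel-center convention — an explicit
convention that prevents half-pixel drift between simulation and
reconstruction. SWV pixels sample the true field at the pixel center plus
independent additive Gaussian noise, clipped to the physical bounds
0.5–16 m/s; no noise model is published for the device, so the simplest
testable choice is used. The simulator does not model acoustic
propagation, speckle, transducer physics or knee kinematics; the 20°
knee-flexion posture of the acquisition protocol is metadata, not
mechanics. Consequently, passing phantom-recovery tests demonstrates the
geometric and statistical correctness of the pipeline, not robustness to
real acquisition artifacts (fiber misalignment, shadowing, speed-of-sound
errors).

## Compounding

`compound()` projects every valid pixel into world space and accumulates
`(w·value, w)` on the voxel grid, with a Gaussian weight in
pixel-to-voxel-center distance, σ = voxel spacing (0.5 mm default),
truncated at 2σ. The published description of the reconstruction is
simply a "weighted averaging scheme"; Gaussian forward splatting is the
standard such scheme, and the kernel is an explicit, swappable parameter.
Voxels whose accumulated weight stays at ≤ 1e-12 are undefined (`NA`) and
excluded from all downstream statistics; holes are never interpolated,
to avoid inventing data. Invalid SWV pixels (device void areas) carry
zero weight — they are skipped, not zero-filled.

Two numerical properties follow and are tested: a constant pixel field
reconstructs exactly (a weighted mean of a constant), and every defined
voxel lies within the range of the contributing pixel values. Frame order
only affects floating-point associativity (< 1e-6 m/s).

One property of any forward-splatting scheme matters for validation:
voxels within one truncation radius of the tendon surface mix tendon and
background pixel values (partial volume). The plateau-recovery tests
therefore evaluate interior voxels — the mask eroded by the kernel
truncation radius, and voxels within one radius of a cut plane excluded —
where the noise-free bias is below 0.1 m/s. Means over the full mask are
biased toward the background by construction, as they are in real masked
reconstructions.

## Regional analysis

`partition_regions()` labels each in-mask voxel by the scalar projection
`s` of its center onto the proximal→distal landmark axis: `s ≤ 10` mm is
proximal, `s ≥ L − 10` distal, otherwise mid-portion. The cut planes are
perpendicular to the straight landmark axis — the simplest geometry
consistent with "distance from the insertion"; the cut orientation is not
otherwise specified in the source protocol. Boundary voxels with `s`
exactly at a cut go to the end regions (a deterministic tie-break).
Landmarks are inputs (phantom ground truth or user-supplied JSON);
`segment_bmode()` is a convenience stand-in for manual segmentation —
threshold, largest 6-connected component, landmarks at the centroids of
the extremal end faces along the component's principal axis — not a
reimplementation of an interactive tool.

`regional_means()` reports arithmetic means over defined voxels per
region plus an overall mean. Whether the study's "overall" value is the
mean over all masked voxels or the mean of the three regional means is
not stated; this package uses all masked voxels (the count-weighted
regional mean), and the regional means plus counts are reported so the
alternative is a one-liner.

## The cohort generative model

`simulate_cohort()` draws, per group, independent Gaussian demographics
(age, weight, height; BMI is derived as weight/(height/100)², never
drawn) and shared-distribution tendon covariates (length, CSA). Regional
SWV follows a linear model with indicator coding (skier = 1, male = 1):

    swv_region = b0 + b_group·skier + (b_sex + b_sex_skier·skier)·male
                 + b_age·age + b_len·tendon_length + ε,  ε ~ N(0, σ_r²)

The `sex_effect_skier` term is a sex-by-group interaction allowing the
published pattern of a sex difference within skiers but not controls.
Demographic correlations (e.g. weight–height) are not modeled — only
marginal mean ± SD summaries are published, and independence is the
neutral default.

The packaged parameterization (`study_cohort_params()`) encodes the
study's design: 38 controls (20 female), 30 skiers (14 female),
demographics from the published baseline table, and regional group /
sex / tendon-length effects equal to the published model estimates
(group: 1.495, 1.184, 1.401, 2.202 m/s for overall, proximal, mid,
distal). The residual SD, 1.477 m/s, is the pooled within-group SD of
the published overall-SWV summaries (1.32 with n = 30; 1.59 with
n = 38). Choices the published tables do not determine:

* **Overall SWV has its own model entry.** The overall region's published
  group effect (1.495 m/s) is not the length-weighted combination of the
  three regional effects (≈ 1.22 m/s) — unsurprising, since the real
  overall value is a voxel-count-weighted mean over an irregular mask.
  A derived overall therefore cannot reproduce both the regional and the
  overall estimates. `swv_model` accepts an explicit `overall` entry
  (the packaged default); without one, `swv_overall` falls back to the
  `10 : (L−20) : 10` length-weighted regional mean.
* **Intercept identification.** With one intercept and the group effect
  fixed at 1.495, both published marginal means (8.9 and 10.4 m/s) cannot
  hold exactly (the implied difference under the study's sex composition
  is 1.511). The control mean is matched exactly; the skier marginal
  lands at 10.411, inside the printed precision.
* **Values not published.** Tendon length 46 ± 4 mm and CSA
  100 ± 15 mm² are normative adult patellar-tendon values; control-group
  regional means 9.0 / 8.6 / 8.9 m/s (proximal / mid / distal) follow
  the qualitative published regional pattern, under which skiers show the
  larger distal-minus-mid difference. None of the parameter-recovery
  checks are sensitive to these choices — coefficient recovery is
  invariant to intercepts — but they keep simulated volumes and cohorts
  physiologically plausible.
* **Mid-portion sex effect.** The packaged default places the mid-portion
  sex effect entirely in the skier group (1.080 m/s, the published
  within-skier estimate), with no sex effect in controls.

## Inference layer

`fit_ols()` is QR-based least squares with textbook standard errors,
t-based two-sided p-values, R² and adjusted R² = 1 − (1−R²)(n−1)/(n−k−1);
its test oracle is an independent SVD-pseudoinverse route (agreement to
1e-10). `loo_score()` is the PRESS-based predictive R²
`1 − PRESS/SStot`, with PRESS through the leverage identity
`e_i/(1−h_i)` — verified exactly equal to literally refitting n times.
A leverage of 1 makes the left-out prediction undefined and is an error.

`select_model()` scores **every** subset of ≤ 12 candidate predictors
(including intercept-only) and refits the winner on the full data. The
source protocol's criterion phrase mixes "leave-one-out validation" with
"maximum adjusted R²", so both criteria are implemented and selectable;
the default is adjusted R², following the parenthetical. Ties break
toward fewer predictors, then lexicographically — fully deterministic.
Collinear subsets score −Inf and drop out of the search rather than
aborting the enumeration (the duplicate-column case). Intercept-only is
scored with adjusted R² defined as 0. A property worth knowing:
maximizing adjusted R² over many all-noise candidates increasingly
overfits (each noise predictor is kept when its F > 1); the LOO-PRESS
criterion is more conservative, which is the practical argument for
leave-one-out validation in the first place.

The candidate pool for whole-population models is {group, sex, age,
weight, height, BMI, tendon length, CSA}; within-group models drop
`group` (`cohort_inference()`). Non-selected predictors get no effect
estimates. No multiple-testing correction is applied, matching the
convention of reporting unadjusted p-values at α = 0.05.

`two_sample_t()` defaults to Welch (the pooling choice is not published;
Welch is the safer default), with the Student variant available.
`regional_delta_test()` computes per-subject deltas (distal − mid,
proximal − mid) and compares them between groups: a group effect common
to all regions cancels in the deltas, isolating regional-pattern
differences. An interaction term in a joint model would be the
alternative formulation; the delta t-test is used because it matches a
per-subject difference comparison directly.

## Reproducibility, problem sizes, numerical choices

Everything stochastic is seeded: sweeps and cohorts are bitwise
reproducible given their seed, and `run_pipeline()` expands one global
seed into per-stage seeds (`seed + 1000·stage`) so stages can be rerun
independently. The test suite uses deliberately modest problem sizes —
phantoms of ~45 mm at 0.5–1 mm voxels, 200–500 simulated cohorts for
recovery checks, 100-seed selection sweeps, 10,000 null draws for t-test
calibration — chosen so the whole suite runs in well under a minute of
compute while keeping Monte-Carlo standard errors small enough for
3-SE assertions.

Numerical conventions: SWV values are bounded to 0.5–16 m/s everywhere;
voxels are undefined below an accumulated weight of 1e-12; NRRD is the
canonical volume format (plain-text header carrying spacing and origin,
raw little-endian doubles, undefined voxels as NaN) with optional NIfTI
export; poses CSVs are validated for orthonormality at 1e-6 on read.

## Known limitations

* The phantom is piecewise-constant and noise is i.i.d. Gaussian; real
  tendons have smooth SWV gradients, anisotropy, and spatially correlated
  device noise. Recovery results bound geometric/statistical errors of
  the pipeline, not device physics.
* Demographics are uncorrelated within group; BMI's collinearity with
  weight and height in real cohorts is only partially reproduced (BMI is
  derived, so the deterministic part is present).
* `segment_bmode()` assumes a bright tendon on dark background — the
  phantom convention, the opposite of real B-mode appearance where
  segmentation is manual.
* Regional means over the full mask are biased toward background near
  the surface (partial volume); comparisons between groups are unaffected
  as the bias is common, but absolute levels from small/thin phantoms
  should be read with the erosion caveat above.
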