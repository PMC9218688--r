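# tendonswe

Simulation and analysis of volumetric shear wave elastography (SWE) of
the patellar tendon.

SWE maps the propagation speed of induced shear waves — the shear wave
velocity (SWV, m/s), which increases with tissue stiffness — onto the
ultrasound image. A single 2D frame is position dependent; tracking the
transducer pose during a freehand sweep and compounding the frames into a
3D voxel volume enables off-line analysis of distinct tendon regions.
`tendonswe` implements that full chain on simulated data, for
methodologists who want a tested, ground-truth-driven reference for
regional 3D-SWE tendon analysis:

* **Digital phantom & sweep simulator** — an elliptical-tube tendon with
  a known piecewise-constant regional SWV field and a pose-tracked 2D
  sweep simulator with pose and value noise.
* **Reconstruction** — Gaussian forward-splatting weighted averaging of
  pose-tagged frames into SWE and B-mode voxel volumes:
  value(v) = Σᵢ wᵢ xᵢ / Σᵢ wᵢ, wᵢ = exp(−dᵢ²/2σ²) truncated at 2σ.
* **Regional analysis** — tendon masking, cuts 10 mm from the proximal
  and distal insertion landmarks perpendicular to the landmark axis,
  regional mean SWV (overall / proximal / mid-portion / distal).
* **Cohort simulator** — two groups (control / skier), sex, Gaussian
  demographics, and regional SWV from a linear generative model
  `swv = β₀ + β_g·skier + β_s·male (+ β_a·age + β_l·length) + ε`,
  packaged with a parameterization matching the published summaries of an
  elite-alpine-skier case-control study (38 controls / 30 skiers,
  overall SWV 8.9 ± 1.59 vs 10.4 ± 1.32 m/s).
* **Inference** — OLS with standard errors and adjusted R², PRESS-based
  leave-one-out predictive R² via the leverage identity e/(1−h),
  exhaustive best-subset model selection (adjusted-R² or LOO-PRESS
  criterion), Welch/Student t tests, and between-group tests on regional
  deltas (distal − mid, proximal − mid).

## Worked example

Simulate a noisy pose-tracked sweep over a phantom, reconstruct, and
summarize regional SWV:

```r
library(tendonswe)
ph <- tendon_phantom(swv_true = c(proximal = 10, mid = 9, distal = 11))
traj <- linear_sweep_trajectory(ph, n_frames = 15)
frames <- simulate_sweep(ph, sweep_config(traj, pose_noise_sd = c(0.5, 0.25),
                                          swv_noise_sd = 0.3, seed = 1))
vols <- compound(frames)
mask <- phantom_mask(ph, vols$swe$spec)
regional_means(apply_mask(vols$swe, mask), partition_regions(mask), mask)
#> Regional mean SWV (m/s)
#>   overall   8.893  (34500 voxels)
#>   proximal  9.258  (7500 voxels)
#>   mid       8.367  (19500 voxels)
#>   distal    9.895  (7500 voxels)
#>   tendon length 46.0 mm
```

The regional ordering (distal > proximal > mid) matches the phantom's
(11, 10, 9) m/s plateaus; absolute means sit below the plateaus because
voxels near the tendon surface mix in background contributions (partial
volume — see the methods vignette; interior voxels recover the plateaus
to < 0.1 m/s).

Simulate a cohort under the packaged study parameterization and fit the
published overall-SWV model (group + sex indicators):

```r
co <- simulate_cohort(study_cohort_params(), seed = 1)
summary(co)
#>          n female swv_overall    sd
#> control 38     20       8.731 1.504
#> skier   30     14      10.604 1.501
fit_ols(co$swv_overall, cohort_design(co, c("group", "sex")))
#> OLS fit: n = 68, R² = 0.2834, adj. R² = 0.2613, sigma = 1.5137
#>             Estimate Std.Error       t p.value
#> (Intercept)   8.6954    0.3011 28.8805  0.0000
#> group         1.8684    0.3704  5.0448  0.0000
#> sex           0.0756    0.3678  0.2054  0.8379
regional_delta_test(co)
#> Regional SWV delta comparison (skier vs control)
#>   distal_minus_mid    skier +0.609, control +0.212, p = 0.4573
#>   proximal_minus_mid  skier -0.756, control +0.349, p = 0.05779
```

The fitted group coefficient (1.87 m/s here) scatters around the
generating value 1.495 m/s with SE ≈ 0.37; averaged over many simulated
cohorts it is unbiased (that recovery is what the acceptance script
measures). `cohort_inference(co)` runs the exhaustive best-subset
selection per region, and `run_pipeline(run_config(seed = 1), "out/")`
drives the whole chain — sweep, volumes (NRRD), mask, regional CSV,
cohort CSV and model-selection JSON — from one seed.

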