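# liftload

Low-back loading and lifting-risk analysis in R: the Revised NIOSH Lifting
Equation (RNLE) next to person-specific, EMG-driven estimates of
lumbosacral (L5-S1) joint loads.

Repeated manual lifting is a leading cause of work-related low-back
disorders, and the forces behind that risk act at the lumbosacral joint.
Ergonomists screen tasks with the RNLE, which scores the *task*; EMG-driven
musculoskeletal models instead estimate the compressive and shear loads a
specific *person* experiences while performing it. `liftload` implements
both and the statistics to compare them, for researchers in occupational
biomechanics and ergonomics who want a tested, scriptable pipeline that
runs end-to-end on synthetic data with known ground truth.

## What the package computes

**RNLE.** The recommended weight limit
`RWL = 23 · HM·VM·DM·AM·FM·CM` (kg) and lifting index
`LI = load / RWL`, using the metric Applications-Manual multiplier
formulas with the frequency/coupling lookup tables shipped as CSV.
`design_task_for_li()` inverts the equation to build task geometry for a
target LI — the device used to construct the three risk conditions
(LI = 1, 2, 3 with 21/21/20 kg loads).

**Signal conditioning.** Zero-phase Butterworth filtering (6 Hz for
motion/forces; 20–400 Hz band-pass, rectification, 5 Hz low-pass for EMG
envelopes), iMVC normalization, lift-cycle segmentation at a 0.025 m/s
vertical box-velocity threshold, and 201-point time normalization.

**Trunk model.** A planar two-segment L5-S1 model with six lumped active
Hill-type muscle groups (bilateral longissimus, iliocostalis, rectus
abdominis) plus a lumped passive group: inverse-dynamics sagittal moments,
EMG-driven moments `M = Σ sᵢ rᵢ(θ) Fᵢ`, and compression/shear from a planar
joint-reaction balance, reported raw and body-normalized (N·m/kg and
multiples of body weight).

**Calibration.** Per-subject personalization of muscle parameters (force
scales, activation shape factors, fibre-length scale) by minimizing the
normalized RMSE between EMG-driven and inverse-dynamics moments over the
low- and high-risk trials, validated on the held-out middle condition.

**Risk statistics.** Shapiro–Wilk normality checks, paired Wilcoxon
signed-rank tests across risk levels with Bonferroni correction, and a
centroid (k-means, default k = 6) re-stratification of peak compressive
loads grouped with peak moments, with pairwise Welch t tests and a
risk-level × cluster cross-tabulation.

**Synthetic data.** A seeded generator emulating the study design
(7 subjects × 3 conditions × 3 repetitions, 340 Hz motion / 1000 Hz EMG,
minimum-jerk box trajectories, risk-scaled trunk flexion and antagonist
co-activation, raw-like EMG whose envelope tracks known excitations), with
ground-truth parameters and loads stored for recovery tests.

## Worked example

```r
library(liftload)

# Score a lifting task with the RNLE
rnle_assess(lifting_task(21, H = 40, V = 50, D = 60))
#> <rnle_result>
#>   multipliers: HM 0.625 VM 0.925 DM 0.895 AM 1.000 FM 1.00 CM 1.00
#>   RWL: 11.90 kg (LC 23 kg)
#>   LI: 1.765 (load 21.0 kg) -> risk medium
```

A 21 kg load on a task whose geometry only permits 11.9 kg gives a lifting
index of 1.77 — a medium-risk lift (1 < LI ≤ 2).

```r
# Generate a synthetic study and estimate one trial's loads
ds <- generate_dataset(generator_config(n_subjects = 7, seed = 42))
tr <- ds$trials[[7]]                       # subject S01, high-risk condition
p  <- process_trial(tr, ds$subjects[[tr$subject_id]])
p
#> <processed_trial> subject S01 L3 rep 1 | cycle 1.46 s | ROM 72.9 deg | peak M_id 261.2 N m

loads <- estimate_trial_loads(ds$models[[tr$subject_id]], p)
loads
#> <joint_load_series> 201 samples | peak moment 257.4 N m | peak compression 7221 N | peak |shear| 806 N
#>   normalized: 3.00 N m/kg, 8.59 BW compression, 0.96 BW shear
round(flag_exceedance(loads)$fraction, 3)
#> [1] 0.851
```

This high-risk lift flexes the trunk through 73°, produces a peak sagittal
lumbosacral moment of 3.0 N·m per kg body mass and a peak compression of
8.6 body weights (7.2 kN) — above the 3.4 kN action limit for 85% of the
lift cycle.

The full pipeline (generate → process → calibrate on the low- and
high-risk trials → estimate loads for all trials → statistics → cluster
re-stratification) runs with one call and writes every stage output to
disk:

```r
out <- run_pipeline(pipeline_config("results", seed = 1))
```

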