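---
title: "Estimating low-back loading during lifting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating low-back loading during lifting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liftload)
```

Work-related low-back disorders are strongly associated with the compressive
and shear forces that repeated lifting places on the lumbosacral (L5-S1)
joint. Ergonomic practice screens lifting tasks with the Revised NIOSH
Lifting Equation (RNLE), an empirical formula that does not observe the
worker at all; musculoskeletal modelling driven by surface EMG and joint
kinematics instead estimates the loads a specific person actually
experiences. `liftload` implements both routes and the statistics needed to
compare them: the RNLE calculator with inverse task design, an EMG-driven
planar trunk model with per-subject calibration, a seeded synthetic-data
generator that emulates a three-risk-level lifting study, and risk
statistics including a centroid re-stratification of compressive loads.

## The RNLE calculator

The recommended weight limit is

$$\mathrm{RWL} = LC \cdot HM \cdot VM \cdot DM \cdot AM \cdot FM \cdot CM,
\qquad LC = 23\ \mathrm{kg},$$

and the lifting index is $\mathrm{LI} = m_\mathrm{load} / \mathrm{RWL}$.
The multiplier formulas are the metric Applications-Manual definitions
($HM = 25/H$ with $H$ in cm clamped to $[25, 63]$; $VM = 1 - 0.003|V-75|$
for $V \in [0, 175]$; $DM = 0.82 + 4.5/D$ with $D$ clamped to $[25, 175]$;
$AM = 1 - 0.0032A$ for $A \in [0, 135]^\circ$), with the frequency and
coupling multipliers taken from the published lookup tables shipped as CSV
files under `inst/extdata/`. Frequencies between tabulated rows use the
next-higher row (the conservative choice); variables beyond the
applicability limits zero the corresponding multiplier and flag the task as
not recommended. Risk bands follow the three design points of the study
design: low for $\mathrm{LI} \le 1$, medium to 2, high to 3, very high
above.

`design_task_for_li()` inverts the equation: given a target LI and load, it
solves for the free geometry variables (any subset of $H$, $V$, $D$) while
holding $AM$, $FM$, $CM$ fixed. The required multiplier product is spread
across the free variables as close to evenly (geometric mean) as each
variable's admissible multiplier range allows, with the last variable
absorbing the exact residual; targets outside the attainable product range
(above 1, or below $\approx 0.26$ when all three variables are free) raise
an infeasible-design error rather than a silently clamped task.

```{r rnle}
rnle_assess(lifting_task(21, H = 40, V = 50, D = 60))
rnle_assess(design_task_for_li(3, 20))$LI
```

## Signal conditioning

All filters are Butterworth designs applied forward and backward
(zero phase). Motion and force channels use a 4th-order 6 Hz low-pass; raw
EMG is band-pass filtered 20–400 Hz, full-wave rectified, low-pass filtered
at 5 Hz (the linear envelope), normalized to the mean of the three iMVC
peaks per channel, and time-normalized to 201 samples over the lift cycle.
Because the standard two-pass trick leaves large transients on signals with
a DC offset, the implementation seeds each pass with its steady-state
initial conditions and pads with odd reflection (three filter lengths), so a
constant trace passes through unchanged.

Lift cycles are bounded by a 0.025 m/s threshold on the vertical box
velocity: the cycle starts at the first sample above the threshold and ends
at the first sample after the displacement maximum that falls back below
it. The end rule deliberately uses the `+threshold` crossing (not a sign
reversal): it captures both a box settling to rest and a small negative
overshoot, and is robust for monotone-rise trajectories. The 201-sample
reduction uses shape-preserving monotone-Hermite cubic interpolation, which
is endpoint-exact and reproduces linear and constant segments without
overshoot.

## The planar trunk model

The full-resolution models used for lifting analyses articulate hundreds of
muscle-tendon units; their geometry cannot be reproduced from published
text, and the analyses of interest here are sagittal. The model is
therefore a planar two-segment system: a fixed pelvis and a trunk (plus a
lumped arms-and-head mass) rotating about L5-S1, with the hand-held load
acting at a fixed lever. Segment parameters come from standard
anthropometric fractions (trunk 43% of body mass, centre of mass 45% up the
trunk, arms+head 16%), all overridable per subject.

The inverse-dynamics moment is
$$M(t) = I\ddot\theta + (m_t d_t + m_{ah} d_{ah})\, g \sin\theta +
F_\mathrm{load}(t)\, d_\mathrm{load} \sin\theta,$$
with angular derivatives by central differences on the filtered angle
(one-sided at the endpoints), and $F_\mathrm{load}$ the vertical hand force
(load weight plus its vertical inertia).

Six lumped active Hill-type groups (bilateral longissimus, iliocostalis,
rectus abdominis) plus one lumped passive group actuate the joint; the
channel-to-MTU bookkeeping of the full model (238 units over 11 rows) is
retained as metadata in `mtu_mapping_table()`, and the lumped group unit
counts reproduce its totals. The passive group carries the unmeasured
muscles at a constant minimal excitation of 0.01, since no recording exists
to drive them. Each group has a rigid tendon, zero pennation, a Gaussian
active force–length curve of width 0.45, a hyperbolic force–velocity curve
with eccentric plateau 1.4 and maximal shortening velocity of 10 optimal
fibre lengths per second, and an exponential passive curve capped at one
$f_\mathrm{max}$. Rigid tendons avoid an inner equilibrium solve; the
systematic offset this introduces is absorbed by calibration. The
excitation-to-activation nonlinearity is
$a(u) = (e^{Au}-1)/(e^{A}-1)$ with shape factor $A \in [-3, 0]$.

Moment arms are polynomials in the flexion angle with magnitudes around
5–7 cm; extensor arms *decrease* with flexion, as erector spinae moment
arms are documented to do. Lengths are defined by the consistency relation
$s_i\, r_i(\theta) = \mathrm{d}l_i/\mathrm{d}\theta$ (with $s_i = +1$ for
extensors, $-1$ for flexors, and $\theta$ flexion-positive), i.e. extensors
lengthen and flexors shorten with flexion; with an extension-positive angle
convention this is the familiar $r = -\mathrm{d}l/\mathrm{d}\varphi$.

Joint reaction uses the planar Newton–Euler balance of the trunk+load free
body. Muscle lines of action are taken along the trunk longitudinal axis,
so muscle force adds one-for-one to compression and contributes no shear —
a deliberate simplification consistent with using the trunk axis as a proxy
for the sacral endplate normal (the endplate orientation is not specified
in the source material for the full model either). Shear is reported
positive when the upper body tends to slide anteriorly, which is its
direction in flexed lifting. Moments are normalized by body mass (N m/kg)
and forces by body weight (multiples of BW), reproducing the units in which
such results are conventionally reported; `flag_exceedance()` compares
compression against the 3.4 kN action limit used in ergonomic guidance.

## Calibration

Generic muscle parameters are personalized by minimizing, over designated
calibration trials (the low- and high-risk conditions, so the model must
interpolate to the middle one), the moment-tracking error

$$J = \frac{1}{N}\sum_\mathrm{trials}
\frac{\mathrm{RMSE}(M_\mathrm{EMG} - M_\mathrm{ID})}{\max |M_\mathrm{ID}|}.$$

The per-trial peak normalization makes low- and high-risk trials weigh
equally despite different moment magnitudes. The default parameter vector
has seven entries: a maximal-force scale in $[0.5, 2.5]$ and a shape factor
in $[-3, -0.001]$ per merged muscle (left/right homologues share
parameters — symmetric lifting halves the parameter count), plus one global
optimal-fibre-length scale in $[0.5, 1.5]$. The optimizer is bounded
L-BFGS-B with numerical gradients and seeded multi-start (default 5
starts): at this parameter count a deterministic multi-start local search
reaches the same basin as stochastic global schemes in a fraction of the
time, and identical seeds reproduce results bit-for-bit. A zero iteration
budget returns the initial parameters, and a result worse than the initial
point is discarded in favour of the initial parameters.

## The synthetic-data generator

No raw recordings ship with this package, so the generator produces
datasets with the statistical structure the analysis assumes, plus the
ground truth needed for recovery tests. Defaults emulate the study design:
7 subjects, 3 conditions designed by `design_task_for_li()` to hit LI 1, 2,
3 with 21/21/20 kg loads, 3 repetitions; motion at 340 Hz and EMG at
1000 Hz. Subjects draw BMI from Normal(24.70, 1.80) and stature from
Normal(1.75, 0.06 m), with mass truncated to [55, 100] kg. Box motion is a
minimum-jerk rise over the task's travel distance (1.5 s, peak velocity
$1.875\,d/T$) between stationary padding; the trunk flexes to a
risk-dependent peak (45/65/85° plus ±5° subject and ±2° repetition jitter,
gaps chosen so the range-of-motion ordering holds for every draw) and
extends back during the lift. Antagonist co-activation is
$0.05 + 0.03 \times$ risk level, which makes compression grow faster than
the moment across levels — the structure the cluster re-stratification
exploits.

Excitations are solved so the ground-truth model reproduces the
inverse-dynamics moment exactly: passive and antagonist contributions are
computed first, the remaining extensor demand is split by a
posture-dependent synergy (the longissimus share grows with flexion, which
keeps the two extensors' force scales separately identifiable in
calibration), and where the demand falls below the extensors' passive floor
the antagonists pick up the surplus. Raw EMG is band-limited (20–400 Hz)
Gaussian noise, flattened by its own linear envelope and amplitude-modulated
by the excitation, plus an additive baseline worth 2% of the iMVC envelope
(typical of surface EMG); the modulation depth is pre-compensated for the
quadrature contribution of that baseline, so the extracted envelope tracks
the excitation target by construction. A `"clean"` mode stores noiseless
envelopes directly for parameter-recovery experiments.

What the generator does *not* emulate: soft-tissue artefact, electrode
crosstalk and placement variability, fatigue-induced spectral shifts,
marker occlusion, asymmetric lifting, and between-repetition strategy
changes. Passing tests on this data therefore demonstrate that the
pipeline's stages are mutually consistent and recover known ground truth —
not that the model reproduces any particular laboratory's subject-level
values, which depend on recordings this package does not ship.

## Risk statistics and cluster re-stratification

Per-trial summaries take peaks strictly within the detected lift cycle;
left/right homologous channels are averaged *after* peak extraction.
Distributions are checked with Shapiro–Wilk; risk levels are compared with
paired Wilcoxon signed-rank tests (pairing by subject × repetition, n = 21
at default scale) with Bonferroni correction over the three level pairs,
reporting the tie-corrected normal-approximation z alongside the exact p
where available. Compressive loads grouped with moments are re-stratified
by seeded multi-start k-means on standardized features with a fixed default
k = 6; since the choice of six is an empirical outcome rather than a stated
rule, a mean-silhouette scan over k ∈ [2, 8] is reported alongside.
Clusters are relabelled by ascending compression centroid, pairwise Welch
t tests quantify their separation (t negative when the lower-labelled
cluster has the lower mean), and a risk-level × cluster cross-tabulation
shows how the empirical risk bands spread across load-based clusters.

```{r pipeline, eval = FALSE}
out <- run_pipeline(pipeline_config("results", seed = 1))
out$clusters
```

## Numerical choices and problem sizes

* Zero-phase filtering: steady-state initial conditions plus odd reflective
  padding of three filter lengths; series shorter than the warm-up raise an
  error rather than returning transient-dominated output.
* Time normalization: monotone-Hermite cubic on the cycle's time axis;
  degenerate cycles (< 2 samples) are errors.
* Segmentation ties: the first threshold crossing wins; if velocity never
  drops below threshold after the displacement maximum, the cycle ends at
  the last sample.
* Calibration: objective tolerance is L-BFGS-B's default with `factr 1e7`;
  per-trial normalized RMSE is reported so held-out validation is
  comparable across magnitudes.
* k-means: 50 restarts under a fixed seed; relabelling breaks label
  permutation nondeterminism.
* Default problem sizes are the study scale (7 × 9 trials, ~3.3 s per
  trial): full dataset generation takes about a second and the complete
  pipeline a few minutes on a single core; unit tests use 1–2 subjects.

## Known limitations

The planar model omits ligaments and other passive joint structures,
intra-abdominal pressure, frontal/transverse moments, and muscle shear
components; absolute load magnitudes are therefore conservative and the
shear channel in particular is gravity-driven only. Moment arms and Hill
constants are lumped-scale choices, not anatomical measurements; the
calibration absorbs subject-level scaling but not structural mismatch. The
Wilcoxon pairing assumes repetitions are exchangeable within condition.
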