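---
title: "Methods: automatic surgical skill rating from instrumented trainer recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic surgical skill rating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lapskill)
```

## The problem

Expert review of surgical training videos with the OSATS rubric (five
domains, each scored 1-5) is the accepted way to rate trainee performance
on tasks such as laparoscopic intracorporeal suturing, but it is slow and
requires a trained rater. `lapskill` implements the alternative: rate the
performance directly from sensor data recorded in an instrumented box
trainer — 6-DOF electromagnetic pose streams for the two instruments
(a Maryland dissector and a needle driver) and the endoscope at roughly
20 Hz, plus a flex-sensor voltage per instrument handle that encodes grip
angle. The pipeline turns those raw streams into 280 motion-analysis
features (MAFs) per trial and regresses the summed OSATS score (5-25 in
principle; 5-20 observed when no domain merits a 5) on them.

## Calibration models

**Tip offset (pivot calibration).** With the tool tip held stationary in a
rig while the handle rotates, every recorded sensor position lies on a
sphere centred on the tip. Writing the tip in world coordinates as
$t = p_i + R_i d$ for each sample $(p_i, R_i)$, the unknowns $(d, t)$ enter
linearly, so `fit_tip_offset()` solves the stacked least-squares system
$[R_i \mid -I]\,(d, t)^\top = -p_i$ directly. This is algebraically the
same estimate as fitting the sphere (the residual norm is the deviation of
each $\lVert p_i - t\rVert$ from $\lVert d\rVert$) but also yields the
sensor-frame offset direction, is closed-form, and cannot diverge. The
smallest singular value of the design matrix guards against degenerate
rigs: if all orientations coincide the problem is rank-deficient and the
function refuses to answer rather than return an arbitrary solution.

**Grip map.** Each handle posture (open / closed, plus the ratcheted
posture for the needle driver) is held ~5 s; the anchor voltage is the
segment mean after trimming 0.5 s from each end (button presses and
settling live in the trimmed zones). Voltage-to-angle conversion is
piecewise-linear between anchors and clipped outside the calibrated range;
a non-monotone anchor sequence indicates a sensor fault and is an error,
not a warning. The handle angles themselves (defaults 30 degrees open, 0 closed,
3 for the unratcheted needle-driver stop) are configuration: they are a
property of the instrument, not something the voltages can identify.

**Field-of-view cone.** The endoscope's visible volume is modelled as a
cone (apex, unit axis, half-angle) in the scope-sensor frame, fitted to
boundary points traced at two or more distances. Initialization is
geometric: a plane-plus-circle fit per traced ring, apex by similar
triangles along the line through the ring centres, half-angle from
$\arctan(\Delta r / \Delta d)$. Refinement minimizes the squared angular
residuals (angle between point-minus-apex and the axis, minus the
half-angle) with BFGS, capped at 200 iterations; if refinement fails to
reduce the residual the initialization is returned, so the fit can never
be worse than its starting point. The traced points are assumed to lie on
the boundary of the view, not merely inside it.

## Kinematic preprocessing

The stage order is fixed: **filter, then resample, then transform, then
differentiate**. Filtering precedes resampling so that noise is removed at
the native rate; differentiation comes last so that derivative noise is
never amplified before smoothing.

**Zero-phase low-pass filter.** Hand-motion analysis conventionally
smooths raw streams with a fourth-order two-way (forward-backward)
low-pass Butterworth filter, here with a 6 Hz cutoff: voluntary and
corrective hand movement lives below ~6 Hz, sensor noise above it. A
two-way pass has zero phase lag
and the *squared* Butterworth magnitude,
$G(f) = 1/(1 + (f/f_c)^{2n})$ with $n = 4$. `lapskill` realizes exactly
that response spectrally: the series is padded by odd reflection
($3(n+1)$ samples per end, the classic forward-backward pad), multiplied
in the Fourier domain by $G(f)$, and transformed back. The conventional
recursive implementation (bilinear-transform design run forward and
backward) warps the response near the Nyquist rate — at $f_s = 20$ Hz and
$f_c = 6$ Hz the warping is severe (a recursive two-way filter passes only
~0.2% at 8 Hz where the nominal response passes 9.1%) — so the spectral
route is used to honour the nominal response. DC gain is exactly 1, and
the 8 Hz two-way gain is $1/(1 + (8/6)^8) = 0.091$.

**Resampling.** All channels are interpolated onto a grid with step
exactly 0.05 s starting at the latest common start time and truncated to
the last common timestamp — never extrapolated. Positions and voltages are
interpolated linearly; quaternions are sign-aligned to the same
hemisphere, filtered component-wise, renormalized, and slerped onto the
grid.

**Orientation.** Euler angles use the intrinsic Z-Y-X convention
(azimuth, elevation, roll), matching electromagnetic-tracker vocabulary,
and are unwrapped over time before differencing so that path lengths and
angular rates are continuous. Proximity to gimbal lock
(|elevation| > 85 degrees) is warned about; the simulator keeps elevations well
clear of it, and real laparoscopic instruments rarely point straight up.

**Visibility.** A tip is visible when, expressed in the scope-sensor
frame, it lies in the forward half-space of the cone apex and within the
half-angle of the axis. There is no far limit (none is physically
implied), and a tip exactly at the apex is counted not visible since its
direction is undefined.

## The feature set

The 280 MAFs split 5 / 8 / 20 / 247 across trial time, tip visibility,
grip and tip motion, and each sensor-subset model draws on the categories
of its sensors: T (5), TG (25), TM (252), TMV (260), TMG (272),
TMVG (280). The tip-motion block is generated from templates — per-tool
path lengths per axis and total, bounding-box diagonal, per-axis angular
path lengths, average and instantaneous velocity/acceleration statistics
(max, min, range, standard deviation), magnitude peak-count rates at fixed
thresholds, and needle/maryland ratios. The template expansion is
version-locked in `maf_manifest()`: models refer to features by manifest
name, and the ordering is part of the file format.

Numerical conventions, chosen once and documented:

* Peak counting: an interior sample that strictly exceeds its predecessor,
  is at least its successor, and is at or above threshold; thresholds as
  catalogued (e.g. linear velocity 2/5/10/100 cm/s, angular acceleration
  50/100/1000/10000 degrees/s^2); counts are divided by trial time.
* "Time at zero velocity" on a noisy derivative uses a dead band:
  |v| <= 1 degree/s (velocity) and |a| <= 10 degrees/s^2 (acceleration) count as zero.
  Both are configurable package constants.
* Tool ratios are needle/maryland; a denominator below 1e-9 in magnitude
  yields 0 rather than an infinity, because downstream standardization
  requires finite values everywhere.
* Time in view and out of view are computed as duration times the visible
  fraction, so they sum to the trial duration exactly.

## Modelling and evaluation

Features are standardized (training mean/SD; zero-variance features
dropped), then the elastic net selects predictors against the summed
score. The mixing parameter is searched over {0.5, 0.7, 0.9, 0.95, 1.0}
jointly with the penalty strength by inner 5-fold cross-validation
(minimum mean-squared error); the grid spans lasso-like selection while
retaining enough ridge behaviour to keep groups of correlated MAFs
together. On the selected features one cost-complexity-pruned regression
tree is grown per OSATS domain (minimum leaf size 3, pruning at the
cross-validated error minimum) and the summed prediction is the sum of the
five tree outputs, rounded and clipped to [5, 25]; a single summed-score
tree is available as an alternative mode. Selection against the summed
score (rather than per-domain selection) is the default because a single
selection step is what the evaluation design calls for; per-domain trees
then let each domain weight those features differently. If the elastic
net selects nothing, the model honestly predicts the training median.

Evaluation is leave-one-subject-out: one fold per subject (sorted subject
ids), with standardization, selection and tree fitting repeated inside
every fold so no information from the held-out subject leaks into its own
predictions — a property the test suite asserts directly by perturbing
held-out labels. Reported metrics are within-2 and within-4 accuracy and
Pearson r on the summed scale, exact and within-1 accuracy and Pearson r
on the rounded-average scale, and a 5x5 confusion matrix of rounded
averages (the scale runs to 5 even when no observed trial reaches it).
Correlation against a constant prediction is undefined and reported as
NaN, as for the median baseline. The random baseline guesses summed
scores uniformly on 5-20, the observed score range.

## The synthetic cohort

No recordings are distributed with the package, so every stage is
validated against a simulator whose defaults describe one fixed study
condition (32 subjects — 6 students, 21 residents, 5 fellows — with two
trials each):

* **Trajectories** are minimum-jerk sub-movements between uniform random
  via-points in a 14 x 19 x 7 cm workspace — the motor-control standard for
  smooth aimed movement. Skill $s \in [1, 5]$ modulates exactly the
  quantities the features measure: trial duration
  $T(s) = 480\,e^{-0.45(s-1)}$ s (capped at 600 s), mean sub-movement
  duration $1.0 + 0.15s$ s, and motion irregularity with amplitude
  $0.02(5-s)$ cm per frequency component.
* **Irregularity sits in the 2-5 Hz band** rather than the 8-12 Hz
  physiological tremor band, deliberately: the analysis pipeline's own
  6 Hz filter would remove true tremor, and what the features measure is
  the sub-cutoff roughness of unskilled motion. A consequence worth
  knowing: peak-rate features at *low* thresholds (e.g. linear
  acceleration >= 10 cm/s^2) count ordinary sub-movement accelerations and
  saturate at every skill level, while the higher thresholds
  (>= 100 cm/s^2) isolate the roughness signal and decrease monotonically
  with skill — the property tests use those.
* **Sensor model:** positions quantized to 0.14 cm and orientations to
  0.5 degrees (the tracker's stated resolutions), sampling intervals jittered
  uniformly by +-10% around 50 ms, plus 0.03 cm white measurement noise.
* **Out-of-view episodes** displace the needle tip outside the viewing
  cone at rate $0.005(5-s)$ per second for 2-5 s at a time; **grip
  events** (open-close pulses through the inverse calibration map, with
  faster ramps at low skill) occur at $0.2 + 0.1(5-s)$ per second.
* **Rater:** each domain is $\mathrm{clip}(\mathrm{round}(s + \eta + \epsilon_d), 1, 5)$
  with shared and domain noise each
  $\mathcal N(0, \sigma/\sqrt 2)$, $\sigma = 0.4$ by default — domains
  from one rater are positively correlated, and the per-domain noise SD
  stays interpretable. Latent skills are drawn per level
  (students $\mathcal N(1.4, 0.4)$, residents $\mathcal N(2.95, 0.5)$,
  fellows $\mathcal N(3.7, 0.4)$, clipped to [1, 5]) to target observed
  level means near 1.3 / 2.9 / 3.6, and a per-subject learning gain
  $0.05 + 0.35\,e^{-(s-2.5)^2/2}$ (largest for mid-skill subjects) is
  added on the repeat trial.

What the simulator does **not** model: suturing task structure (needle
passes, knot ties), tissue contact forces, occlusion of one instrument by
the other, metallic field distortion, or rater drift. Passing the
end-to-end recovery test therefore shows that the pipeline's machinery —
calibration, filtering, feature extraction, selection, trees, LOSO
bookkeeping — recovers a skill signal that is present in the kinematics;
it does not show that real suturing skill expresses itself through these
features, which is an empirical property of real recordings.

## Problem sizes and tolerances

The package's own validation uses the default cohort (64 trials) with
leave-one-subject-out evaluation repeated over five seeds, pivot and cone
calibrations with 200 and 80 samples, and a 10,000-point visibility check
against a brute-force oracle. Noise-free geometric recoveries are asserted
to 1e-9 (pivot) and 1e-6 (cone); noisy recoveries at the sensor's 0.14 cm
resolution to 0.1 cm and 1 degree; filter closed forms to 0.01 in gain; the
end-to-end LOSO Pearson r to at least 0.75 on average. Optimization uses
deterministic initialization everywhere; the only stochastic components
are the simulator and cross-validation fold assignment, and both take
explicit seeds.

## Known limitations

* The 247-item tip-motion expansion is one defensible reading of the
  published feature templates; the manifest is version-locked so results
  are comparable across package versions, but other expansions with the
  same totals exist.
* The spectral zero-phase filter treats the padded series as periodic;
  the odd-reflection pad suppresses edge transients, but the first and
  last ~0.75 s of a trial are still the least trustworthy samples, as
  with any two-way filter.
* Elastic-net selection is performed once against the summed score;
  per-domain selection is a plausible alternative that would multiply the
  selection variance on 60-trial training sets.
* With ~2 trials per subject, LOSO metrics on 64 trials have wide
  sampling variability; single-seed comparisons between sensor subsets
  are not meaningful, which is why the recovery property averages seeds.
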