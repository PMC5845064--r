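# lapskill

Automatic rating of laparoscopic surgical skill from instrumented
box-trainer recordings.

Trainees practising intracorporeal suturing are conventionally scored by
an expert who watches the video and assigns five OSATS domain ratings
(Respect for Tissue, Time and Motion, Instrument Handling, Flow of
Operation, Knowledge of Specific Procedure; 1–5 each, summed to 5–25).
`lapskill` replaces the expert with sensors: 6-DOF electromagnetic pose
streams for the two instruments and the endoscope (~20 Hz, positions in
cm, orientations as unit quaternions) plus a flex-sensor voltage per
instrument handle. The package implements the full chain:

1. **Calibration** — pivot (sphere-fit) estimation of each tool-tip
   offset, solved as the linear system
   `pos_i + R_i·offset = tip` jointly over `(offset, tip)`;
   piecewise-linear grip voltage→angle maps from timed hold postures; and
   a least-squares cone (apex, axis, half-angle) for the endoscope's
   field of view.
2. **Kinematics** — zero-phase fourth-order low-pass Butterworth
   filtering (6 Hz cutoff, two-way gain `1/(1+(f/f_c)^8)`), resampling to
   exactly 20 Hz, tip transform, Z–Y–X Euler extraction with unwrapping,
   derivatives, grip-angle series, and per-sample tip visibility inside
   the viewing cone.
3. **Features** — a version-locked manifest of 280 motion-analysis
   features (5 trial-time, 8 visibility, 20 grip, 247 tip-motion: path
   lengths, velocity/acceleration statistics, peak-count rates,
   needle/maryland ratios).
4. **Modelling** — feature standardization, elastic-net selection against
   the summed OSATS score (`glmnet`, mixing and penalty chosen by inner
   5-fold CV), one pruned regression tree per OSATS domain (`rpart`),
   summed predictions clipped to [5, 25], and leave-one-subject-out
   (LOSO) evaluation with random/median baselines and six metrics
   (±2/±4 accuracy and Pearson r on summed scores; exact/±1 accuracy and
   Pearson r on rounded averages).
5. **Synthetic cohort** — a skill-graded simulator (minimum-jerk
   sub-movements, sensor quantization, out-of-view episodes, grip events,
   noisy rater) so the whole pipeline is testable without recordings.

## Worked example

Simulate the default cohort (32 subjects — 6 students, 21 residents,
5 fellows — two trials each), extract features, and evaluate the
all-sensors model with LOSO cross-validation:

```r
library(lapskill)

co    <- simulate_cohort(seed = 11)
kins  <- lapply(co$trials, trial_kinematics, cal = co$calibration)
feats <- extract_maf_table(kins)
feats <- feats[match(co$ratings$trial_id, feats$trial_id), ]

ev <- loso_evaluate(feats, co$ratings[, osats_domain_names()],
                    co$ratings$subject_id, subset = "TMVG", seed = 11)
ev
#> <skill_eval> subset TMVG, 32 LOSO folds
#> acc_within2_summed acc_within4_summed           r_summed      acc_exact_avg
#>              0.766              0.969              0.851              0.688
#>    acc_within1_avg              r_avg
#>              1.000              0.763
```

Reading the numbers: 77% of held-out trials are predicted within ±2
points of the rated summed OSATS score and 97% within ±4; the Pearson
correlation between predicted and rated summed scores is 0.85. On the
coarser rounded-average scale, 69% of trials get exactly the rated score
and all are within one point. `summary(ev)` adds the confusion matrix and
the mean number of selected features per category; `plot(ev)` shows
predicted versus rated scores.

Individual stages are exported: `fit_tip_offset()`, `fit_grip_map()`,
`fit_camera_cone()`, `lowpass_zero_phase()`, `trial_kinematics()`,
`extract_mafs()`, `skill_model()` / `predict()`, `baseline_predict()`,
`skill_metrics()`. Trials are stored one per CSV (long format, channels
`maryland_pose`, `needle_pose`, `scope_pose`, `maryland_grip`,
`needle_grip`) with a JSON metadata sidecar; `read_trial()`,
`write_trial()` and `validate_trial()` handle them. A thin command-line
wrapper lives at `inst/cli/lapskill.R`
(`simulate | validate | manifest | evaluate`).

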