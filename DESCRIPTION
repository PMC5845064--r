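Package: lapskill
Title: Automatic Surgical Skill Rating from Instrumented Laparoscopic Trainer Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for objective assessment of laparoscopic suturing skill
    from instrument and endoscope pose streams and handle grip-sensor voltages.
    Covers pivot (sphere-fit) tool-tip calibration, grip voltage-to-angle
    mapping, endoscope field-of-view cone fitting, zero-phase low-pass
    filtering and uniform 20 Hz resampling of the raw streams, extraction of
    280 named motion-analysis features (trial time, tool-tip path and
    velocity/acceleration statistics, tip visibility, grip dynamics), and
    OSATS score prediction by elastic-net feature selection with regression
    trees, evaluated by leave-one-subject-out cross-validation against random
    and median baselines. Includes a skill-graded synthetic cohort simulator
    producing minimum-jerk instrument trajectories with sensor noise and a
    noisy simulated rater, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Depends: R (>= 4.1)
Imports:
    glmnet,
    graphics,
    jsonlite,
    rpart,
    stats,
    utils
Encoding: UTF-8
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
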