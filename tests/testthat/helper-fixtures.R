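# Shared fixtures, built in code.

# deterministic uniform-rate trial: n samples per channel at exactly 20 Hz,
# smooth sinusoidal motion, no RNG
make_uniform_trial <- function(n = 1200, rate = 20) {
  tt <- (seq_len(n) - 1) / rate
  pose <- function(cx, cy, cz) {
    az <- 20 * sin(2 * pi * 0.05 * tt)
    el <- -30 + 10 * sin(2 * pi * 0.07 * tt)
    ro <- 15 * sin(2 * pi * 0.04 * tt)
    q <- lapskill:::euler_to_quat(az, el, ro)
    data.frame(t = tt,
               x = cx + 2 * sin(2 * pi * 0.1 * tt),
               y = cy + 3 * sin(2 * pi * 0.08 * tt),
               z = cz + 1 * sin(2 * pi * 0.06 * tt),
               qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4])
  }
  grip <- function(base) data.frame(
    t = tt, voltage = base + 0.2 * sin(2 * pi * 0.1 * tt))
  trial_recording(
    streams = list(maryland_pose = pose(-3, 0, 3),
                   needle_pose = pose(3, 0, 3),
                   scope_pose = pose(0, -16, 12)),
    grip = list(maryland = grip(1.5), needle = grip(1.5)),
    subject_id = "FIX", trial_index = 1L)
}

# hand-built kinematics object for closed-form feature checks
make_kin <- function(t, tip_m, tip_n, euler_m = NULL, euler_n = NULL,
                     grip = NULL, visible_m = NULL, visible_n = NULL) {
  n <- length(t)
  zero3 <- matrix(0, n, 3, dimnames = list(NULL, c("azimuth", "elevation", "roll")))
  if (is.null(euler_m)) euler_m <- zero3
  if (is.null(euler_n)) euler_n <- zero3
  if (is.null(grip)) grip <- rep(5, n)
  if (is.null(visible_m)) visible_m <- rep(TRUE, n)
  if (is.null(visible_n)) visible_n <- rep(TRUE, n)
  mk <- function(tip, eul, vis) {
    dl <- derivatives(tip); da <- derivatives(eul); dg <- derivatives(grip)
    list(tip_pos = tip, euler = eul, lin_vel = dl$d1, lin_acc = dl$d2,
         ang_vel = da$d1, ang_acc = da$d2, grip_angle = grip,
         grip_vel = dg$d1, grip_acc = dg$d2, visible = vis)
  }
  structure(list(t = t, duration = t[n] - t[1],
                 tools = list(maryland = mk(tip_m, euler_m, visible_m),
                              needle = mk(tip_n, euler_n, visible_n))),
            class = "trial_kinematics")
}

stationary_kin <- function(duration = 60, step = 0.05) {
  t <- seq(0, duration, by = step)
  p <- matrix(rep(c(0, 0, 3), each = length(t)), ncol = 3)
  make_kin(t, p, p)
}

# random feature table with all 280 manifest columns (for modelling tests)
random_feature_table <- function(n, seed = 1) {
  set.seed(seed)
  man <- maf_manifest()
  X <- matrix(rnorm(n * nrow(man)), n, nrow(man),
              dimnames = list(NULL, man$name))
  as.data.frame(X)
}

# domain-score data.frame from a vector of latent skills (noise-free)
domains_from_skill <- function(s) {
  d <- vapply(osats_domain_names(), function(nm)
    pmin(pmax(round(s), 1), 5), numeric(length(s)))
  as.data.frame(d)
}

skill_eval_cache <- new.env(parent = emptyenv())

# one shared small cohort, processed once per test run
small_cohort_features <- function(seed = 42) {
  key <- paste0("co", seed)
  if (!is.null(skill_eval_cache[[key]])) return(skill_eval_cache[[key]])
  co <- simulate_cohort(n_subjects = 8, trials_each = 2,
                        levels = c(student = 3, resident = 3, fellow = 2),
                        seed = seed)
  kins <- lapply(co$trials, trial_kinematics, cal = co$calibration)
  feats <- extract_maf_table(kins)
  feats <- feats[match(co$ratings$trial_id, feats$trial_id), ]
  out <- list(cohort = co, features = feats)
  skill_eval_cache[[key]] <- out
  out
}
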