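# Skill-graded synthetic cohort simulator.
#
# Stands in for study recordings: minimum-jerk sub-movement trajectories in
# a 14 x 19 x 7 cm trainer workspace, low-frequency motion irregularity and
# sensor quantization noise, skill-dependent trial duration, out-of-view
# episodes, abrupt grip events, and a noisy simulated rater. Deterministic
# given a seed.

#' Generator configuration
#'
#' All values are package choices emulating the acquisition setup (sensor
#' resolution 0.14 cm / 0.5 deg, ~20 Hz jittered sampling, 600 s trial cap);
#' every rate scales with (5 - s) so lower skill s produces longer, rougher,
#' less economical motion.
#'
#' @param base_duration duration at s = 1, seconds.
#' @param duration_decay exponential decay of duration per skill point.
#' @param max_duration trial cap, seconds.
#' @param seg_mean_base,seg_mean_slope mean sub-movement duration =
#'   base + slope * s, seconds.
#' @param irregularity_amp motion-irregularity amplitude per unit (5 - s),
#'   cm (placed in the 2-5 Hz band, below the 6 Hz analysis cutoff).
#' @param ang_irregularity_amp angular counterpart, degrees per unit (5-s).
#' @param pos_quantum,ang_quantum sensor quantization, cm and degrees.
#' @param rate_jitter relative sampling-interval jitter (uniform).
#' @param outview_rate out-of-view episode rate per second per unit (5-s)
#'   (needle tool).
#' @param grip_rate_base,grip_rate_slope grip event rate = base +
#'   slope * (5 - s), events/s.
#' @param rater_sigma per-domain rater noise standard deviation.
#' @return list of generator parameters.
#' @export
generator_config <- function(base_duration = 480, duration_decay = 0.45,
                             max_duration = 600,
                             seg_mean_base = 1.0, seg_mean_slope = 0.15,
                             irregularity_amp = 0.02,
                             ang_irregularity_amp = 0.3,
                             pos_quantum = 0.14, ang_quantum = 0.5,
                             rate_jitter = 0.1,
                             outview_rate = 0.005,
                             grip_rate_base = 0.2, grip_rate_slope = 0.1,
                             rater_sigma = 0.4) {
  as.list(environment())
}

#' The simulator's ground-truth calibration set
#'
#' Tip offsets of (0, 0, -2.5) cm (sensor mounted 2.5 cm up the shaft),
#' grip anchors at the default handle angles, and a 35-degree half-angle
#' viewing cone with apex at the scope sensor.
#'
#' @return a [calibration_set()].
#' @export
default_calibration <- function() {
  tip <- lapply(TOOLS, function(tool)
    structure(list(offset = c(0, 0, -2.5), tip_world = c(0, 0, 0),
                   rms_residual = 0), class = "tip_calibration"))
  names(tip) <- TOOLS
  grip <- list(
    maryland = structure(list(
      anchors = data.frame(voltage = c(1.0, 2.0), angle = c(30, 0)),
      postures = c("open", "closed")), class = "grip_calibration"),
    needle = structure(list(
      anchors = data.frame(voltage = c(1.0, 1.8, 2.0), angle = c(30, 3, 0)),
      postures = c("open", "closed_unratcheted", "ratcheted")),
      class = "grip_calibration"))
  cam <- structure(list(apex = c(0, 0, 0.5), axis = c(0, 0, 1),
                        half_angle = 35, rms_residual_deg = 0),
                   class = "camera_cone")
  calibration_set(tip, grip, cam)
}

# workspace of the trainer insert, cm (world frame, z up)
WORKSPACE <- list(lo = c(-7, -9.5, 0), hi = c(7, 9.5, 7))
SCOPE_POS <- c(0, -16, 12)

# minimum-jerk position profile on tau in [0, 1]
minjerk <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)

# piecewise minimum-jerk interpolation through via-points
# via_t: K+1 times, via: (K+1) x d matrix -> n x d at times t
mj_interp <- function(t, via_t, via) {
  seg <- pmin(pmax(findInterval(t, via_t, rightmost.closed = TRUE), 1L),
              length(via_t) - 1L)
  tau <- (t - via_t[seg]) / (via_t[seg + 1L] - via_t[seg])
  w <- minjerk(pmin(pmax(tau, 0), 1))
  via[seg, , drop = FALSE] +
    (via[seg + 1L, , drop = FALSE] - via[seg, , drop = FALSE]) * w
}

# band-limited irregularity: fixed sub-cutoff frequencies, random phases
irregularity <- function(t, amp, ncomp = 3) {
  freqs <- c(2.7, 3.8, 4.9)[seq_len(ncomp)]
  ph <- stats::runif(ncomp, 0, 2 * pi)
  rowSums(vapply(seq_len(ncomp),
                 function(i) sin(2 * pi * freqs[i] * t + ph[i]),
                 numeric(length(t)))) * amp / sqrt(ncomp)
}

jittered_times <- function(duration, jitter) {
  n <- ceiling(duration / 0.05) + 10L
  dt <- 0.05 * (1 + stats::runif(n, -jitter, jitter))
  tt <- c(0, cumsum(dt))
  tt[tt <= duration]
}

quantize <- function(x, q) round(x / q) * q

#' Simulate the rater's OSATS scores for a latent skill
#'
#' Each domain score is clip(round(s + shared + own), 1, 5), where the
#' shared and per-domain noise components are each Normal(0, sigma/sqrt(2)),
#' so a single domain has total noise s.d. sigma and domains are positively
#' correlated, as scores from one human rater are.
#'
#' @param s latent skill in [1, 5].
#' @param sigma total per-domain noise s.d.
#' @param seed integer seed.
#' @return an [osats_rating()].
#' @export
simulate_rater <- function(s, sigma = 0.4, seed = 1L) {
  stopifnot(sigma >= 0)
  set.seed(seed)
  shared <- stats::rnorm(1, 0, sigma / sqrt(2))
  eps <- shared + stats::rnorm(5, 0, sigma / sqrt(2))
  osats_rating(pmin(pmax(round(s + eps), 1), 5))
}

#' Simulate one trial recording
#'
#' Builds tip trajectories from minimum-jerk sub-movements between random
#' via-points in the trainer workspace, orientation trajectories through
#' random Euler via-points, grip-angle event trains pushed through the
#' inverse calibration map, and a slowly wobbling endoscope; adds
#' skill-scaled motion irregularity, quantization and sampling jitter;
#' inserts out-of-view excursions of the needle tool at a skill-scaled rate.
#'
#' @param s latent skill in [1, 5] (lower = longer, rougher trials).
#' @param config [generator_config()].
#' @param seed integer seed; the recording is bit-identical for equal
#'   (s, config, seed).
#' @param subject_id,trial_index metadata passed through to the recording.
#' @return a [trial_recording()] whose `meta$rating` holds the simulated
#'   ground-truth [osats_rating()].
#' @export
simulate_trial <- function(s, config = generator_config(), seed = 1L,
                           subject_id = "sim", trial_index = 1L) {
  stopifnot(s >= 1, s <= 5)
  set.seed(seed)
  cal <- default_calibration()
  dur <- min(config$max_duration,
             config$base_duration * exp(-config$duration_decay * (s - 1)) *
               exp(stats::rnorm(1, 0, 0.1)))
  dur <- max(dur, 30)
  rough <- 5 - s
  completed <- dur < config$max_duration

  make_tool_stream <- function(tool) {
    tt <- jittered_times(dur, config$rate_jitter)
    seg_mean <- config$seg_mean_base + config$seg_mean_slope * s
    K <- max(2L, round(dur / seg_mean))
    seg_w <- stats::rlnorm(K, 0, 0.4)
    via_t <- c(0, cumsum(seg_w)) / sum(seg_w) * dur
    lo <- WORKSPACE$lo; hi <- WORKSPACE$hi
    via <- cbind(stats::runif(K + 1, lo[1], hi[1]),
                 stats::runif(K + 1, lo[2], hi[2]),
                 stats::runif(K + 1, lo[3], hi[3]))
    # keep each tool biased to its own side of the midline
    via[, 1] <- via[, 1] / 2 + ifelse(tool == "maryland", -3.5, 3.5)
    tip <- mj_interp(tt, via_t, via)
    for (j in 1:3)
      tip[, j] <- tip[, j] + irregularity(tt, config$irregularity_amp * rough)
    # out-of-view excursions (dominant-hand tool leaves the cone)
    if (tool == "needle") {
      n_ep <- stats::rpois(1, config$outview_rate * rough * dur)
      if (n_ep > 0) {
        for (ep in seq_len(n_ep)) {
          t0 <- stats::runif(1, 0, max(dur - 6, 1))
          len <- stats::runif(1, 2, 5)
          ramp <- 0.6
          w <- rep(0, length(tt))
          rising <- tt >= t0 & tt < t0 + ramp
          hold <- tt >= t0 + ramp & tt < t0 + len - ramp
          falling <- tt >= t0 + len - ramp & tt < t0 + len
          w[rising] <- minjerk((tt[rising] - t0) / ramp)
          w[hold] <- 1
          w[falling] <- 1 - minjerk((tt[falling] - (t0 + len - ramp)) / ramp)
          excursion <- c(10, -14, -2)
          tip <- tip + outer(w, excursion)
        }
      }
    }
    # orientation: Euler via-points (tool points downward; away from gimbal lock)
    evia <- cbind(stats::runif(K + 1, -40, 40),     # azimuth
                  stats::runif(K + 1, -50, -10),    # elevation
                  stats::runif(K + 1, -60, 60))     # roll
    eul <- mj_interp(tt, via_t, evia)
    for (j in 1:3)
      eul[, j] <- eul[, j] + irregularity(tt, config$ang_irregularity_amp * rough)
    eul <- quantize(eul, config$ang_quantum)
    q <- euler_to_quat(eul[, 1], eul[, 2], eul[, 3])
    # sensor sits up the shaft: pos = tip - R q . offset
    pos <- tip - quat_rotate(q, cal$tip[[tool]]$offset)
    pos <- quantize(pos + matrix(stats::rnorm(length(pos), 0, 0.03),
                                 ncol = 3), config$pos_quantum)
    data.frame(t = tt, x = pos[, 1], y = pos[, 2], z = pos[, 3],
               qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4])
  }

  make_scope_stream <- function() {
    tt <- jittered_times(dur, config$rate_jitter)
    target <- c(0, 0, 3.5)
    d <- target - SCOPE_POS; d <- d / sqrt(sum(d^2))
    ax <- c(-d[2], d[1], 0)    # rotation axis taking +z to d
    ax <- ax / sqrt(sum(ax^2))
    ang <- acos(d[3])
    base_q <- c(cos(ang / 2), sin(ang / 2) * ax)
    wob <- 1.5 * sin(2 * pi * 0.02 * tt + stats::runif(1, 0, 2 * pi))
    qw <- cos(wob * pi / 360); qs <- sin(wob * pi / 360)
    # compose base with a small rotation about the scope x-axis
    q <- cbind(qw * base_q[1] - qs * base_q[2],
               qw * base_q[2] + qs * base_q[1],
               qw * base_q[3] - qs * base_q[4],
               qw * base_q[4] + qs * base_q[3])
    ph <- stats::runif(3, 0, 2 * pi)
    pos <- cbind(SCOPE_POS[1] + 0.3 * sin(2 * pi * 0.015 * tt + ph[1]),
                 SCOPE_POS[2] + 0.3 * sin(2 * pi * 0.012 * tt + ph[2]),
                 SCOPE_POS[3] + 0.2 * sin(2 * pi * 0.010 * tt + ph[3]))
    pos <- quantize(pos, config$pos_quantum)
    data.frame(t = tt, x = pos[, 1], y = pos[, 2], z = pos[, 3],
               qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4])
  }

  make_grip_stream <- function(tool) {
    tt <- jittered_times(dur, config$rate_jitter)
    baseline <- if (tool == "maryland") 5 else 3
    ang <- rep(baseline, length(tt))
    n_ev <- stats::rpois(1, (config$grip_rate_base +
                               config$grip_rate_slope * rough) * dur)
    ramp <- pmax(0.12 + 0.05 * s + stats::rnorm(max(n_ev, 1), 0, 0.02), 0.08)
    for (ev in seq_len(n_ev)) {
      t0 <- stats::runif(1, 0, max(dur - 2, 1))
      amp <- stats::runif(1, 12, 25)
      hold <- stats::runif(1, 0.1, 0.4)
      r <- ramp[ev]
      up <- tt >= t0 & tt < t0 + r
      flat <- tt >= t0 + r & tt < t0 + r + hold
      down <- tt >= t0 + r + hold & tt < t0 + 2 * r + hold
      ang[up] <- pmax(ang[up], baseline + amp * minjerk((tt[up] - t0) / r))
      ang[flat] <- pmax(ang[flat], baseline + amp)
      ang[down] <- pmax(ang[down], baseline +
                          amp * (1 - minjerk((tt[down] - (t0 + r + hold)) / r)))
    }
    ang <- pmin(ang, 30)
    volt <- grip_voltage(cal$grip[[tool]], ang) +
      stats::rnorm(length(tt), 0, 0.005)
    data.frame(t = tt, voltage = volt)
  }

  streams <- list(maryland_pose = make_tool_stream("maryland"),
                  needle_pose = make_tool_stream("needle"),
                  scope_pose = make_scope_stream())
  grip <- list(maryland = make_grip_stream("maryland"),
               needle = make_grip_stream("needle"))
  rating <- simulate_rater(s, config$rater_sigma,
                           seed = (seed * 131 + 17) %% 2147483629L)
  trial_recording(streams, grip, subject_id, trial_index,
                  rate_hz = 20, completed = completed, rating = rating,
                  seed = seed)
}

#' Simulate a full training cohort
#'
#' Draws one latent skill per subject by training level (students low,
#' fellows high), applies a per-subject learning gain to the repeat trial,
#' simulates every trial and its rating, and optionally writes all
#' artifacts (trial CSVs, ratings CSV, calibration JSON) through the
#' package's own writers.
#'
#' @param n_subjects number of subjects.
#' @param trials_each trials per subject.
#' @param levels named integer vector partitioning the subjects among
#'   student/resident/fellow (must sum to `n_subjects`).
#' @param config [generator_config()].
#' @param seed integer master seed.
#' @param out_dir optional directory to write trial files into.
#' @return list of class `sim_cohort`: `trials` (named list of recordings),
#'   `ratings` (data.frame with trial_id, subject_id, trial_index, level,
#'   latent skill, the five domain scores, summed, rounded_avg),
#'   `calibration`.
#' @export
simulate_cohort <- function(n_subjects = 32, trials_each = 2,
                            levels = c(student = 6, resident = 21, fellow = 5),
                            config = generator_config(), seed = 1L,
                            out_dir = NULL) {
  stopifnot(sum(levels) == n_subjects, all(levels >= 0))
  set.seed(seed)
  level <- rep(names(levels), levels)
  skill_mean <- c(student = 1.4, resident = 2.95, fellow = 3.7)
  skill_sd <- c(student = 0.4, resident = 0.5, fellow = 0.4)
  s0 <- pmin(pmax(stats::rnorm(n_subjects, skill_mean[level],
                               skill_sd[level]), 1), 5)
  gain <- 0.05 + 0.35 * exp(-(s0 - 2.5)^2 / 2)   # mid-skill improves most
  trials <- list()
  rows <- list()
  idx <- 0L
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", i)
    for (k in seq_len(trials_each)) {
      idx <- idx + 1L
      s <- min(5, s0[i] + (k - 1) * gain[i])
      tseed <- (seed * 7919 + idx * 104729) %% 2147483629L
      rec <- simulate_trial(s, config, seed = tseed, subject_id = sid,
                            trial_index = k)
      tid <- sprintf("%s_T%d", sid, k)
      trials[[tid]] <- rec
      r <- rec$meta$rating
      rows[[idx]] <- data.frame(
        trial_id = tid, subject_id = sid, trial_index = k,
        level = level[i], latent_skill = s,
        as.list(r$domains), summed = r$summed, rounded_avg = r$rounded_avg)
    }
  }
  ratings <- do.call(rbind, rows)
  out <- structure(list(trials = trials, ratings = ratings,
                        calibration = default_calibration(), seed = seed),
                   class = "sim_cohort")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (tid in names(trials))
      write_trial(trials[[tid]], file.path(out_dir, paste0(tid, ".csv")))
    utils::write.csv(ratings, file.path(out_dir, "ratings.csv"),
                     row.names = FALSE)
    write_calibration(out$calibration, file.path(out_dir, "calibration.json"))
  }
  out
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d trials from %d subjects\n",
              nrow(x$ratings), length(unique(x$ratings$subject_id))))
  invisible(x)
}

#' Simulate a pivot-calibration recording
#'
#' Poses of a sensor rotating about a stationary tool tip: random
#' orientations, sensor position = tip - R offset (+ optional noise).
#' Used to exercise [fit_tip_offset()].
#'
#' @param offset true sensor-frame tip offset (cm).
#' @param n number of samples.
#' @param noise_sd position noise s.d. (cm).
#' @param tip_world stationary tip position (cm).
#' @param seed integer seed.
#' @return data.frame with columns x, y, z, qw, qx, qy, qz.
#' @export
simulate_pivot_recording <- function(offset = c(0, 0, -2.5), n = 200,
                                     noise_sd = 0, tip_world = c(5, -3, 2),
                                     seed = 1L) {
  set.seed(seed)
  az <- stats::runif(n, -180, 180)
  el <- stats::runif(n, -70, 70)
  ro <- stats::runif(n, -180, 180)
  q <- euler_to_quat(az, el, ro)
  pos <- -quat_rotate(q, offset) +
    matrix(tip_world, n, 3, byrow = TRUE) +
    matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3)
  data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
             qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4])
}

#' Simulate traced field-of-view boundary points
#'
#' Points on the rim of a cone at given distances from the apex along the
#' axis, with optional isotropic noise; exercises [fit_camera_cone()].
#'
#' @param cone a `camera_cone` (truth).
#' @param distances distances along the axis of the traced circles (cm).
#' @param n_per_circle points per circle.
#' @param noise_sd isotropic noise s.d. (cm).
#' @param seed integer seed.
#' @return matrix n x 3 (scope-sensor frame).
#' @export
simulate_cone_points <- function(cone, distances = c(10, 20),
                                 n_per_circle = 40, noise_sd = 0, seed = 1L) {
  set.seed(seed)
  axis <- cone$axis / sqrt(sum(cone$axis^2))
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  tanh_ <- tan(cone$half_angle * pi / 180)
  P <- do.call(rbind, lapply(distances, function(d) {
    th <- stats::runif(n_per_circle, 0, 2 * pi)
    r <- d * tanh_
    sweep(outer(cos(th) * r, e1) + outer(sin(th) * r, e2) +
            outer(rep(d, n_per_circle), axis), 2, cone$apex, "+")
  }))
  P + matrix(stats::rnorm(length(P), 0, noise_sd), nrow(P), 3)
}

#' Simulate grip-calibration hold segments
#'
#' One noisy constant-voltage segment per posture, 5 s each, for
#' [fit_grip_map()].
#'
#' @param cal a `grip_calibration` (truth, supplies anchor voltages).
#' @param noise_sd voltage noise s.d.
#' @param seed integer seed.
#' @return named list of data.frames (t, voltage), one per posture.
#' @export
simulate_grip_segments <- function(cal, noise_sd = 0.01, seed = 1L) {
  set.seed(seed)
  segs <- lapply(seq_len(nrow(cal$anchors)), function(i) {
    tt <- seq(0, 5, by = 0.05)
    data.frame(t = tt, voltage = cal$anchors$voltage[i] +
                 stats::rnorm(length(tt), 0, noise_sd))
  })
  names(segs) <- cal$postures
  segs
}
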