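test_that("zero-phase filter has unit DC gain and the closed-form rolloff", {
  expect_equal(lowpass_zero_phase(rep(2.7, 100), fs = 20), rep(2.7, 100),
               tolerance = 1e-9)
  tt <- seq(0, 30, by = 0.05)
  pass <- lowpass_zero_phase(sin(2 * pi * 1 * tt), fs = 20)
  core <- 101:500
  expect_gte(max(abs(pass[core])), 0.999)
  stopb <- lowpass_zero_phase(sin(2 * pi * 8 * tt), fs = 20)
  # closed form: two-way gain 1/(1 + (8/6)^8) = 0.0910; amplitude by
  # quadrature projection on the interior (avoids edge effects)
  amp <- 2 * sqrt(mean(stopb[core] * sin(2 * pi * 8 * tt[core]))^2 +
                    mean(stopb[core] * cos(2 * pi * 8 * tt[core]))^2)
  expect_lt(abs(amp - 0.091), 0.01)
  expect_error(lowpass_zero_phase(rnorm(10), fs = 20), "too short")
})

test_that("zero-phase filter introduces no lag", {
  tt <- seq(0, 30, by = 0.05)
  x <- sin(2 * pi * 2 * tt)
  y <- lowpass_zero_phase(x, fs = 20)
  lags <- -5:5
  cc <- vapply(lags, function(l) {
    i <- 51:550
    cor(x[i], y[i + l])
  }, 0)
  expect_identical(lags[which.max(cc)], 0L)
})

test_that("resampling yields an exact 0.05 s grid and is exact on ramps", {
  tt <- seq(0, 10, by = 0.05)
  out <- resample_20hz(tt, sin(tt))
  expect_equal(out$t, tt)
  expect_equal(out$x, sin(tt), tolerance = 1e-12)
  set.seed(1)
  tj <- cumsum(runif(200, 0.03, 0.07))
  tj <- c(0, tj)
  ramp <- 3 + 2 * tj
  out <- resample_20hz(tj, ramp)
  expect_equal(unique(round(diff(out$t), 10)), 0.05)
  expect_equal(out$x, 3 + 2 * out$t, tolerance = 1e-10)
  expect_lte(max(out$t), max(tj))  # no extrapolation ever
})

test_that("tip transform applies the calibrated offset in the sensor frame", {
  pos <- matrix(c(1, 2, 3), 1, 3)
  qid <- matrix(c(1, 0, 0, 0), 1, 4)
  expect_equal(tip_trajectory(pos, qid, NULL)$tip_pos, pos)
  cal <- structure(list(offset = c(0, 0, -2.5)), class = "tip_calibration")
  expect_equal(tip_trajectory(pos, qid, cal)$tip_pos,
               pos + matrix(c(0, 0, -2.5), 1, 3))
  q90 <- lapskill:::euler_to_quat(90, 0, 0)  # 90 deg about world z
  cal2 <- structure(list(offset = c(1, 0, 0)), class = "tip_calibration")
  tp <- tip_trajectory(pos, q90, cal2)$tip_pos
  expect_equal(as.vector(tp - pos), c(0, 1, 0), tolerance = 1e-12)
})

test_that("euler output is unwrapped and round-trips the quaternion", {
  az <- seq(-300, 300, by = 2.5)   # crosses the +-180 wrap
  q <- lapskill:::euler_to_quat(az, -20 + 0 * az, 5 + 0 * az)
  eul <- tip_trajectory(matrix(0, length(az), 3), q, NULL)$euler
  expect_lt(max(abs(diff(eul[, "azimuth"]))), 180)
  expect_equal(diff(eul[, "azimuth"]), rep(2.5, length(az) - 1),
               tolerance = 1e-9)
  expect_equal(eul[, "elevation"], rep(-20, length(az)), tolerance = 1e-9)
  expect_equal(eul[, "roll"], rep(5, length(az)), tolerance = 1e-9)
})

test_that("derivatives are exact on constants, ramps and quadratics", {
  t <- seq(0, 5, by = 0.05)
  d <- derivatives(cbind(0 * t, 0 * t + 4, 0 * t))
  expect_true(all(d$d1 == 0) && all(d$d2 == 0))
  d <- derivatives(cbind(0 * t, 2 * t, 0 * t))
  expect_equal(d$d1[, 2], rep(2, length(t)), tolerance = 1e-12)
  expect_true(all(abs(d$d2) < 1e-9))
  d <- derivatives(t^2)
  interior <- 3:(length(t) - 2)
  expect_equal(d$d2[interior], rep(2, length(interior)), tolerance = 1e-9)
  expect_error(derivatives(1:2), "at least 3")
})

test_that("trapezoid integration of velocity recovers net displacement", {
  rec <- simulate_trial(3, seed = 21)
  kin <- trial_kinematics(rec, default_calibration())
  for (tool in c("maryland", "needle")) {
    k <- kin$tools[[tool]]
    n <- nrow(k$tip_pos)
    for (j in 1:3) {
      net <- k$tip_pos[n, j] - k$tip_pos[1, j]
      integ <- sum((k$lin_vel[-1, j] + k$lin_vel[-n, j]) / 2) * 0.05
      expect_lt(abs(integ - net), max(1e-6, abs(net) * 0.001))
    }
  }
})

test_that("visibility test matches the geometric definition", {
  cone <- structure(list(apex = c(0, 0, 0), axis = c(0, 0, 1),
                         half_angle = 30), class = "camera_cone")
  scope_pos <- matrix(0, 1, 3)
  scope_q <- matrix(c(1, 0, 0, 0), 1, 4)
  on_axis <- matrix(c(0, 0, 5), 1, 3)
  expect_true(visibility_series(on_axis, scope_pos, scope_q, cone))
  off31 <- matrix(c(5 * tan(31 * pi / 180), 0, 5), 1, 3)
  expect_false(visibility_series(off31, scope_pos, scope_q, cone))
  at_apex <- matrix(0, 1, 3)
  expect_false(visibility_series(at_apex, scope_pos, scope_q, cone))
  behind <- matrix(c(0, 0, -5), 1, 3)
  expect_false(visibility_series(behind, scope_pos, scope_q, cone))
})

test_that("visibility agrees with a brute-force point-in-cone oracle", {
  set.seed(99)
  n <- 10000
  cone <- structure(list(apex = c(0.3, -0.2, 0.5), axis = c(0.2, 0.5, 0.84),
                         half_angle = 35), class = "camera_cone")
  cone$axis <- cone$axis / sqrt(sum(cone$axis^2))
  tips <- matrix(runif(3 * n, -20, 20), n, 3)
  scope_pos <- matrix(rep(c(1, -2, 3), n), n, 3, byrow = TRUE)
  scope_q <- matrix(rep(lapskill:::euler_to_quat(25, -35, 10), n), n, 4,
                    byrow = TRUE)
  got <- visibility_series(tips, scope_pos, scope_q, cone)
  # oracle: explicit per-point transform and angle test
  R <- lapskill:::quat_to_rotmat(scope_q[1, ])
  oracle <- vapply(seq_len(n), function(i) {
    local <- as.vector(t(R) %*% (tips[i, ] - scope_pos[i, ]))
    v <- local - cone$apex
    proj <- sum(v * cone$axis)
    if (proj <= 0) return(FALSE)
    ang <- acos(min(max(proj / sqrt(sum(v^2)), -1), 1)) * 180 / pi
    ang <= cone$half_angle
  }, TRUE)
  expect_identical(got, oracle)
})

test_that("kinematics are invariant under a global rigid motion", {
  rec <- simulate_trial(3.5, seed = 31)
  cal <- default_calibration()
  kin <- trial_kinematics(rec, cal)
  qg <- lapskill:::euler_to_quat(60, 25, -40)
  Rg <- lapskill:::quat_to_rotmat(qg)
  shift <- c(12, -7, 4)
  rec2 <- rec
  for (ch in names(rec2$streams)) {
    s <- rec2$streams[[ch]]
    p <- as.matrix(s[, c("x", "y", "z")]) %*% t(Rg)
    s[, c("x", "y", "z")] <- sweep(p, 2, shift, "+")
    s[, c("qw", "qx", "qy", "qz")] <-
      lapskill:::quat_multiply(qg, as.matrix(s[, c("qw", "qx", "qy", "qz")]))
    rec2$streams[[ch]] <- s
  }
  kin2 <- trial_kinematics(rec2, cal)
  f1 <- extract_mafs(kin)
  f2 <- extract_mafs(kin2)
  for (nm in c("path_total_maryland", "path_total_needle",
               "avgspeed_lin_mag_maryland", "avgspeed_lin_mag_needle",
               "ivel_lin_mag_max_needle"))
    expect_equal(f2[[nm]], f1[[nm]], tolerance = 1e-6)
  expect_equal(kin2$tools$needle$visible, kin$tools$needle$visible)
  expect_equal(kin2$tools$maryland$visible, kin$tools$maryland$visible)
})

test_that("grip series tracks the calibrated map and flags transitions", {
  cal <- default_calibration()
  tt <- seq(0, 20, by = 0.05)
  # square wave: 4 transitions between the two anchor voltages
  v <- ifelse(tt %% 10 < 5, 1.2, 1.8)
  transitions <- sum(diff(v) != 0)
  rec <- make_uniform_trial(length(tt))
  rec$grip$maryland <- data.frame(t = tt, voltage = v)
  kin <- trial_kinematics(rec, cal)
  peaks <- count_peaks(abs(kin$tools$maryland$grip_vel), 5)
  expect_identical(peaks, as.integer(transitions))
  # constant voltage at the open anchor -> constant open angle, zero velocity
  rec$grip$maryland <- data.frame(t = tt, voltage = rep(1.0, length(tt)))
  kin <- trial_kinematics(rec, cal)
  expect_equal(kin$tools$maryland$grip_angle,
               rep(30, length(kin$t)), tolerance = 1e-6)
  expect_lt(max(abs(kin$tools$maryland$grip_vel)), 1e-4)
})
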