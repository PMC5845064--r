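# Sensor calibration: pivot (tool-tip offset), grip voltage-to-angle map,
# and endoscope field-of-view cone.

#' Pivot calibration: estimate the tool-tip offset
#'
#' During calibration the tool tip is held stationary while the handle is
#' rotated, so every recorded sensor position lies on a sphere centred on the
#' tip. With tip position `tip_world` and sensor-frame offset `offset`
#' (tip = pos + R(quat) %*% offset), the residuals
#' pos_i + R_i offset - tip_world are linear in (offset, tip_world), and the
#' joint least-squares problem is solved in closed form.
#'
#' @param poses data.frame with columns x, y, z, qw, qx, qy, qz (one row per
#'   sample; at least 30 samples with diverse orientations).
#' @param min_samples minimum number of samples required.
#' @param sv_tol smallest-singular-value tolerance below which the geometry
#'   is declared degenerate (all orientations too similar).
#' @return object of class `tip_calibration`: `offset` (3-vector, cm, sensor
#'   frame), `tip_world` (3-vector, cm), `rms_residual` (cm).
#' @export
fit_tip_offset <- function(poses, min_samples = 30L, sv_tol = 1e-6) {
  n <- nrow(poses)
  if (n < min_samples)
    stop("pivot calibration needs at least ", min_samples, " samples")
  q <- quat_normalize(as.matrix(poses[, c("qw", "qx", "qy", "qz")]))
  p <- as.matrix(poses[, c("x", "y", "z")])
  A <- matrix(0, 3 * n, 6)
  for (i in seq_len(n)) {
    A[(3 * i - 2):(3 * i), 1:3] <- quat_to_rotmat(q[i, ])
    A[(3 * i - 2):(3 * i), 4:6] <- -diag(3)
  }
  b <- -as.vector(t(p))
  sv <- svd(A, nu = 0, nv = 0)$d
  if (sv[length(sv)] / sv[1] < sv_tol)
    stop("degenerate pivot geometry: orientations lack diversity")
  x <- qr.solve(A, b)
  offset <- x[1:3]; tip_world <- x[4:6]
  if (sqrt(sum(offset^2)) >= 10)
    stop("implausible tip offset (>= 10 cm); check calibration recording")
  resid <- matrix(A %*% x - b, ncol = 3, byrow = TRUE)
  structure(list(offset = offset, tip_world = tip_world,
                 rms_residual = sqrt(mean(rowSums(resid^2)))),
            class = "tip_calibration")
}

#' @export
print.tip_calibration <- function(x, ...) {
  cat(sprintf("<tip_calibration> offset (%.3f, %.3f, %.3f) cm, |offset| %.3f cm, rms %.4f cm\n",
              x$offset[1], x$offset[2], x$offset[3],
              sqrt(sum(x$offset^2)), x$rms_residual))
  invisible(x)
}

#' Grip calibration: voltage-to-angle map from hold segments
#'
#' Each anchor posture (e.g. fully open, fully closed, and for the ratcheted
#' needle driver also closed-unratcheted) is held for ~5 s; the anchor
#' voltage is the mean over its segment after trimming the first and last
#' 0.5 s. The map is piecewise-linear between anchors and clipped to the
#' terminal anchor angles outside the calibrated voltage range.
#'
#' @param segments named list, one element per anchor in posture order; each
#'   a data.frame with columns t, voltage covering at least 2 s.
#' @param anchor_angles numeric, the handle angle (degrees) of each posture,
#'   same order and length as `segments`. Defaults:
#'   [grip_anchor_angles()].
#' @param trim seconds trimmed from each end of every segment.
#' @return object of class `grip_calibration` with `anchors`
#'   (data.frame voltage, angle, ordered by voltage) and the posture order.
#' @export
fit_grip_map <- function(segments, anchor_angles, trim = 0.5) {
  stopifnot(length(segments) == length(anchor_angles),
            length(segments) >= 2)
  volts <- vapply(seq_along(segments), function(i) {
    seg <- segments[[i]]
    if (max(seg$t) - min(seg$t) < 2)
      stop("grip calibration segment ", i, " shorter than 2 s")
    keep <- seg$t >= min(seg$t) + trim & seg$t <= max(seg$t) - trim
    mean(seg$voltage[keep])
  }, 0)
  dv <- diff(volts)
  if (any(dv == 0) || length(unique(sign(dv))) != 1)
    stop("anchor voltages not strictly monotone; flex sensor fault?")
  da <- diff(anchor_angles)
  if (any(sign(da[da != 0]) != sign(da[da != 0][1])))
    stop("anchor angles must be monotone across postures")
  ord <- order(volts)
  structure(list(anchors = data.frame(voltage = volts[ord],
                                      angle = anchor_angles[ord]),
                 postures = names(segments)),
            class = "grip_calibration")
}

#' Default handle anchor angles (degrees)
#'
#' The Maryland dissector is calibrated open/closed; the needle driver
#' open / closed-unratcheted / ratcheted. Handle geometry is configuration,
#' not measured, so these defaults are overridable.
#'
#' @param tool "maryland" or "needle".
#' @return named numeric vector of posture angles.
#' @export
grip_anchor_angles <- function(tool = c("maryland", "needle")) {
  switch(match.arg(tool),
         maryland = c(open = 30, closed = 0),
         needle = c(open = 30, closed_unratcheted = 3, ratcheted = 0))
}

#' Apply a grip calibration map
#'
#' Piecewise-linear interpolation between anchors; voltages outside the
#' calibrated range are clipped to the terminal anchor angle and flagged
#' with a warning.
#'
#' @param cal a `grip_calibration`.
#' @param voltage numeric vector, volts.
#' @param warn warn on out-of-range voltages.
#' @return numeric vector of grip angles, degrees.
#' @export
grip_angle <- function(cal, voltage, warn = TRUE) {
  a <- cal$anchors
  oob <- voltage < min(a$voltage) | voltage > max(a$voltage)
  if (warn && any(oob, na.rm = TRUE))
    warning(sum(oob, na.rm = TRUE),
            " voltage sample(s) outside the calibrated range; clipped")
  stats::approx(a$voltage, a$angle, xout = voltage, rule = 2)$y
}

#' Invert a grip calibration map (angle to voltage)
#'
#' Used by the cohort simulator to turn simulated grip-angle trajectories
#' into raw sensor voltages through the same piecewise-linear model.
#'
#' @param cal a `grip_calibration`.
#' @param angle numeric vector, degrees.
#' @return numeric vector of voltages.
#' @export
grip_voltage <- function(cal, angle) {
  a <- cal$anchors[order(cal$anchors$angle), ]
  stats::approx(a$angle, a$voltage, xout = angle, rule = 2, ties = "ordered")$y
}

#' Fit the endoscope field-of-view cone
#'
#' Boundary points traced on the rim of the visible field at two (or more)
#' distances, expressed in the scope-sensor frame, determine a cone
#' (apex, axis, half-angle). Initialization: cluster the points by their
#' projection onto `axis_hint`, fit a plane + in-plane circle per cluster,
#' place the apex on the line through the circle centres by similar
#' triangles, and set half_angle = atan(delta radius / delta centre
#' distance). The fit is then refined by least squares on the angular
#' residuals angle(point - apex, axis) - half_angle.
#'
#' @param boundary_points n x 3 matrix (cm, scope-sensor frame), n >= 6,
#'   from at least two distinct planes transverse to `axis_hint`.
#' @param axis_hint length-3 vector roughly along the viewing axis.
#' @param max_iter refinement iteration cap.
#' @return object of class `camera_cone`: `apex` (cm), `axis` (unit vector),
#'   `half_angle` (degrees in (0, 90)), `rms_residual_deg`.
#' @export
fit_camera_cone <- function(boundary_points, axis_hint, max_iter = 200L) {
  P <- as.matrix(boundary_points)
  stopifnot(ncol(P) == 3, nrow(P) >= 6)
  hint <- axis_hint / sqrt(sum(axis_hint^2))
  proj <- as.vector(P %*% hint)
  if (diff(range(proj)) < 1e-6)
    stop("degenerate cone geometry: all boundary points coplanar")
  # two clusters split at the midpoint of the projection range
  grp <- proj > mean(range(proj))
  if (sum(grp) < 3 || sum(!grp) < 3)
    stop("degenerate cone geometry: need >= 3 points per traced circle")
  circ <- lapply(split.data.frame(P, grp), fit_circle_3d)
  c1 <- circ[[1]]; c2 <- circ[[2]]   # c1 = nearer cluster (grp FALSE first)
  dcen <- c2$center - c1$center
  dist_cc <- sqrt(sum(dcen^2))
  if (dist_cc < 1e-9 || abs(c2$radius - c1$radius) < 1e-12)
    stop("degenerate cone geometry: traced circles coincide")
  axis0 <- dcen / dist_cc
  if (sum(axis0 * hint) < 0) { # orient along the hint
    axis0 <- -axis0
    tmp <- c1; c1 <- c2; c2 <- tmp
    dcen <- -dcen
  }
  # similar triangles: radius grows linearly with distance from the apex
  slope <- (c2$radius - c1$radius) / dist_cc
  apex0 <- c1$center - axis0 * (c1$radius / slope)
  half0 <- atan(slope) * 180 / pi
  if (!is.finite(half0) || half0 <= 0 || half0 >= 90)
    stop("cone fit failure: initial half-angle outside (0, 90) degrees")
  par0 <- c(apex0, axis_to_sph(axis0), half0)
  obj <- function(par) {
    ang <- cone_angles(P, par[1:3], sph_to_axis(par[4:5]))
    sum((ang - par[6])^2)
  }
  fit <- stats::optim(par0, obj, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-14))
  par <- if (fit$value <= obj(par0)) fit$par else par0
  half <- par[6]
  if (half <= 0 || half >= 90)
    stop("cone fit failure: refined half-angle outside (0, 90) degrees")
  structure(list(apex = par[1:3], axis = sph_to_axis(par[4:5]),
                 half_angle = half,
                 rms_residual_deg = sqrt(obj(par) / nrow(P))),
            class = "camera_cone")
}

#' @export
print.camera_cone <- function(x, ...) {
  cat(sprintf("<camera_cone> apex (%.2f, %.2f, %.2f) cm, half-angle %.2f deg, rms %.3f deg\n",
              x$apex[1], x$apex[2], x$apex[3], x$half_angle,
              x$rms_residual_deg))
  invisible(x)
}

# angle (degrees) between each point-minus-apex vector and the axis
cone_angles <- function(P, apex, axis) {
  V <- sweep(P, 2, apex)
  nv <- sqrt(rowSums(V^2))
  cosang <- pmin(pmax((V %*% axis) / pmax(nv, 1e-300), -1), 1)
  acos(as.vector(cosang)) * 180 / pi
}

axis_to_sph <- function(a) c(acos(pmin(pmax(a[3], -1), 1)), atan2(a[2], a[1]))
sph_to_axis <- function(s) c(sin(s[1]) * cos(s[2]), sin(s[1]) * sin(s[2]), cos(s[1]))

# plane fit by PCA, then in-plane circle fit (Kasa) in the plane basis
fit_circle_3d <- function(P) {
  ctr <- colMeans(P)
  Q <- sweep(P, 2, ctr)
  sv <- svd(Q)
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]
  u <- Q %*% e1; v <- Q %*% e2
  A <- cbind(2 * u, 2 * v, 1)
  b <- u^2 + v^2
  sol <- qr.solve(A, b)
  center <- ctr + sol[1] * e1 + sol[2] * e2
  radius <- sqrt(sol[3] + sol[1]^2 + sol[2]^2)
  list(center = as.vector(center), radius = radius)
}

#' Bundle and persist a calibration set
#'
#' @param tip named list (`maryland`, `needle`) of `tip_calibration`.
#' @param grip named list (`maryland`, `needle`) of `grip_calibration`.
#' @param camera a `camera_cone`.
#' @return object of class `calibration_set`.
#' @export
calibration_set <- function(tip, grip, camera) {
  structure(list(tip = tip, grip = grip, camera = camera),
            class = "calibration_set")
}

#' Write a calibration set to JSON
#' @param cal a `calibration_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(cal, path) {
  x <- list(
    tip = lapply(cal$tip, function(tc) list(
      offset = tc$offset, tip_world = tc$tip_world,
      rms_residual = tc$rms_residual)),
    grip = lapply(cal$grip, function(gc) list(
      voltage = gc$anchors$voltage, angle = gc$anchors$angle,
      postures = gc$postures)),
    camera = list(apex = cal$camera$apex, axis = cal$camera$axis,
                  half_angle = cal$camera$half_angle,
                  rms_residual_deg = cal$camera$rms_residual_deg))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration set from JSON
#' @param path JSON path written by [write_calibration()].
#' @return a `calibration_set`.
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tip <- lapply(x$tip, function(tc)
    structure(list(offset = tc$offset, tip_world = tc$tip_world,
                   rms_residual = tc$rms_residual),
              class = "tip_calibration"))
  grip <- lapply(x$grip, function(gc)
    structure(list(anchors = data.frame(voltage = gc$voltage,
                                        angle = gc$angle),
                   postures = gc$postures),
              class = "grip_calibration"))
  cam <- structure(list(apex = x$camera$apex, axis = x$camera$axis,
                        half_angle = x$camera$half_angle,
                        rms_residual_deg = x$camera$rms_residual_deg),
                   class = "camera_cone")
  calibration_set(tip, grip, cam)
}
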