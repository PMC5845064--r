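# Quaternion and Euler-angle helpers.
#
# Convention: quaternions are (w, x, y, z), unit norm, sensor-to-world.
# Euler angles are intrinsic Z-Y-X (azimuth about z, then elevation about y,
# then roll about x), in degrees, matching electromagnetic-tracker vocabulary.

#' Normalize quaternion rows
#'
#' @param q numeric matrix with 4 columns (w, x, y, z) or a length-4 vector.
#' @return matrix of the same shape with unit rows.
#' @keywords internal
quat_normalize <- function(q) {
  q <- rbind_quat(q)
  n <- sqrt(rowSums(q^2))
  if (any(n < 1e-12)) stop("zero-norm quaternion")
  q / n
}

rbind_quat <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  stopifnot(ncol(q) == 4)
  q
}

#' Rotation matrix from a unit quaternion
#'
#' @param q length-4 numeric (w, x, y, z).
#' @return 3x3 rotation matrix mapping sensor-frame vectors to world frame.
#' @keywords internal
quat_to_rotmat <- function(q) {
  q <- as.numeric(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Rotate vectors by quaternion rows
#'
#' Vectorized: row i of `v` is rotated by row i of `q`.
#'
#' @param q n x 4 quaternion matrix (w, x, y, z), unit rows.
#' @param v n x 3 matrix of sensor-frame vectors, or a single length-3 vector
#'   recycled across rows.
#' @return n x 3 matrix of world-frame vectors.
#' @keywords internal
quat_rotate <- function(q, v) {
  q <- rbind_quat(q)
  if (is.null(dim(v))) v <- matrix(v, nrow = nrow(q), ncol = 3, byrow = TRUE)
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  vx <- v[, 1]; vy <- v[, 2]; vz <- v[, 3]
  # t = 2 q_vec x v ; v' = v + w t + q_vec x t
  tx <- 2 * (y * vz - z * vy)
  ty <- 2 * (z * vx - x * vz)
  tz <- 2 * (x * vy - y * vx)
  cbind(
    vx + w * tx + (y * tz - z * ty),
    vy + w * ty + (z * tx - x * tz),
    vz + w * tz + (x * ty - y * tx)
  )
}

#' Quaternion from intrinsic Z-Y-X Euler angles (degrees)
#'
#' @param azimuth,elevation,roll numeric vectors, degrees.
#' @return n x 4 quaternion matrix (w, x, y, z).
#' @keywords internal
euler_to_quat <- function(azimuth, elevation, roll) {
  hz <- azimuth * pi / 360; hy <- elevation * pi / 360; hx <- roll * pi / 360
  cz <- cos(hz); sz <- sin(hz)
  cy <- cos(hy); sy <- sin(hy)
  cx <- cos(hx); sx <- sin(hx)
  # q = qz(azimuth) * qy(elevation) * qx(roll)
  cbind(
    cz * cy * cx + sz * sy * sx,
    cz * cy * sx - sz * sy * cx,
    cz * sy * cx + sz * cy * sx,
    sz * cy * cx - cz * sy * sx
  )
}

#' Z-Y-X Euler angles (degrees) from quaternion rows
#'
#' Returns azimuth, elevation, roll with elevation in [-90, 90]. Near gimbal
#' lock (|elevation| -> 90) azimuth and roll are not separately identifiable;
#' the roll is then set to 0 and folded into azimuth.
#'
#' @param q n x 4 quaternion matrix.
#' @return n x 3 matrix with columns azimuth, elevation, roll (degrees).
#' @keywords internal
quat_to_euler <- function(q) {
  q <- rbind_quat(q)
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  # R = Rz(az) Ry(el) Rx(roll); R31 = -sin(el), R21/R11 -> az, R32/R33 -> roll
  r11 <- 1 - 2 * (y^2 + z^2)
  r21 <- 2 * (x * y + w * z)
  r31 <- 2 * (x * z - w * y)
  r32 <- 2 * (y * z + w * x)
  r33 <- 1 - 2 * (x^2 + y^2)
  s <- pmin(pmax(-r31, -1), 1)
  el <- asin(s)
  az <- atan2(r21, r11)
  roll <- atan2(r32, r33)
  lock <- abs(s) > 1 - 1e-12
  if (any(lock)) {
    # fold the degenerate rotation into azimuth
    az[lock] <- atan2(-2 * (y * z - w * x), 1 - 2 * (x^2 + z^2))[lock] * sign(s[lock])
    roll[lock] <- 0
  }
  cbind(azimuth = az, elevation = el, roll = roll) * 180 / pi
}

#' Align quaternion signs for hemisphere continuity
#'
#' Flips the sign of rows so consecutive quaternions have positive dot
#' product (q and -q encode the same rotation).
#'
#' @param q n x 4 quaternion matrix.
#' @return n x 4 matrix, sign-aligned.
#' @keywords internal
quat_hemisphere_align <- function(q) {
  q <- rbind_quat(q)
  if (nrow(q) < 2) return(q)
  d <- rowSums(q[-1, , drop = FALSE] * q[-nrow(q), , drop = FALSE])
  flips <- cumprod(ifelse(d < 0, -1, 1))
  q[-1, ] <- q[-1, , drop = FALSE] * flips
  q
}

#' Spherical linear interpolation of a quaternion time series
#'
#' Interpolates a sign-aligned unit-quaternion series onto new times. Never
#' extrapolates: `t_out` must lie within the input range.
#'
#' @param t numeric, strictly increasing sample times.
#' @param q n x 4 quaternion matrix at those times.
#' @param t_out numeric, query times within range(t).
#' @return length(t_out) x 4 matrix of unit quaternions.
#' @keywords internal
quat_slerp_series <- function(t, q, t_out) {
  q <- quat_hemisphere_align(quat_normalize(q))
  stopifnot(all(diff(t) > 0), min(t_out) >= t[1], max(t_out) <= t[length(t)])
  idx <- findInterval(t_out, t, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(t) - 1L)
  t0 <- t[idx]; t1 <- t[idx + 1L]
  u <- (t_out - t0) / (t1 - t0)
  q0 <- q[idx, , drop = FALSE]; q1 <- q[idx + 1L, , drop = FALSE]
  d <- pmin(pmax(rowSums(q0 * q1), -1), 1)
  th <- acos(d)
  small <- th < 1e-8
  w0 <- ifelse(small, 1 - u, sin((1 - u) * th) / sin(pmax(th, 1e-300)))
  w1 <- ifelse(small, u, sin(u * th) / sin(pmax(th, 1e-300)))
  quat_normalize(q0 * w0 + q1 * w1)
}

#' Hamilton product of quaternion rows
#'
#' Row-wise q1 * q2; single rows are recycled.
#'
#' @param q1,q2 n x 4 quaternion matrices (w, x, y, z) or length-4 vectors.
#' @return n x 4 matrix.
#' @keywords internal
quat_multiply <- function(q1, q2) {
  q1 <- rbind_quat(q1); q2 <- rbind_quat(q2)
  if (nrow(q1) == 1 && nrow(q2) > 1) q1 <- q1[rep(1, nrow(q2)), ]
  if (nrow(q2) == 1 && nrow(q1) > 1) q2 <- q2[rep(1, nrow(q1)), ]
  w1 <- q1[, 1]; x1 <- q1[, 2]; y1 <- q1[, 3]; z1 <- q1[, 4]
  w2 <- q2[, 1]; x2 <- q2[, 2]; y2 <- q2[, 3]; z2 <- q2[, 4]
  cbind(w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
        w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
        w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
        w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2)
}

#' Unwrap an angle series in degrees
#'
#' Removes jumps larger than 180 degrees between consecutive samples so the
#' series is continuous (suitable for path-length and derivative computation).
#'
#' @param x numeric vector of angles, degrees.
#' @return unwrapped numeric vector.
#' @keywords internal
unwrap_deg <- function(x) {
  if (length(x) < 2) return(x)
  d <- diff(x)
  corr <- -360 * round(d / 360)
  x + c(0, cumsum(corr))
}
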