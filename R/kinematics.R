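# Per-cycle shank kinematics: sensor-frame correction, orientation
# integration and ZUPT-anchored ankle trajectory reconstruction.
#
# The sensor sits at the ankle, so the ankle trajectory is taken as the
# sensor trajectory (no lever-arm correction). Each cycle is integrated on
# its own: the attitude is anchored at the mid-stance zero-velocity instant
# from the accelerometer (gravity defines "up"; heading is arbitrary and
# cancels because the progression axis is defined per cycle from the two
# landing points), the gyro is propagated forwards and backwards from that
# anchor, gravity is removed in the global frame, and the remaining
# acceleration is double-integrated with a zero-velocity reset and linear
# de-drifting between the reset and the next landing.

#' Align the sensor frame with the shank
#'
#' Estimates the fixed mounting misalignment from a quasi-static window
#' (quiet standing) at the start of the recording: the measured specific
#' force during standing must map to (-1, 0, 0) g, i.e. gravity along the
#' negative X (shank long) axis. The estimated rotation is applied
#' consistently to both gyroscope and accelerometer.
#'
#' @param series an [imu_series].
#' @param rotation optional 3x3 rotation override; when given, no static
#'   window is searched.
#' @param static_gyro_dps gyro magnitude threshold (deg/s) below which a
#'   sample counts as static.
#' @param min_static_s minimum static-window duration in seconds.
#' @return the corrected [imu_series]; the applied rotation is attached as
#'   attribute `"rotation"`.
#' @export
correct_sensor_frame <- function(series, rotation = NULL,
                                 static_gyro_dps = 5, min_static_s = 0.5) {
  if (is.null(rotation)) {
    fs <- series$rate_hz
    gmag <- sqrt(rowSums(series$gyro^2)) * 180 / pi
    amag <- sqrt(rowSums(series$accel^2))
    static <- gmag < static_gyro_dps &
      abs(amag - GRAVITY_MPS2) < 0.1 * GRAVITY_MPS2
    run <- rle(static)
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1L
    good <- which(run$values & run$lengths >= min_static_s * fs)
    if (!length(good))
      abort_gs("no quasi-static window found and no rotation override given",
               "gaitscore_calibration_error")
    i0 <- starts[good[1]]; i1 <- ends[good[1]]
    a_mean <- colMeans(series$accel[i0:i1, , drop = FALSE])
    if (sqrt(sum(a_mean^2)) < 1e-6)
      abort_gs("gravity unobservable: static acceleration is zero",
               "gaitscore_calibration_error")
    rotation <- rotation_between(a_mean, c(-1, 0, 0))
  }
  out <- series
  out$gyro <- series$gyro %*% t(rotation)
  out$accel <- series$accel %*% t(rotation)
  colnames(out$gyro) <- colnames(out$accel) <- c("x", "y", "z")
  attr(out, "rotation") <- rotation
  out
}

#' Integrate shank rotation angles over a cycle
#'
#' Cumulative trapezoidal integral of each gyro axis from the cycle start,
#' in degrees; all three angles are zero at the first sample of the cycle.
#'
#' @param cycle a `gait_cycle`.
#' @param series the [imu_series].
#' @return n x 3 matrix (columns `x`, `y`, `z`) of rotation angles, deg.
#' @export
integrate_orientation <- function(cycle, series) {
  idx <- cycle$start_hs:cycle$end_hs
  ang <- cumtrapz(series$time[idx], series$gyro[idx, , drop = FALSE])
  ang <- ang * 180 / pi
  colnames(ang) <- c("x", "y", "z")
  ang
}

# index (into the series) of the zero-velocity instant: the stance sample
# minimizing the smoothed gyro magnitude.
find_zupt <- function(cycle, series, zupt_window_s = 0.1) {
  stance <- cycle$start_hs:(cycle$to - 1L)
  if (length(stance) < 2)
    abort_gs("stance phase too short for a zero-velocity instant",
             "gaitscore_kinematics_error")
  gmag <- sqrt(rowSums(series$gyro[stance, , drop = FALSE]^2))
  gsm <- moving_avg(gmag, round(zupt_window_s * series$rate_hz))
  stance[which.min(gsm)]
}

#' Reconstruct the per-cycle ankle trajectory
#'
#' Strapdown reconstruction for one gait cycle. The attitude at the
#' zero-velocity instant is taken from the accelerometer (specific force =
#' gravity reaction), propagated with the gyro across the cycle, gravity is
#' subtracted in the global frame, and acceleration is integrated twice.
#' Velocity is forced to zero at the zero-velocity instant and residual
#' drift is removed linearly up to the terminal heel-strike (the next
#' landing, itself a zero-velocity instant). The progression axis P is the
#' horizontal unit vector joining the two landing points, V points up, and
#' L completes the right-handed frame.
#'
#' @param cycle a `gait_cycle`.
#' @param series the frame-corrected [imu_series].
#' @param zupt_window_s smoothing window used to locate the zero-velocity
#'   instant, s.
#' @param gravity_mps2 local gravity magnitude.
#' @param drift_model `"linear"` (default) or `"none"`.
#' @return an object of class `cycle_kinematics`: list with `time`,
#'   `pos_pvl`, `vel_pvl` (metres, m/s; zeroed at cycle start), `rot`
#'   (degrees), `zupt` (series index), and `axes` (P/V/L expressed in the
#'   anchor frame).
#' @export
compute_trajectory <- function(cycle, series, zupt_window_s = 0.1,
                               gravity_mps2 = GRAVITY_MPS2,
                               drift_model = c("linear", "none")) {
  drift_model <- match.arg(drift_model)
  idx <- cycle$start_hs:cycle$end_hs
  t <- series$time[idx]
  n <- length(idx)
  gyr <- series$gyro[idx, , drop = FALSE]
  acc <- series$accel[idx, , drop = FALSE]

  zupt_abs <- find_zupt(cycle, series, zupt_window_s)
  iz <- match(zupt_abs, idx)

  # attitude anchor: specific force at the zero-velocity instant is the
  # gravity reaction, i.e. +V in the global frame
  fs <- series$rate_hz
  w <- max(1L, round(zupt_window_s * fs / 2))
  win <- max(1L, iz - w):min(n, iz + w)
  f0 <- colMeans(acc[win, , drop = FALSE])
  if (sqrt(sum(f0^2)) < 1e-3)
    abort_gs("no usable gravity signal at the zero-velocity instant",
             "gaitscore_kinematics_error")
  R0 <- rotation_between(f0, c(0, 1, 0))  # sensor -> global (V = +y)

  # propagate sensor->global rotation with the gyro, both directions
  Rs <- vector("list", n)
  Rs[[iz]] <- R0
  if (iz < n) for (k in iz:(n - 1L)) {
    wmid <- (gyr[k, ] + gyr[k + 1L, ]) / 2
    Rs[[k + 1L]] <- Rs[[k]] %*% rotvec_to_matrix(wmid * (t[k + 1L] - t[k]))
  }
  if (iz > 1) for (k in iz:2L) {
    wmid <- (gyr[k, ] + gyr[k - 1L, ]) / 2
    Rs[[k - 1L]] <- Rs[[k]] %*% rotvec_to_matrix(-wmid * (t[k] - t[k - 1L]))
  }

  # gravity-free acceleration in the global frame
  a_g <- matrix(0, n, 3)
  for (k in seq_len(n)) a_g[k, ] <- Rs[[k]] %*% acc[k, ]
  a_g[, 2] <- a_g[, 2] - gravity_mps2

  vel <- cumtrapz(t, a_g)
  vel <- sweep(vel, 2, vel[iz, ])  # zero-velocity reset
  if (drift_model == "linear" && iz < n) {
    span <- t[n] - t[iz]
    if (span > 0) {
      drift <- vel[n, ] / span
      after <- iz:n
      vel[after, ] <- vel[after, ] - outer(t[after] - t[iz], drift)
    }
  }
  pos <- cumtrapz(t, vel)
  pos <- sweep(pos, 2, pos[1, ])  # zeroed at cycle start

  # per-cycle P/V/L axes from the two landing points
  d <- pos[n, ] - pos[1, ]
  V <- c(0, 1, 0)
  h <- d - sum(d * V) * V
  if (sqrt(sum(h^2)) < 1e-9) {
    P <- c(1, 0, 0)  # degenerate (no horizontal progression)
  } else {
    P <- h / sqrt(sum(h^2))
  }
  L <- c(P[2] * V[3] - P[3] * V[2],
         P[3] * V[1] - P[1] * V[3],
         P[1] * V[2] - P[2] * V[1])
  A <- cbind(P = P, V = V, L = L)
  pos_pvl <- pos %*% A
  vel_pvl <- vel %*% A
  colnames(pos_pvl) <- colnames(vel_pvl) <- c("P", "V", "L")

  structure(
    list(time = t, pos_pvl = pos_pvl, vel_pvl = vel_pvl,
         rot = integrate_orientation(cycle, series),
         zupt = zupt_abs, axes = A),
    class = "cycle_kinematics")
}
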