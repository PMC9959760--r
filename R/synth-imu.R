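# Raw-signal synthetic gait trials.
#
# An analytic ankle trajectory is built per cycle -- the ankle is
# stationary through stance and follows smooth polynomial arcs through
# swing (quintic smoothstep forward, C2 bump upward) -- and the shank
# pitch rate is a mid-swing positive bump (peaking at the MSV target)
# flanked by narrow negative dips at toe-off and heel-strike, the
# landmark pattern event detection keys on. Accelerometer samples are the
# exact second derivative of the trajectory plus gravity, rotated into
# the pitching sensor frame, so the emitted 100 Hz streams are mutually
# consistent and the processing pipeline can be tested against recorded
# ground truth. Net pitch over a cycle is not forced to zero; the
# per-cycle, ZUPT-anchored reconstruction is invariant to that secular
# term, and the per-cycle rotation ranges are recorded as derived truths.

#' Specification for the raw-signal generator
#'
#' Per-cycle targets are the height-independent physical quantities; the
#' corresponding feature truths (height-normalized where the pipeline
#' normalizes) are recorded in the generation output.
#'
#' @param stride_m stride length target, metres.
#' @param cycle_s gait cycle duration, seconds.
#' @param swing_pct percent swing phase.
#' @param max_height_m peak ankle elevation during swing, metres.
#' @param lateral_m range of lateral ankle displacement during swing,
#'   metres.
#' @param peak_gyro_dps peak mediolateral angular velocity at mid-swing,
#'   deg/s.
#' @param dip_dps depth of the toe-off / heel-strike troughs, deg/s.
#' @param height_m subject height, metres.
#' @param n_cycles number of gait cycles emitted per leg (the first
#'   detectable cycle starts at the second heel-strike, so `n_cycles`
#'   yields `n_cycles - 1` usable cycles).
#' @param lead_s quiet-standing lead-in (used for frame calibration) and
#'   lead-out, seconds.
#' @param gyro_noise_dps,accel_noise_g additive white measurement noise.
#' @param fs sampling rate, Hz.
#' @return list of class `signal_gen_spec`.
#' @export
signal_gen_spec <- function(stride_m = 1.20, cycle_s = 1.10,
                            swing_pct = 40, max_height_m = 0.25,
                            lateral_m = 0.03, peak_gyro_dps = 400,
                            dip_dps = 120, height_m = 1.60,
                            n_cycles = 16, lead_s = 1.2,
                            gyro_noise_dps = 0, accel_noise_g = 0,
                            fs = 100) {
  spec <- list(stride_m = stride_m, cycle_s = cycle_s,
               swing_pct = swing_pct, max_height_m = max_height_m,
               lateral_m = lateral_m, peak_gyro_dps = peak_gyro_dps,
               dip_dps = dip_dps, height_m = height_m,
               n_cycles = n_cycles, lead_s = lead_s,
               gyro_noise_dps = gyro_noise_dps,
               accel_noise_g = accel_noise_g, fs = fs)
  moving <- stride_m > 0 || peak_gyro_dps > 0
  if (stride_m < 0 || max_height_m < 0 || lateral_m < 0 ||
      peak_gyro_dps < 0 || cycle_s <= 0 || height_m <= 0)
    abort_gs("targets must be non-negative (durations/height positive)",
             "gaitscore_data_error")
  if (moving) {
    t_swing <- cycle_s * swing_pct / 100
    if (swing_pct <= 5 || swing_pct >= 95 || t_swing <= 0.25)
      abort_gs("inconsistent targets: swing phase too short for the arcs",
               "gaitscore_data_error")
    # physical sanity: the swing arc's peak forward velocity stays realistic
    if (stride_m * 1.875 / t_swing > 10)
      abort_gs("inconsistent targets: implied peak foot velocity > 10 m/s",
               "gaitscore_data_error")
  }
  structure(spec, class = "signal_gen_spec")
}

# shape functions on [0, 1] with analytic derivatives --------------------

# quintic smoothstep: q(0)=0, q(1)=1, zero vel/acc at both ends
qstep <- function(s) s^3 * (10 - 15 * s + 6 * s^2)
qstep1 <- function(s) 30 * s^2 - 60 * s^3 + 30 * s^4
qstep2 <- function(s) 60 * s - 180 * s^2 + 120 * s^3

# C2 bump peaking at 1 at s = 1/2, zero value/vel/acc at both ends
hbump <- function(s) 64 * (s^3 - 3 * s^4 + 3 * s^5 - s^6)
hbump1 <- function(s) 64 * (3 * s^2 - 12 * s^3 + 15 * s^4 - 6 * s^5)
hbump2 <- function(s) 64 * (6 * s - 36 * s^2 + 60 * s^3 - 30 * s^4)

# sequence a with cumtrapz(a) == v exactly: a[k+1] = 2*diff(v)/dt - a[k],
# seeded with a[1] = 0 (signals start at rest)
inverse_trapz <- function(v, dt) {
  n <- length(v)
  if (n < 2) return(numeric(n))
  d <- 2 * diff(v) / dt
  sgn <- (-1)^(0:(n - 1))
  sgn * c(0, cumsum((-1)^(1:(n - 1)) * d))
}

# C2 window (1-u^2)^3 on [-1, 1] and its antiderivative
wbump <- function(u) ifelse(abs(u) < 1, (1 - u^2)^3, 0)
wbump_int <- function(u) {
  u <- pmin(1, pmax(-1, u))
  (u - u^3 + 3 * u^5 / 5 - u^7 / 7) + 16 / 35  # zero at u = -1
}
WBUMP_AREA <- 32 / 35

#' Generate a synthetic two-shank IMU trial
#'
#' @param spec a [signal_gen_spec].
#' @param seed optional RNG seed (only used when noise is requested).
#' @return list with `left` and `right` ([imu_series], right shifted by
#'   half a cycle), and `truth`: event times per side, the 12 feature
#'   targets/derived values (`features`), and per-sample ground truth for
#'   the left side (`time`, `theta_deg`, `accel_global`, `pos_global` in
#'   P/V/L coordinates).
#' @export
generate_imu_trial <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "signal_gen_spec"))
  if (!is.null(seed)) set.seed(seed)
  fs <- spec$fs
  T <- spec$cycle_s
  t_stance <- T * (1 - spec$swing_pct / 100)
  t_swing <- T - t_stance
  g0 <- GRAVITY_MPS2

  t0_left <- spec$lead_s
  t0_right <- spec$lead_s + T / 2
  total <- spec$lead_s + spec$n_cycles * T + T / 2 + spec$lead_s
  time <- seq(0, total, by = 1 / fs)

  one_side <- function(t0, side) {
    tau <- time - t0
    walk_dur <- spec$n_cycles * T
    k <- floor(tau / T)             # cycle index
    ph <- tau - k * T               # phase within cycle
    in_walk <- tau >= 0 & tau < walk_dur

    # trajectory (global P/V/L, metres)
    s <- pmin(1, pmax(0, (ph - t_stance) / t_swing))
    in_swing <- in_walk & ph >= t_stance
    s[!in_swing] <- 0
    pos_P <- ifelse(in_walk, k * spec$stride_m, 0) +
      ifelse(tau >= walk_dur, spec$n_cycles * spec$stride_m, 0) +
      spec$stride_m * qstep(s)
    pos_V <- spec$max_height_m * hbump(s)
    pos_L <- spec$lateral_m * hbump(s)
    vel_P <- spec$stride_m * qstep1(s) / t_swing * in_swing
    vel_V <- spec$max_height_m * hbump1(s) / t_swing * in_swing
    vel_L <- spec$lateral_m * hbump1(s) / t_swing * in_swing
    # acceleration samples chosen so that trapezoidal re-integration
    # reproduces the analytic velocity exactly at the sample instants
    acc_P <- inverse_trapz(vel_P, 1 / fs)
    acc_V <- inverse_trapz(vel_V, 1 / fs)
    acc_L <- inverse_trapz(vel_L, 1 / fs)

    # pitch rate (deg/s): swing bump + TO/HS dips at every event; a trial
    # with no swing rotation has no event landmarks either
    gap <- 0.09
    hw_sw <- (t_swing - 2 * gap) / 2
    c_sw <- t_stance + t_swing / 2
    dip_amp <- if (spec$peak_gyro_dps > 0) spec$dip_dps else 0
    omega <- numeric(length(time))
    theta <- numeric(length(time))      # deg, analytic integral
    add_bump <- function(center, hw, amp) {
      u <- (tau - center) / hw
      omega <<- omega + amp * wbump(u)
      theta <<- theta + amp * hw * wbump_int(u)
    }
    for (kk in 0:(spec$n_cycles - 1)) {
      add_bump(kk * T + c_sw, hw_sw, spec$peak_gyro_dps)
      add_bump(kk * T + t_stance, 0.06, -dip_amp)
      add_bump(kk * T, 0.06, -dip_amp)
    }
    add_bump(spec$n_cycles * T, 0.06, -dip_amp)  # final landing

    th <- theta * pi / 180
    # sensor axes in P/V/L coordinates at pitch th:
    #   x (shank long, inferior) = (sin th, -cos th, 0)
    #   y (anterior)             = (cos th,  sin th, 0)
    #   z (mediolateral)         = (0, 0, 1)
    f_P <- acc_P
    f_V <- acc_V + g0
    f_L <- acc_L
    accel <- cbind(sin(th) * f_P - cos(th) * f_V,
                   cos(th) * f_P + sin(th) * f_V,
                   f_L)
    gyro <- cbind(0, 0, omega * pi / 180)
    if (spec$gyro_noise_dps > 0)
      gyro <- gyro + matrix(stats::rnorm(length(gyro), 0,
                                         spec$gyro_noise_dps * pi / 180),
                            ncol = 3)
    if (spec$accel_noise_g > 0)
      accel <- accel + matrix(stats::rnorm(length(accel), 0,
                                           spec$accel_noise_g * g0),
                              ncol = 3)
    list(series = imu_series(time, gyro, accel, side = side, rate_hz = fs),
         theta_deg = theta,
         accel_global = cbind(P = acc_P, V = acc_V, L = acc_L),
         pos_global = cbind(P = pos_P, V = pos_V, L = pos_L),
         hs_times = t0 + (0:spec$n_cycles) * T,
         to_times = t0 + (0:(spec$n_cycles - 1)) * T + t_stance)
  }

  left <- one_side(t0_left, "left")
  right <- one_side(t0_right, "right")

  # derived per-cycle rotation range (pitch excursion over one interior
  # cycle, relative to its own start)
  i0 <- which(time >= t0_left + T)[1]
  i1 <- which(time >= t0_left + 2 * T)[1]
  rsz <- diff(range(left$theta_deg[i0:i1] - left$theta_deg[i0]))

  h <- spec$height_m
  features <- c(
    SL = spec$stride_m / h,
    GD = T,
    PSP = spec$swing_pct,
    MH = spec$max_height_m / h,
    RL = spec$lateral_m / h,
    RSZ = rsz, RSY = 0, RSX = 0,
    MPV = spec$stride_m * 1.875 / t_swing / h,
    MVV = spec$max_height_m * max(hbump1(seq(0, 1, 1e-3))) / t_swing / h,
    MSV = spec$peak_gyro_dps,
    MHD = spec$stride_m * 0.5 / h)

  list(left = left$series, right = right$series,
       truth = list(
         features = features, height_m = h,
         hs_times = list(left = left$hs_times, right = right$hs_times),
         to_times = list(left = left$to_times, right = right$to_times),
         time = time, theta_deg = left$theta_deg,
         accel_global = left$accel_global, pos_global = left$pos_global))
}
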