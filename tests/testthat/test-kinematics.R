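# Frame correction, orientation integration and ZUPT trajectory
# reconstruction.

test_that("an aligned static series yields the identity calibration", {
  s <- correct_sensor_frame(static_series())
  expect_equal(attr(s, "rotation"), diag(3), tolerance = 1e-9)
})

test_that("a known mounting tilt is recovered within 0.5 degrees", {
  s <- static_series()
  th <- 10 * pi / 180
  Rm <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  tilted <- imu_series(s$time, s$gyro %*% Rm, s$accel %*% Rm, s$side,
                       validate = FALSE)
  corr <- correct_sensor_frame(tilted)
  expect_equal(corr$accel[1, ], c(x = -9.80665, y = 0, z = 0),
               tolerance = 9.80665 * 0.5 * pi / 180)
})

test_that("zero acceleration makes gravity unobservable", {
  s <- static_series()
  dead <- imu_series(s$time, s$gyro, matrix(0, length(s$time), 3), s$side,
                     validate = FALSE)
  expect_error(correct_sensor_frame(dead),
               class = "gaitscore_calibration_error")
})

test_that("orientation integration matches analytic integrals", {
  fs <- 100
  n <- fs + 1
  mk <- function(gz_dps) {
    imu_series(seq(0, 1, by = 1 / fs),
               cbind(0, 0, gz_dps * pi / 180),
               cbind(rep(-9.80665, n), 0, 0))
  }
  cy <- structure(list(start_hs = 1L, to = 50L, end_hs = n),
                  class = "gait_cycle")
  # constant 90 deg/s over 1 s -> 90 deg range
  rot <- integrate_orientation(cy, mk(rep(90, n)))
  expect_equal(diff(range(rot[, "z"])), 90, tolerance = 1e-6)
  expect_equal(diff(range(rot[, "x"])), 0)
  # zero gyro -> zero everywhere
  expect_equal(max(abs(integrate_orientation(cy, mk(rep(0, n))))), 0)
  # sinusoid amplitude A, period = cycle: angle range = A*T/pi (degrees)
  A <- 120
  tt <- seq(0, 1, by = 1 / fs)
  rot_s <- integrate_orientation(cy, mk(A * sin(2 * pi * tt)))
  expect_equal(diff(range(rot_s[, "z"])), A / pi, tolerance = 1e-3)
})

test_that("a stationary cycle reconstructs zero displacement", {
  s <- static_series(3)
  cy <- structure(list(start_hs = 50L, to = 150L, end_hs = 250L),
                  class = "gait_cycle")
  kin <- compute_trajectory(cy, s)
  expect_lt(max(abs(kin$pos_pvl)), 1e-9)
  expect_equal(kin$pos_pvl[1, ], c(P = 0, V = 0, L = 0))
})

test_that("stride length and peak ankle height are recovered from truth", {
  trial <- generate_imu_trial(signal_gen_spec(stride_m = 1.20,
                                              max_height_m = 0.25))
  s <- correct_sensor_frame(trial$left)
  ev <- detect_gait_events(s)
  cy <- select_steady_cycles(ev, s)[[1]]
  kin <- compute_trajectory(cy, s)
  n <- nrow(kin$pos_pvl)
  expect_equal(unname(kin$pos_pvl[n, "P"]), 1.20, tolerance = 0.05)
  expect_equal(max(kin$pos_pvl[, "V"]), 0.25, tolerance = 0.02)
  # velocity is zero at the zero-velocity instant after compensation
  iz <- match(kin$zupt, cy$start_hs:cy$end_hs)
  expect_lt(sqrt(sum(kin$vel_pvl[iz, ]^2)), 0.05)
})

test_that("trajectories are invariant to a common sensor rotation", {
  trial <- generate_imu_trial(signal_gen_spec(n_cycles = 8))
  s0 <- correct_sensor_frame(trial$left)
  ev <- detect_gait_events(s0)
  cy <- suppressWarnings(select_steady_cycles(ev, s0))[[1]]
  ref <- compute_trajectory(cy, s0)

  axis <- c(1, 2, 3) / sqrt(14)
  th <- 15 * pi / 180
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  raw <- trial$left
  rot <- imu_series(raw$time, raw$gyro %*% R, raw$accel %*% R, raw$side,
                    validate = FALSE)
  s1 <- correct_sensor_frame(rot)
  kin1 <- compute_trajectory(cy, s1)
  expect_equal(kin1$pos_pvl, ref$pos_pvl, tolerance = 1e-6)
})

test_that("doubling the stride doubles the recovered progression", {
  rec <- function(stride) {
    trial <- generate_imu_trial(signal_gen_spec(stride_m = stride,
                                                n_cycles = 8))
    s <- correct_sensor_frame(trial$left)
    cy <- suppressWarnings(select_steady_cycles(detect_gait_events(s), s))[[1]]
    kin <- compute_trajectory(cy, s)
    unname(kin$pos_pvl[nrow(kin$pos_pvl), "P"])
  }
  expect_equal(rec(1.2) / rec(0.6), 2, tolerance = 0.05)
})
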