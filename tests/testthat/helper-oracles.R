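# Independent oracles and small constructors shared across tests.

# Straight-line re-implementation of the scoring chain (signed distance ->
# sigmoid bounding -> piecewise rescaling), written without any package
# code so it can serve as an independent cross-check.
oracle_score <- function(x, w, c, p, bl = -0.5, bu = 4.5) {
  xhp <- sum(w * x) + c
  yrd <- (bu - bl) / (1 + exp(-(xhp - (bu + bl) / 2))) + bl
  b <- c(bl, p, bu)
  j <- 0
  for (i in 1:4) if (yrd > b[i + 1]) j <- i
  (yrd - b[j + 1]) / (b[j + 2] - b[j + 1]) + bl + j
}

# random constraint-satisfying parameter set
random_params <- function(nf, bl = -0.5, bu = 4.5) {
  gaps <- stats::runif(5, 0.2, 1)
  p <- bl + cumsum(gaps)[1:4] / sum(gaps) * (bu - bl)
  scorer_params(w = stats::rnorm(nf), c = stats::rnorm(1), p = p,
                bl = bl, bu = bu)
}

# quick static imu_series: n seconds of quiet standing, aligned mounting
static_series <- function(n_s = 3, fs = 100) {
  n <- n_s * fs + 1
  imu_series(time = seq(0, n_s, by = 1 / fs),
             gyro = matrix(0, n, 3),
             accel = cbind(rep(-9.80665, n), 0, 0))
}

# gait_events object with regularly spaced steps (for windowing tests)
fake_events <- function(n_steps, fs = 100, cycle_s = 1.1, swing_frac = 0.4) {
  per <- round(cycle_s * fs)
  hs <- 1L + (0:n_steps) * per
  to <- hs[-length(hs)] + round((1 - swing_frac) * per)
  structure(list(hs = hs, to = to, swing_peaks = integer(0), flipped = FALSE),
            class = "gait_events")
}

fake_series_for <- function(events, fs = 100) {
  n <- max(events$hs) + 10L
  imu_series(time = seq(0, by = 1 / fs, length.out = n),
             gyro = matrix(0, n, 3),
             accel = cbind(rep(-9.80665, n), 0, 0))
}

# mean internal band width of the default generator truth (xhp units)
default_band_width <- function() {
  d <- inverse_bounded_distance(c(0.5, 1.5, 2.5, 3.5))
  mean(diff(d))
}
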