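# Gait event detection from the mediolateral shank angular velocity.
#
# The shank gyro Z trace of level walking is cyclic: a large positive peak
# at mid-swing flanked by negative troughs near toe-off (before the peak)
# and heel-strike (after it). Events are read off a zero-phase low-passed
# copy of the trace; all thresholds are exposed as arguments.

#' Detect heel-strike and toe-off events
#'
#' Low-passes the mediolateral (Z) angular velocity with a zero-phase
#' Butterworth filter, finds mid-swing positive peaks, and takes the
#' preceding local minimum as toe-off and the following local minimum as
#' heel-strike. Events strictly interleave as HS, TO, HS, TO, ...; swings
#' whose flanking minima fall outside the recording are dropped, so the
#' result always starts with a heel-strike.
#'
#' If the sensor is mounted mirrored (so that swing produces negative
#' peaks), the axis is flipped automatically: the median sign of the three
#' largest-magnitude extrema decides.
#'
#' @param series an [imu_series].
#' @param lowpass_hz filter cutoff in Hz.
#' @param peak_prominence_dps minimum swing-peak height above the filtered
#'   baseline, deg/s.
#' @param min_step_s minimum separation between successive swing peaks, s.
#' @return an object of class `gait_events`: list with `hs` and `to`
#'   (sample indices), `swing_peaks`, and `flipped`.
#' @export
detect_gait_events <- function(series, lowpass_hz = 10,
                               peak_prominence_dps = 50, min_step_s = 0.4) {
  t <- series$time
  if (length(t) < 2 || diff(range(t)) < 2)
    abort_gs("need at least 2 s of signal", "gaitscore_segmentation_error")
  fs <- series$rate_hz
  gz <- series$gyro[, 3] * 180 / pi  # deg/s

  bf <- signal::butter(2, lowpass_hz / (fs / 2), type = "low")
  gzf <- as.numeric(signal::filtfilt(bf, gz))

  # auto-flip for mirrored mounting
  ext <- local_extrema(gzf)
  mags <- abs(gzf[ext])
  flipped <- FALSE
  if (length(ext)) {
    top <- ext[order(mags, decreasing = TRUE)][seq_len(min(3, length(ext)))]
    if (stats::median(gzf[top]) < 0) {
      gzf <- -gzf
      flipped <- TRUE
    }
  }

  peaks <- find_peaks(gzf, height = peak_prominence_dps,
                      min_sep = round(min_step_s * fs))
  if (!length(peaks))
    abort_gs("no swing peaks found: no walking signal present",
             "gaitscore_segmentation_error")

  n <- length(gzf)
  hs <- integer(0); to <- integer(0)
  for (pk in peaks) {
    to_i <- previous_minimum(gzf, pk)
    hs_i <- next_minimum(gzf, pk)
    if (is.na(to_i) || is.na(hs_i)) next  # boundary-truncated swing
    to <- c(to, to_i); hs <- c(hs, hs_i)
  }
  if (!length(to))
    abort_gs("no complete swing (TO before, HS after) found",
             "gaitscore_segmentation_error")
  # interleave as HS, TO, HS, TO, ... : each kept TO must follow a detected
  # HS; the leading TO (whose initiating HS was not observed) is dropped.
  events <- data.frame(idx = c(hs, to),
                       type = c(rep("hs", length(hs)), rep("to", length(to))))
  events <- events[order(events$idx), ]
  while (nrow(events) && events$type[1] != "hs") events <- events[-1, ]
  keep <- logical(nrow(events))
  expect <- "hs"
  for (i in seq_len(nrow(events))) {
    if (events$type[i] == expect) {
      keep[i] <- TRUE
      expect <- if (expect == "hs") "to" else "hs"
    }
  }
  events <- events[keep, ]
  hs <- events$idx[events$type == "hs"]
  to <- events$idx[events$type == "to"]
  if (!length(hs) || !length(to))
    abort_gs("could not form an interleaved HS/TO sequence",
             "gaitscore_segmentation_error")
  structure(list(hs = hs, to = to, swing_peaks = peaks, flipped = flipped),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d heel-strikes, %d toe-offs%s\n",
              length(x$hs), length(x$to),
              if (x$flipped) " (z-axis auto-flipped)" else ""))
  invisible(x)
}

# all strict local extrema (interior)
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  which(d[-length(d)] * d[-1] < 0) + 1L
}

# local maxima above `height`, greedily thinned to a minimum separation
find_peaks <- function(x, height, min_sep) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- local_extrema(x)
  cand <- cand[x[cand] >= height & x[cand] > x[cand - 1L] & x[cand] > x[cand + 1L]]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand)
    if (!length(kept) || all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  sort(kept)
}

previous_minimum <- function(x, i) {
  while (i > 1 && x[i - 1] <= x[i]) i <- i - 1
  # require a true turning point, not the series edge
  if (i == 1) return(NA_integer_)
  i
}

next_minimum <- function(x, i) {
  n <- length(x)
  while (i < n && x[i + 1] <= x[i]) i <- i + 1
  if (i == n) return(NA_integer_)
  i
}

#' Carve steady gait cycles out of detected events
#'
#' The first `n_skip` steps of each leg belong to the accelerating phase of
#' the walk and are discarded; up to `n_keep` of the following steady
#' cycles are returned in temporal order. A cycle runs from one heel-strike
#' to the next heel-strike of the same leg, with the intervening toe-off
#' splitting stance from swing.
#'
#' @param events a `gait_events` object.
#' @param series the [imu_series] the events index into (used for the
#'   cycle-duration plausibility window).
#' @param n_skip accelerating steps to discard (default 4).
#' @param n_keep steady cycles to keep (default 10).
#' @param duration_range plausible cycle duration bounds in seconds.
#' @return list of `gait_cycle` objects, each with `start_hs`, `to`,
#'   `end_hs` sample indices.
#' @export
select_steady_cycles <- function(events, series, n_skip = 4, n_keep = 10,
                                 duration_range = c(0.4, 4)) {
  hs <- events$hs; to <- events$to
  n_cycles <- min(length(hs) - 1L, length(to))
  if (n_cycles < 1 || length(hs) < n_skip + 1)
    abort_gs(sprintf("only %d step(s) detected; need more than n_skip = %d",
                     max(0L, n_cycles), n_skip),
             "gaitscore_insufficient_data_error")
  cycles <- vector("list", n_cycles)
  for (k in seq_len(n_cycles)) {
    cycles[[k]] <- structure(
      list(start_hs = hs[k], to = to[k], end_hs = hs[k + 1L]),
      class = "gait_cycle")
  }
  ok <- vapply(cycles, function(cy) {
    dur <- series$time[cy$end_hs] - series$time[cy$start_hs]
    cy$start_hs < cy$to && cy$to < cy$end_hs &&
      dur > duration_range[1] && dur < duration_range[2]
  }, logical(1))
  cycles <- cycles[ok]
  if (length(cycles) <= n_skip)
    abort_gs(sprintf("only %d plausible cycle(s); need more than n_skip = %d",
                     length(cycles), n_skip),
             "gaitscore_insufficient_data_error")
  steady <- cycles[(n_skip + 1L):length(cycles)]
  if (length(steady) < n_keep)
    warn_gs(sprintf("only %d steady cycle(s) available (wanted %d)",
                    length(steady), n_keep),
            "gaitscore_short_trial_warning")
  steady[seq_len(min(n_keep, length(steady)))]
}
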