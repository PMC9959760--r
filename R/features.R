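# The twelve per-cycle gait parameters and their aggregation.
#
# Abbreviations (canonical column order):
#   SL  height-normalized stride length (landing point to landing point)
#   GD  gait cycle duration, s
#   PSP percent swing phase, %
#   MH  height-normalized max ankle height (V, relative to cycle-start HS)
#   RL  height-normalized range of lateral (L) displacement
#   RSZ/RSY/RSX ranges of integrated shank rotation about Z/Y/X, deg
#   MPV height-normalized max progressive (P) ankle velocity, 1/s
#   MVV height-normalized max vertical (V) ankle velocity, 1/s
#   MSV max mediolateral angular velocity during swing, deg/s
#   MHD height-normalized P displacement at the instant of MH

#' Compute the twelve gait features for one cycle
#'
#' @param kin a `cycle_kinematics` object for the cycle.
#' @param cycle the `gait_cycle`.
#' @param series the frame-corrected [imu_series].
#' @param height subject height in metres; SL, MH, RL, MPV, MVV and MHD are
#'   divided by it.
#' @param gyro_sign +1, or -1 when event detection flipped the Z axis for a
#'   mirrored mounting (affects MSV only; rotation ranges are signless).
#' @return named numeric vector of the 12 features.
#' @export
compute_cycle_features <- function(kin, cycle, series, height,
                                   gyro_sign = 1) {
  if (!is.numeric(height) || height <= 0)
    abort_gs("height must be positive", "gaitscore_feature_error")
  if (cycle$to <= cycle$start_hs || cycle$end_hs <= cycle$to)
    abort_gs("degenerate cycle: events do not satisfy HS < TO < HS",
             "gaitscore_feature_error")
  t <- kin$time
  n <- length(t)
  gd <- t[n] - t[1]
  t_to <- series$time[cycle$to]
  psp <- 100 * (t[n] - t_to) / gd

  pos <- kin$pos_pvl; vel <- kin$vel_pvl
  sl_m <- sqrt(pos[n, "P"]^2 + pos[n, "L"]^2)  # horizontal landing-to-landing
  v_rel <- pos[, "V"] - pos[1, "V"]
  i_mh <- which.max(v_rel)
  mh_m <- v_rel[i_mh]
  mhd_m <- pos[i_mh, "P"] - pos[1, "P"]
  rl_m <- diff(range(pos[, "L"]))

  rot_rng <- apply(kin$rot, 2, function(a) diff(range(a)))

  idx <- cycle$start_hs:cycle$end_hs
  swing <- idx >= cycle$to
  msv <- max(gyro_sign * series$gyro[idx[swing], 3]) * 180 / pi

  c(SL = unname(sl_m) / height,
    GD = gd,
    PSP = psp,
    MH = unname(mh_m) / height,
    RL = rl_m / height,
    RSZ = unname(rot_rng["z"]),
    RSY = unname(rot_rng["y"]),
    RSX = unname(rot_rng["x"]),
    MPV = max(vel[, "P"]) / height,
    MVV = max(vel[, "V"]) / height,
    MSV = msv,
    MHD = unname(mhd_m) / height)
}

#' Extract per-cycle features from one trial recording
#'
#' Runs the full single-IMU pipeline: sensor-frame correction, event
#' detection, steady-cycle selection, per-cycle trajectory reconstruction
#' and feature computation.
#'
#' @param series an [imu_series] (raw; frame correction is applied here).
#' @param height subject height in metres.
#' @param config a [gaitscore_config] list (segmentation/kinematics keys).
#' @return data.frame with one row per steady cycle and the 12 feature
#'   columns; the detected events are attached as attribute `"events"`.
#' @export
extract_trial_features <- function(series, height,
                                   config = gaitscore_config()) {
  seg <- config$segmentation
  kinc <- config$kinematics
  corrected <- correct_sensor_frame(series)
  events <- detect_gait_events(corrected,
                               lowpass_hz = seg$lowpass_hz,
                               peak_prominence_dps = seg$peak_prominence_dps,
                               min_step_s = seg$min_step_s)
  cycles <- select_steady_cycles(events, corrected,
                                 n_skip = seg$n_skip, n_keep = seg$n_keep)
  sgn <- if (events$flipped) -1 else 1
  rows <- lapply(cycles, function(cy) {
    kin <- compute_trajectory(cy, corrected,
                              zupt_window_s = kinc$zupt_window_s,
                              gravity_mps2 = kinc$gravity_mps2,
                              drift_model = kinc$drift_model)
    compute_cycle_features(kin, cy, corrected, height, gyro_sign = sgn)
  })
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "events") <- events
  out
}

#' Aggregate per-cycle features to one row per subject
#'
#' Flat arithmetic mean over all steady cycles of a subject (both legs, all
#' trials pooled), as collected during the steady walking phase.
#'
#' @param per_cycle data.frame of per-cycle feature rows (12 feature
#'   columns) with a `subject_id` column.
#' @param meta optional data.frame with `subject_id`, `rated_level`,
#'   `group` columns to join onto the result.
#' @return data.frame with one row per subject.
#' @export
aggregate_subjects <- function(per_cycle, meta = NULL) {
  if (!nrow(per_cycle))
    abort_gs("no cycles to aggregate", "gaitscore_feature_error")
  if (!"subject_id" %in% names(per_cycle))
    abort_gs("per_cycle must carry a subject_id column",
             "gaitscore_feature_error")
  feats <- intersect(FEATURE_NAMES, names(per_cycle))
  agg <- stats::aggregate(per_cycle[feats],
                          by = list(subject_id = per_cycle$subject_id),
                          FUN = mean)
  if (!is.null(meta)) {
    keep <- unique(meta[intersect(c("subject_id", "rated_level", "group",
                                    "height"), names(meta))])
    agg <- merge(agg, keep, by = "subject_id", sort = TRUE)
  }
  agg[order(agg$subject_id), , drop = FALSE]
}

#' Standardize features against the healthy reference
#'
#' Column-wise z-scores using the mean and standard deviation of the
#' healthy rows: `z = (x - mean_healthy) / sd_healthy`. Used for feature
#' presentation and the ANOVA screen; the scoring model itself consumes
#' raw features.
#'
#' @param table feature data.frame with a `group` column.
#' @param features columns to standardize (default: the 12 canonical ones
#'   present).
#' @param reference_group rows defining the reference (default healthy).
#' @return the table with standardized feature columns; reference means and
#'   sds are attached as attributes `"center"` and `"scale"`.
#' @export
standardize_features <- function(table, features = NULL,
                                 reference_group = "healthy") {
  features <- features %||% intersect(FEATURE_NAMES, names(table))
  ref <- table[table$group == reference_group, features, drop = FALSE]
  if (nrow(ref) < 2)
    abort_gs("need at least 2 healthy reference rows",
             "gaitscore_feature_error")
  mu <- vapply(ref, mean, numeric(1))
  sdv <- vapply(ref, stats::sd, numeric(1))
  zero <- names(sdv)[sdv <= 0 | !is.finite(sdv)]
  if (length(zero))
    abort_gs(paste0("zero healthy standard deviation for feature(s): ",
                    paste(zero, collapse = ", ")),
             "gaitscore_feature_error")
  out <- table
  out[features] <- sweep(sweep(table[features], 2, mu), 2, sdv, "/")
  attr(out, "center") <- mu
  attr(out, "scale") <- sdv
  out
}
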