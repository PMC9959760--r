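# IMU trial container and on-disk formats.
#
# File conventions: one CSV per shank with header t,gx,gy,gz,ax,ay,az in
# units s, deg/s and g. Internally angular velocity is kept in rad/s and
# specific force in m/s^2; conversions happen only at the file boundary.

#' Construct an IMU series
#'
#' A validated container for one shank-mounted 6-axis IMU recording.
#' Sensor axes follow the device convention: X inferior-superior (along the
#' shank), Y anterior-posterior, Z mediolateral. During quiet standing the
#' specific force is close to (-1, 0, 0) g.
#'
#' @param time numeric vector of timestamps in seconds, strictly increasing,
#'   nominally sampled at 100 Hz.
#' @param gyro n x 3 matrix of angular velocity in rad/s (sensor axes).
#' @param accel n x 3 matrix of specific force in m/s^2 (sensor axes).
#' @param side `"left"` or `"right"`.
#' @param rate_hz nominal sampling rate; the median sampling interval must
#'   agree with `1/rate_hz` within 1%.
#' @param validate set to `FALSE` to skip invariant checks (internal use).
#' @return an object of class `imu_series`.
#' @export
imu_series <- function(time, gyro, accel, side = "left", rate_hz = 100,
                       validate = TRUE) {
  gyro <- as.matrix(gyro); accel <- as.matrix(accel)
  colnames(gyro) <- c("x", "y", "z"); colnames(accel) <- c("x", "y", "z")
  x <- structure(
    list(time = as.numeric(time), gyro = gyro, accel = accel,
         side = match.arg(side, c("left", "right")), rate_hz = rate_hz),
    class = "imu_series")
  if (validate) validate_imu_series(x)
  x
}

validate_imu_series <- function(x) {
  n <- length(x$time)
  if (nrow(x$gyro) != n || nrow(x$accel) != n)
    abort_gs("gyro/accel and time lengths differ", "gaitscore_format_error")
  if (n >= 2) {
    dt <- diff(x$time)
    if (any(dt <= 0))
      abort_gs("time stamps are not strictly increasing",
               "gaitscore_data_error")
    if (abs(stats::median(dt) - 1 / x$rate_hz) > 0.01 / x$rate_hz)
      abort_gs(sprintf(
        "median sampling interval %.5f s is not within 1%% of %.5f s",
        stats::median(dt), 1 / x$rate_hz), "gaitscore_data_error")
  }
  # sensor ranges: +-1000 deg/s and +-8 g; reject, never clip
  gyro_dps <- x$gyro * 180 / pi
  accel_g <- x$accel / GRAVITY_MPS2
  bad <- rowSums(abs(gyro_dps) > 1000) > 0 | rowSums(abs(accel_g) > 8) > 0
  if (mean(bad) > 0.01)
    abort_gs(sprintf(
      "%.1f%% of samples exceed the sensor range (+-1000 deg/s, +-8 g)",
      100 * mean(bad)), "gaitscore_data_error")
  invisible(x)
}

#' @export
print.imu_series <- function(x, ...) {
  cat(sprintf("<imu_series> %s shank, %d samples, %.2f s @ %g Hz\n",
              x$side, length(x$time),
              if (length(x$time)) diff(range(x$time)) else 0, x$rate_hz))
  invisible(x)
}

#' Read a raw IMU trial file
#'
#' Reads a comma-separated file with header `t,gx,gy,gz,ax,ay,az` holding
#' time in seconds, angular velocity in deg/s and specific force in g, and
#' returns a validated [imu_series] (rad/s and m/s^2 internally). Rows are
#' taken as stored: the reader never reorders or resamples, and range
#' violations are rejected rather than clipped.
#'
#' @param path file path.
#' @param side which shank the file belongs to.
#' @param rate_hz nominal sampling rate (Hz).
#' @return an [imu_series].
#' @export
read_imu_csv <- function(path, side = "left", rate_hz = 100) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("t", "gx", "gy", "gz", "ax", "ay", "az")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    abort_gs(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
             "gaitscore_format_error")
  imu_series(
    time = df$t,
    gyro = cbind(df$gx, df$gy, df$gz) * pi / 180,
    accel = cbind(df$ax, df$ay, df$az) * GRAVITY_MPS2,
    side = side, rate_hz = rate_hz)
}

#' Write an IMU trial file
#'
#' Inverse of [read_imu_csv()]: converts back to deg/s and g and writes the
#' seven-column CSV.
#'
#' @param series an [imu_series].
#' @param path output file path.
#' @export
write_imu_csv <- function(series, path) {
  df <- data.frame(
    t = series$time,
    gx = series$gyro[, 1] * 180 / pi,
    gy = series$gyro[, 2] * 180 / pi,
    gz = series$gyro[, 3] * 180 / pi,
    ax = series$accel[, 1] / GRAVITY_MPS2,
    ay = series$accel[, 2] / GRAVITY_MPS2,
    az = series$accel[, 3] / GRAVITY_MPS2)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Trial metadata
#'
#' @param subject_id opaque subject identifier.
#' @param height subject height in metres (must lie in (0.5, 2.5)).
#' @param rated_level clinician-rated UPDRS gait level 0-4, or `NA` when
#'   unknown.
#' @param group `"healthy"` or `"pd"`.
#' @return a one-row `data.frame` of class `trial_meta`.
#' @export
trial_meta <- function(subject_id, height, rated_level = NA_integer_,
                       group = c("healthy", "pd")) {
  group <- match.arg(group)
  if (!is.numeric(height) || height <= 0.5 || height >= 2.5)
    abort_gs("height must be in (0.5, 2.5) metres", "gaitscore_data_error")
  if (!is.na(rated_level) && !(rated_level %in% 0:4))
    abort_gs("rated_level must be in 0..4 or NA", "gaitscore_data_error")
  structure(data.frame(subject_id = as.character(subject_id),
                       height = height,
                       rated_level = as.integer(rated_level),
                       group = group,
                       stringsAsFactors = FALSE),
            class = c("trial_meta", "data.frame"))
}

# Canonical feature column order (Table-2 listing order).
FEATURE_NAMES <- c("SL", "GD", "PSP", "MH", "RL", "RSZ", "RSY", "RSX",
                   "MPV", "MVV", "MSV", "MHD")

#' Read / write a subject-level feature table
#'
#' The feature table holds one row per subject with the twelve gait feature
#' columns (`SL, GD, PSP, MH, RL, RSZ, RSY, RSX, MPV, MVV, MSV, MHD`) plus
#' `subject_id`, `rated_level` and `group`.
#'
#' @param path file path.
#' @return `read_feature_csv` returns a `data.frame`;
#'   `write_feature_csv` returns `path` invisibly.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("subject_id", FEATURE_NAMES), names(df))
  if (length(missing_cols))
    abort_gs(paste0("feature table is missing column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "gaitscore_format_error")
  df
}

#' @rdname read_feature_csv
#' @param table a feature `data.frame`.
#' @export
write_feature_csv <- function(table, path) {
  front <- intersect(c("subject_id", "rated_level", "group"), names(table))
  ord <- c(front, intersect(FEATURE_NAMES, names(table)),
           setdiff(names(table), c(front, FEATURE_NAMES)))
  utils::write.csv(table[, ord, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Serialize scorer parameters to JSON
#'
#' Parameters round-trip at full double precision; a file whose demarcation
#' values violate the model constraints is rejected on read.
#'
#' @param params a [scorer_params] object.
#' @param path output file path.
#' @export
write_model_json <- function(params, path) {
  stopifnot(inherits(params, "scorer_params"))
  jsonlite::write_json(
    list(w = params$w, c = params$c, p = params$p,
         bl = params$bl, bu = params$bu, features = params$features),
    path, auto_unbox = FALSE, digits = I(17))  # 17 sig. digits: lossless
  invisible(path)
}

#' @rdname write_model_json
#' @return `read_model_json` returns a [scorer_params] object.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("w", "c", "p", "bl", "bu")
  if (length(setdiff(need, names(obj))))
    abort_gs("model file is missing required fields", "gaitscore_format_error")
  scorer_params(w = as.numeric(obj$w), c = as.numeric(obj$c),
                p = as.numeric(obj$p), bl = as.numeric(obj$bl),
                bu = as.numeric(obj$bu),
                features = if (length(obj$features)) as.character(obj$features)
                           else NULL)
}
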