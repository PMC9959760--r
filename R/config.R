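# One nested configuration list drives the whole pipeline; a YAML file with
# the same sections can override any subset of keys.

#' Pipeline configuration
#'
#' Returns the default configuration for the extraction, training,
#' selection and evaluation stages, optionally overridden by a YAML file
#' and/or named arguments (deep-merged section-wise).
#'
#' Sections and defaults:
#' * `segmentation`: `lowpass_hz = 10`, `peak_prominence_dps = 50`,
#'   `min_step_s = 0.4`, `n_skip = 4`, `n_keep = 10`.
#' * `kinematics`: `zupt_window_s = 0.1`, `gravity_mps2 = 9.80665`,
#'   `drift_model = "linear"`.
#' * `train`: `lambda = 0.1`, `beta = 0.005`, `eps_gap = 1e-3`,
#'   `maxit = 200`, `outer_iterations = 12`, `reltol = 1e-9`,
#'   `huber_delta = NULL` (exact absolute error).
#' * `select`: `alpha = 0.01`, `direction = "forward"`.
#' * `eval`: `svm_kernel = "linear"`, `svm_cost = 1`.
#'
#' @param file optional YAML file path.
#' @param ... named section overrides, e.g.
#'   `segmentation = list(n_keep = 8)`.
#' @return nested list of class `gaitscore_config`.
#' @export
gaitscore_config <- function(file = NULL, ...) {
  cfg <- list(
    segmentation = list(lowpass_hz = 10, peak_prominence_dps = 50,
                        min_step_s = 0.4, n_skip = 4, n_keep = 10),
    kinematics = list(zupt_window_s = 0.1, gravity_mps2 = GRAVITY_MPS2,
                      drift_model = "linear"),
    train = list(lambda = 0.1, beta = 0.005, eps_gap = 1e-3,
                 maxit = 200, outer_iterations = 12, reltol = 1e-9,
                 huber_delta = NULL),
    select = list(alpha = 0.01, direction = "forward"),
    eval = list(svm_kernel = "linear", svm_cost = 1))
  if (!is.null(file)) cfg <- merge_config(cfg, yaml::read_yaml(file))
  dots <- list(...)
  if (length(dots)) cfg <- merge_config(cfg, dots)
  structure(cfg, class = "gaitscore_config")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}
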