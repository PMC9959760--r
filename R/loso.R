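# Leave-one-subject-out cross-validation, shared by the nonlinear scorer
# and the three baselines so that comparisons are fold-paired.

#' Leave-one-subject-out cross-validation
#'
#' For each subject the chosen model is trained on all remaining subjects
#' (the per-feature standard deviations entering the R1 penalty are
#' recomputed from the training rows of the fold) and evaluated on the
#' held-out subject. All model kinds consume identical fold splits, so
#' errors are directly comparable across models.
#'
#' @param formula model formula (`rated_level ~ ...`).
#' @param data feature data.frame with one row per subject and a
#'   `subject_id` column.
#' @param model `"nonlinear"`, `"svm"`, `"nb"` or `"mlr"`.
#' @param subject_col name of the subject identifier column.
#' @param config a [gaitscore_config] (train/eval sections used).
#' @return data.frame of class `loso_cv` with columns `subject_id`,
#'   `true_level`, `score`, `pred_level`, plus attributes `model` and
#'   `folds`.
#' @export
loso_cv <- function(formula, data, model = c("nonlinear", "svm", "nb", "mlr"),
                    subject_col = "subject_id",
                    config = gaitscore_config()) {
  model <- match.arg(model)
  if (!subject_col %in% names(data))
    abort_gs(paste0("missing subject column: ", subject_col),
             "gaitscore_model_error")
  subjects <- unique(data[[subject_col]])
  if (length(subjects) < 3)
    abort_gs("need at least 3 subjects for LOSO", "gaitscore_model_error")
  resp <- all.vars(formula)[1]

  rows <- vector("list", length(subjects))
  for (k in seq_along(subjects)) {
    hold <- data[[subject_col]] == subjects[k]
    train <- data[!hold, , drop = FALSE]
    test <- data[hold, , drop = FALSE]
    if (length(unique(train[[resp]])) < 2) {
      warn_gs(sprintf("fold %s skipped: training set has a single level",
                      as.character(subjects[k])),
              "gaitscore_fold_warning")
      next
    }
    pred <- fit_and_predict(formula, train, test, model, config)
    rows[[k]] <- data.frame(subject_id = subjects[k],
                            true_level = test[[resp]][1],
                            score = pred$score,
                            pred_level = pred$level,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "model") <- model
  attr(out, "folds") <- length(subjects)
  class(out) <- c("loso_cv", "data.frame")
  out
}

# one fold: train on `train`, score the single-subject `test`
fit_and_predict <- function(formula, train, test, model, config) {
  tc <- config$train
  if (model == "nonlinear") {
    fit <- gait_scorer(formula, train, lambda = tc$lambda, beta = tc$beta,
                       eps_gap = tc$eps_gap, huber_delta = tc$huber_delta,
                       control = list(maxit = tc$maxit,
                                      outer_iterations = tc$outer_iterations,
                                      reltol = tc$reltol))
    sc <- predict(fit, test, type = "score")
    list(score = sc[1], level = round_to_level(sc)[1])
  } else {
    fit <- train_baseline(model, formula, train, config)
    predict_baseline(fit, test)
  }
}

#' @export
print.loso_cv <- function(x, ...) {
  e <- abs(x$pred_level - x$true_level)
  cat(sprintf(
    "<loso_cv> model %s: %d folds, %.1f%% exact, %.1f%% within one, mean error %.3f\n",
    attr(x, "model"), nrow(x), 100 * mean(e == 0), 100 * mean(e <= 1),
    mean(e)))
  invisible(x)
}
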