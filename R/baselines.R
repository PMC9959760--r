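# Comparison models (SVM, Gaussian naive Bayes, multiple linear
# regression) and the evaluation statistics.

#' Train a baseline model
#'
#' The three comparison models: a multiclass SVM over the levels (linear
#' kernel, C = 1 by default), a Gaussian naive Bayes classifier, and a
#' multiple linear regression of the level on the features whose
#' predictions are clamped to the score bounds and rounded with
#' [round_to_level()].
#'
#' @param kind `"svm"`, `"nb"` or `"mlr"`.
#' @param formula model formula (`rated_level ~ ...`).
#' @param data training data.frame.
#' @param config a [gaitscore_config] (eval section: `svm_kernel`,
#'   `svm_cost`).
#' @return object of class `gait_baseline`.
#' @export
train_baseline <- function(kind = c("svm", "nb", "mlr"), formula, data,
                           config = gaitscore_config()) {
  kind <- match.arg(kind)
  resp <- all.vars(formula)[1]
  fit <- switch(kind,
    svm = e1071::svm(stats::update(formula, factor(.y) ~ .),
                     data = transform_resp(data, resp),
                     kernel = config$eval$svm_kernel,
                     cost = config$eval$svm_cost, scale = TRUE),
    nb = fit_gaussian_nb(formula, data),
    mlr = stats::lm(formula, data))
  structure(list(kind = kind, fit = fit, formula = formula, resp = resp),
            class = "gait_baseline")
}

transform_resp <- function(data, resp) {
  data$.y <- data[[resp]]
  data
}

# Gaussian naive Bayes with a variance floor for degenerate classes.
fit_gaussian_nb <- function(formula, data, var_floor = 1e-9) {
  resp <- all.vars(formula)[1]
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  y <- factor(stats::model.response(mf))
  classes <- levels(y)
  stats_by <- lapply(classes, function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    mu <- colMeans(Xc)
    s2 <- apply(Xc, 2, function(v) if (length(v) > 1) stats::var(v) else 0)
    list(mu = mu, s2 = pmax(s2, var_floor),
         prior = nrow(Xc) / nrow(X))
  })
  names(stats_by) <- classes
  list(classes = classes, stats = stats_by, features = colnames(X))
}

predict_gaussian_nb <- function(nb, newdata) {
  X <- as.matrix(newdata[nb$features])
  ll <- vapply(nb$classes, function(cl) {
    st <- nb$stats[[cl]]
    lp <- rep(log(st$prior), nrow(X))
    for (j in seq_along(st$mu))
      lp <- lp + stats::dnorm(X[, j], st$mu[j], sqrt(st$s2[j]), log = TRUE)
    lp
  }, numeric(nrow(X)))
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1)
  nb$classes[max.col(ll, ties.method = "first")]
}

#' Predict with a baseline model
#'
#' @param object a `gait_baseline`.
#' @param newdata data.frame of feature values.
#' @param ... unused.
#' @return list with `score` (numeric) and `level` (integer). Classifier
#'   baselines return the predicted class as both score and level; the
#'   regression baseline returns the clamped continuous prediction and its
#'   rounding.
#' @export
predict.gait_baseline <- function(object, newdata, ...) {
  out <- switch(object$kind,
    svm = {
      lv <- as.integer(as.character(
        stats::predict(object$fit, transform_resp(newdata, object$resp))))
      list(score = as.numeric(lv), level = lv)
    },
    nb = {
      lv <- as.integer(predict_gaussian_nb(object$fit, newdata))
      list(score = as.numeric(lv), level = lv)
    },
    mlr = {
      sc <- pmin(4.5, pmax(-0.5, unname(stats::predict(object$fit, newdata))))
      list(score = sc, level = round_to_level(sc))
    })
  out
}

predict_baseline <- function(object, newdata) {
  p <- predict.gait_baseline(object, newdata)
  list(score = p$score[1], level = p$level[1])
}

#' Level estimation errors
#'
#' `e = |se - sn|` between rounded predicted levels and clinician levels.
#'
#' @param pred integer vector of predicted (rounded) levels.
#' @param true integer vector of clinician-rated levels.
#' @return list with `e` (integer vector) and `mean`.
#' @export
estimation_errors <- function(pred, true) {
  if (length(pred) != length(true))
    abort_gs("pred and true differ in length", "gaitscore_model_error")
  e <- abs(as.numeric(pred) - as.numeric(true))
  list(e = e, mean = mean(e))
}

#' Cumulative distribution of estimation errors
#'
#' `c_i = 100 * #(e <= i) / N` for i = 0, 1, ... up to the largest observed
#' error; non-decreasing with final value 100.
#'
#' @param e numeric vector of estimation errors.
#' @return named numeric vector (`c0`, `c1`, ...) in percent.
#' @export
cumulative_error_distribution <- function(e) {
  if (!length(e))
    abort_gs("empty error vector: cumulative distribution undefined",
             "gaitscore_model_error")
  imax <- max(0, ceiling(max(e)))
  ci <- vapply(0:imax, function(i) 100 * mean(e <= i), numeric(1))
  stats::setNames(ci, paste0("c", 0:imax))
}

#' Per-group error counts
#'
#' Number of mis-scored subjects in each reporting group (healthy controls
#' and PD subjects split by clinician level).
#'
#' @param report data.frame with `true_level`, `pred_level` columns.
#' @param groups character vector assigning each row to a reporting group
#'   (e.g. `"HC"`, `"PD0"`, `"PD1"`, `"PD2"`).
#' @return named integer vector of error counts per group (all groups
#'   present in `groups`, zero-filled).
#' @export
per_group_error_counts <- function(report, groups) {
  if (nrow(report) != length(groups))
    abort_gs("groups must label every report row", "gaitscore_model_error")
  wrong <- report$pred_level != report$true_level
  counts <- tapply(wrong, factor(groups), sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Evaluate all four models under shared LOSO folds
#'
#' Runs [loso_cv()] for the nonlinear scorer and the three baselines on the
#' same data (folds are identical by construction: one fold per subject, in
#' subject order) and assembles the error statistics.
#'
#' @param formula model formula.
#' @param data feature data.frame with `subject_id` (and optionally
#'   `group`).
#' @param models subset of `c("nonlinear", "svm", "nb", "mlr")`.
#' @param config a [gaitscore_config].
#' @return object of class `gait_eval`: list with per-model `cv` tables,
#'   `mean_error`, `cumulative` and, when a `group` column exists,
#'   `group_errors`.
#' @export
evaluate_models <- function(formula, data,
                            models = c("nonlinear", "svm", "nb", "mlr"),
                            config = gaitscore_config()) {
  models <- match.arg(models, several.ok = TRUE)
  cvs <- lapply(models, function(m)
    loso_cv(formula, data, model = m, config = config))
  names(cvs) <- models
  mean_error <- vapply(cvs, function(cv)
    estimation_errors(cv$pred_level, cv$true_level)$mean, numeric(1))
  cumulative <- lapply(cvs, function(cv)
    cumulative_error_distribution(
      estimation_errors(cv$pred_level, cv$true_level)$e))
  group_errors <- NULL
  if ("group" %in% names(data)) {
    key <- data[match(cvs[[1]]$subject_id, data$subject_id), ]
    glab <- ifelse(key$group == "healthy", "HC",
                   paste0("PD", key$rated_level))
    group_errors <- lapply(cvs, per_group_error_counts, groups = glab)
  }
  structure(list(cv = cvs, mean_error = mean_error,
                 cumulative = cumulative, group_errors = group_errors,
                 formula = formula),
            class = "gait_eval")
}

#' @export
print.gait_eval <- function(x, ...) {
  cat("LOSO evaluation (shared folds)\n")
  for (m in names(x$cv)) {
    ci <- x$cumulative[[m]]
    cat(sprintf("  %-9s mean error %.3f | exact %.1f%%, within one %.1f%%\n",
                m, x$mean_error[m], ci["c0"],
                if (length(ci) > 1) ci["c1"] else 100))
  }
  if (!is.null(x$group_errors)) {
    cat("  errors by group:\n")
    for (m in names(x$group_errors)) {
      g <- x$group_errors[[m]]
      cat(sprintf("    %-9s %s\n", m,
                  paste(names(g), g, sep = "=", collapse = " ")))
    }
  }
  invisible(x)
}
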