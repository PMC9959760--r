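# Feature selection: one-way ANOVA pre-filter and the greedy wrapper
# search over LOSO mean estimation error.

#' ANOVA screen of the gait features
#'
#' One-way fixed-effects ANOVA of each feature across the clinician-rated
#' level groups (healthy subjects count as level 0). Features whose F-test
#' p-value is below `alpha` are retained; the rest are treated as
#' redundant. A feature that is identical across all groups carries no
#' between-group variance and is reported with F = 0, p = 1.
#'
#' @param table feature data.frame with a level column.
#' @param features columns to screen (default: the canonical 12 present).
#' @param alpha retention threshold on the p-value (study value 0.01).
#' @param level_col grouping column.
#' @return list with `retained` (character), `p_values` and `F` (named
#'   numeric over all screened features).
#' @export
anova_filter <- function(table, features = NULL, alpha = 0.01,
                         level_col = "rated_level") {
  features <- features %||% intersect(FEATURE_NAMES, names(table))
  g <- factor(table[[level_col]])
  if (nlevels(g) < 2)
    abort_gs("need at least 2 level groups", "gaitscore_model_error")
  if (any(table(g) < 2))
    abort_gs("every level group needs at least 2 rows",
             "gaitscore_model_error")
  within_var <- vapply(features, function(f)
    sum(tapply(table[[f]], g, function(v) sum((v - mean(v))^2))), numeric(1))
  if (all(within_var == 0))
    abort_gs("all groups have zero variance in every feature",
             "gaitscore_model_error")
  Fv <- numeric(length(features)); pv <- numeric(length(features))
  names(Fv) <- names(pv) <- features
  for (f in features) {
    x <- table[[f]]
    if (stats::var(x) == 0 ||
        sum(tapply(x, g, function(v) length(v) * (mean(v) - mean(x))^2)) == 0) {
      Fv[f] <- 0; pv[f] <- 1
      next
    }
    a <- stats::anova(stats::lm(x ~ g))
    Fv[f] <- a$`F value`[1]
    pv[f] <- a$`Pr(>F)`[1]
    if (!is.finite(pv[f])) { Fv[f] <- 0; pv[f] <- 1 }
  }
  list(retained = features[pv < alpha], p_values = pv, F = Fv)
}

#' Greedy wrapper feature search
#'
#' Forward-greedy search over feature subsets: starting from the empty set,
#' each step adds the single feature giving the largest decrease (or
#' smallest increase) in LOSO mean estimation error, until all candidate
#' features are included. The whole error-vs-size curve is recorded; the
#' optimal set is the argmin of the curve, with ties broken towards the
#' smaller set and then canonical feature order. A backward-elimination
#' mode is available for comparison.
#'
#' @param data feature data.frame (one row per subject, `subject_id`
#'   column).
#' @param features candidate features (typically the ANOVA-retained set).
#' @param model model kind passed to [loso_cv()].
#' @param level_col response column.
#' @param direction `"forward"` (default) or `"backward"`.
#' @param config a [gaitscore_config].
#' @return list of class `greedy_search`: `curve` (data.frame with `k`,
#'   `features`, `mean_error`), `optimal` (list with `features`,
#'   `mean_error`), `model`, `direction`.
#' @export
greedy_feature_search <- function(data, features,
                                  model = c("nonlinear", "svm", "nb", "mlr"),
                                  level_col = "rated_level",
                                  direction = c("forward", "backward"),
                                  config = gaitscore_config()) {
  model <- match.arg(model)
  direction <- match.arg(direction)
  stopifnot(length(features) >= 1)

  eval_set <- function(set) {
    fml <- stats::reformulate(set, response = level_col)
    cv <- loso_cv(fml, data, model = model, config = config)
    mean(abs(cv$pred_level - cv$true_level))
  }

  curve <- list()
  if (direction == "forward") {
    current <- character(0)
    remaining <- features
    while (length(remaining)) {
      errs <- vapply(remaining, function(f) eval_set(c(current, f)),
                     numeric(1))
      best <- remaining[which.min(errs)]  # which.min: first = canonical order
      current <- c(current, best)
      remaining <- setdiff(remaining, best)
      curve[[length(curve) + 1L]] <-
        list(k = length(current), features = current,
             mean_error = min(errs))
    }
  } else {
    current <- features
    curve[[1L]] <- list(k = length(current), features = current,
                        mean_error = eval_set(current))
    while (length(current) > 1) {
      errs <- vapply(current, function(f) eval_set(setdiff(current, f)),
                     numeric(1))
      drop_f <- current[which.min(errs)]
      current <- setdiff(current, drop_f)
      curve[[length(curve) + 1L]] <-
        list(k = length(current), features = current,
             mean_error = min(errs))
    }
  }
  ks <- vapply(curve, `[[`, numeric(1), "k")
  errs <- vapply(curve, `[[`, numeric(1), "mean_error")
  ord <- order(errs, ks)  # min error, ties -> smaller set (curve order)
  best <- curve[[ord[1]]]
  structure(
    list(curve = data.frame(k = ks, mean_error = errs,
                            features = vapply(curve, function(s)
                              paste(s$features, collapse = "+"),
                              character(1))),
         optimal = list(features = best$features,
                        mean_error = best$mean_error),
         model = model, direction = direction),
    class = "greedy_search")
}

#' @export
print.greedy_search <- function(x, ...) {
  cat(sprintf("<greedy_search> model %s (%s)\n", x$model, x$direction))
  print(x$curve, row.names = FALSE)
  cat("optimal:", paste(x$optimal$features, collapse = ", "),
      sprintf(" (mean error %.3f)\n", x$optimal$mean_error))
  invisible(x)
}
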