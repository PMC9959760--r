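# Comparison models and error statistics.

test_that("a linear SVM separates a separable toy problem in-sample", {
  tab <- data.frame(rated_level = c(0L, 0L, 2L, 2L),
                    f1 = c(0, 0.2, 5, 5.2), f2 = c(0.1, 0, 5.1, 5))
  fit <- train_baseline("svm", rated_level ~ f1 + f2, tab)
  pred <- predict(fit, tab)
  expect_equal(pred$level, tab$rated_level)
})

test_that("linear regression recovers an exact linear rule", {
  set.seed(33)
  tab <- data.frame(x1 = runif(20), x2 = runif(20))
  tab$rated_level <- 2 * tab$x1
  fit <- train_baseline("mlr", rated_level ~ x1 + x2, tab)
  expect_equal(unname(coef(fit$fit)), c(0, 2, 0), tolerance = 1e-8)
  # predictions are clamped to the score bounds before rounding
  far <- data.frame(x1 = c(100, -100), x2 = 0)
  pr <- predict(fit, far)
  expect_equal(pr$score, c(4.5, -0.5))
  expect_equal(pr$level, c(4L, 0L))
})

test_that("Gaussian naive Bayes separates two well-separated clusters", {
  set.seed(35)
  n <- 60
  train <- data.frame(rated_level = rep(c(0L, 2L), each = n / 2),
                      f1 = c(rnorm(n / 2, 0), rnorm(n / 2, 4)),
                      f2 = c(rnorm(n / 2, 0), rnorm(n / 2, 4)))
  test <- data.frame(rated_level = rep(c(0L, 2L), each = 20),
                     f1 = c(rnorm(20, 0), rnorm(20, 4)),
                     f2 = c(rnorm(20, 0), rnorm(20, 4)))
  fit <- train_baseline("nb", rated_level ~ f1 + f2, train)
  acc <- mean(predict(fit, test)$level == test$rated_level)
  expect_gte(acc, 0.95)
})

test_that("naive Bayes tolerates a single-sample class", {
  tab <- data.frame(rated_level = c(0L, 0L, 0L, 1L),
                    f1 = c(0, 0.1, -0.1, 3))
  # the singleton class gets a variance floor instead of a crash; a point
  # at its mean is still recognized, nearby mass belongs to the wide class
  fit <- train_baseline("nb", rated_level ~ f1, tab)
  expect_equal(predict(fit, data.frame(f1 = 3))$level, 1L)
  expect_equal(predict(fit, data.frame(f1 = 0.05))$level, 0L)
})

test_that("estimation errors follow the absolute-difference rule", {
  expect_equal(estimation_errors(c(1, 2), c(1, 2))$mean, 0)
  expect_equal(estimation_errors(2, 1)$e, 1)
  r <- estimation_errors(c(0, 1, 2, 0), c(0, 2, 2, 2))
  expect_equal(r$e, c(0, 1, 0, 2))
  expect_equal(r$mean, 0.75)
  expect_error(estimation_errors(1:3, 1:2), class = "gaitscore_model_error")
})

test_that("cumulative error distribution is a percent CDF over integers", {
  ci <- cumulative_error_distribution(c(0, 0, 1, 2))
  expect_equal(unname(ci), c(50, 75, 100))
  expect_equal(names(ci), c("c0", "c1", "c2"))
  expect_equal(unname(cumulative_error_distribution(c(0, 0))), 100)
  expect_true(all(diff(ci) >= 0))
  expect_error(cumulative_error_distribution(numeric(0)),
               class = "gaitscore_model_error")
})

test_that("per-group error counts match their construction", {
  rep_df <- data.frame(true_level = c(0, 0, 1, 2, 2),
                       pred_level = c(0, 1, 1, 2, 0))
  groups <- c("HC", "HC", "PD1", "PD2", "PD2")
  counts <- per_group_error_counts(rep_df, groups)
  expect_equal(counts[["HC"]], 1L)
  expect_equal(counts[["PD1"]], 0L)
  expect_equal(counts[["PD2"]], 1L)
  all_right <- per_group_error_counts(
    data.frame(true_level = 0:1, pred_level = 0:1), c("HC", "PD1"))
  expect_true(all(all_right == 0L))
})

test_that("the shared-fold evaluation reports every requested model", {
  sim <- generate_features(feature_gen_spec(n_per_level = c(4, 4, 4)),
                           seed = 37)
  ev <- evaluate_models(rated_level ~ F1 + F2 + F3, sim$table,
                        models = c("svm", "nb", "mlr"))
  expect_named(ev$cv, c("svm", "nb", "mlr"))
  expect_equal(length(ev$mean_error), 3)
  # paired folds: identical subject order in every model's table
  expect_identical(ev$cv$svm$subject_id, ev$cv$mlr$subject_id)
  expect_identical(ev$cv$svm$true_level, ev$cv$nb$true_level)
  # exact accuracy is c0
  e <- abs(ev$cv$mlr$pred_level - ev$cv$mlr$true_level)
  expect_equal(unname(ev$cumulative$mlr["c0"]), 100 * mean(e == 0))
})
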