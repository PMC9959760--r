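# Loss assembly, constrained fitting and LOSO cross-validation.

test_that("loss components match hand assembly", {
  p0 <- scorer_params(rep(0, 2))
  X <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  lb <- scorer_loss(p0, X, c(0, 1, 1))
  expect_equal(lb$R1, 0)
  expect_equal(lb$R2, 5.0)  # five unit gaps at the default demarcations
  y0 <- 5 / (1 + exp(2)) - 0.5  # score of every point at w = 0, c = 0
  E_hand <- c(abs(y0 - 0), abs(y0 - 1))
  expect_equal(unname(lb$E), E_hand, tolerance = 1e-12)
  expect_equal(lb$total, sum(E_hand) / 2 + 0.1 * 0 + 0.005 * 5,
               tolerance = 1e-12)

  # single subject at level 0
  lb1 <- scorer_loss(p0, X[1, , drop = FALSE], 0)
  expect_equal(unname(lb1$E), y0, tolerance = 1e-12)
  expect_equal(lb1$total, y0 + 0.005 * 5, tolerance = 1e-12)
})

test_that("a perfect scorer leaves only the penalty terms", {
  # rows placed exactly on score targets via the inverse chain
  p <- scorer_params(c(2, 0), c = -1)
  lvls <- c(0, 1, 2)
  yrd <- lvls  # default p: piecewise map is identity, so yrd = wanted score
  xhp <- inverse_bounded_distance(yrd)
  X <- cbind((xhp + 1) / 2, rnorm(3))
  lb <- scorer_loss(p, X, lvls)
  expect_lt(sum(lb$E), 1e-9)
  expect_equal(lb$total, 0.1 * lb$R1 + 0.005 * lb$R2, tolerance = 1e-9)
})

test_that("degenerate gaps and empty data are rejected", {
  expect_error(scorer_loss(scorer_params(1), matrix(0, 0, 1), integer(0)),
               class = "gaitscore_model_error")
  bad <- scorer_params(1, validate = FALSE)
  bad$p <- c(-0.5, 1.5, 2.5, 3.5)  # p1 - bl = 0
  expect_error(scorer_loss(bad, matrix(1), 0),
               class = "gaitscore_model_error")
})

test_that("fitting a separable synthetic dataset recovers the labels", {
  sim <- generate_features(feature_gen_spec(n_per_level = c(20, 20, 20),
                                            noise = 0.05), seed = 2)
  fit <- gait_scorer(rated_level ~ F1 + F2 + F3, sim$table)
  expect_length(check_constraints(fit$params), 0)
  expect_lte(fit$loss$total, fit$init_loss$total)
  expect_gte(mean(fit$levels == sim$table$rated_level), 0.9)
})

test_that("a single perfectly predictive feature dominates the fit", {
  set.seed(13)
  n <- 45
  lev <- rep(0:2, each = n / 3)
  tab <- data.frame(rated_level = lev,
                    good = lev * 2 + rnorm(n, 0, 0.05),
                    junk1 = rnorm(n), junk2 = rnorm(n))
  fit <- gait_scorer(rated_level ~ good + junk1 + junk2, tab)
  contrib <- abs(fit$params$w) * apply(fit$x, 2, sd)
  expect_gt(contrib[["good"]], 5 * max(contrib[c("junk1", "junk2")]))
})

test_that("an extreme L2 weight collapses the coefficients", {
  sim <- generate_features(feature_gen_spec(n_per_level = c(10, 10, 10)),
                           seed = 4)
  fit <- gait_scorer(rated_level ~ F1 + F2 + F3, sim$table, lambda = 1e6)
  expect_lt(max(abs(fit$params$w)), 1e-3)
  expect_lt(diff(range(fit$fitted)), 0.2)
})

test_that("fitting is reproducible bit for bit", {
  sim <- generate_features(feature_gen_spec(n_per_level = c(8, 8, 8)),
                           seed = 6)
  f1 <- gait_scorer(rated_level ~ F1 + F2 + F3, sim$table)
  f2 <- gait_scorer(rated_level ~ F1 + F2 + F3, sim$table)
  expect_identical(f1$params$w, f2$params$w)
  expect_identical(f1$params$p, f2$params$p)
})

test_that("single-level data cannot be fit", {
  tab <- data.frame(rated_level = rep(1L, 6), F1 = rnorm(6))
  expect_error(gait_scorer(rated_level ~ F1, tab),
               class = "gaitscore_model_error")
})

test_that("LOSO produces one fold per subject", {
  sim <- generate_features(feature_gen_spec(n_per_level = c(2, 2, 1)),
                           seed = 8)
  cv <- loso_cv(rated_level ~ F1 + F2 + F3, sim$table)
  expect_equal(nrow(cv), 5)
  expect_setequal(cv$subject_id, sim$table$subject_id)
})

test_that("duplicated subjects are predicted from their twins", {
  sim <- generate_features(feature_gen_spec(n_per_level = c(2, 2, 2)),
                           seed = 10)
  twin <- sim$table
  twin$subject_id <- paste0(twin$subject_id, "dup")
  both <- rbind(sim$table, twin)
  cv <- loso_cv(rated_level ~ F1 + F2 + F3, both)
  expect_equal(cv$pred_level, cv$true_level)
})

test_that("scores sharpen as generator noise shrinks", {
  bw <- default_band_width()
  err_at <- function(noise) {
    sim <- generate_features(feature_gen_spec(n_per_level = c(25, 25, 25),
                                              noise = noise), seed = 12)
    fit <- gait_scorer(rated_level ~ F1 + F2 + F3, sim$table)
    probe <- generate_features(feature_gen_spec(n_per_level = c(40, 40, 40)),
                               seed = 13)
    mean(predict(fit, probe$table, type = "level") !=
           probe$table$rated_level)
  }
  expect_lte(err_at(0.075 * bw), err_at(0.3 * bw) + 0.02)
})

test_that("mean predictions respect ordinal structure", {
  sim <- generate_features(feature_gen_spec(n_per_level = c(15, 15, 15),
                                            noise = 0.1), seed = 14)
  fit <- gait_scorer(rated_level ~ F1 + F2 + F3, sim$table)
  m <- tapply(fit$fitted, sim$table$rated_level, mean)
  expect_true(all(diff(m) > 0))
  expect_s3_class(summary(fit), "summary.gait_scorer")
  expect_length(coef(fit), 3 + 1 + 4)
  expect_equal(unname(residuals(fit)), unname(fit$fitted - sim$table$rated_level))
})
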