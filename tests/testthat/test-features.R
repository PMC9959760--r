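# The twelve gait parameters, aggregation and healthy-reference
# standardization.

test_that("temporal features follow from the event times", {
  # HS at 0.00 s, TO at 0.66 s, next HS at 1.10 s -> GD 1.10, PSP 40%
  fs <- 100
  n <- 111
  s <- imu_series(seq(0, 1.10, by = 1 / fs),
                  cbind(0, 0, rep(0, n)), cbind(rep(-9.80665, n), 0, 0))
  cy <- structure(list(start_hs = 1L, to = 67L, end_hs = n),
                  class = "gait_cycle")  # t[67] = 0.66 s
  kin <- compute_trajectory(cy, s)
  f <- compute_cycle_features(kin, cy, s, height = 1.60)
  expect_equal(f[["GD"]], 1.10)
  expect_equal(f[["PSP"]], 40.0, tolerance = 1e-9)
})

test_that("full-pipeline features match the generator targets", {
  trial <- generate_imu_trial(signal_gen_spec(stride_m = 1.20,
                                              height_m = 1.60,
                                              peak_gyro_dps = 400))
  feats <- extract_trial_features(trial$left, trial$truth$height_m)
  m <- colMeans(feats)
  expect_equal(m[["SL"]], 1.20 / 1.60, tolerance = 0.03)  # 0.75
  expect_equal(m[["MSV"]], 400, tolerance = 5)
  expect_equal(m[["RSZ"]], trial$truth$features[["RSZ"]], tolerance = 2)
  expect_equal(m[["MHD"]], trial$truth$features[["MHD"]], tolerance = 0.03)
  expect_equal(m[["MPV"]], trial$truth$features[["MPV"]], tolerance = 0.1)
  expect_equal(m[["MVV"]], trial$truth$features[["MVV"]], tolerance = 0.05)
  # velocity bound: a stride cannot exceed peak forward speed x duration
  expect_true(all(feats$SL <= feats$MPV * feats$GD + 1e-9))
})

test_that("degenerate cycles are rejected", {
  s <- static_series()
  cy <- structure(list(start_hs = 10L, to = 10L, end_hs = 50L),
                  class = "gait_cycle")
  kin <- compute_trajectory(structure(list(start_hs = 10L, to = 30L,
                                           end_hs = 50L),
                                      class = "gait_cycle"), s)
  expect_error(compute_cycle_features(kin, cy, s, 1.6),
               class = "gaitscore_feature_error")
  expect_error(compute_cycle_features(kin, cy, s, -1),
               class = "gaitscore_feature_error")
})

test_that("jointly scaling trajectory and height leaves normalized features unchanged", {
  k <- 1.3
  f1 <- colMeans(extract_trial_features(
    generate_imu_trial(signal_gen_spec())$left, 1.60))
  f2 <- colMeans(extract_trial_features(
    generate_imu_trial(signal_gen_spec(stride_m = 1.20 * k,
                                       max_height_m = 0.25 * k,
                                       lateral_m = 0.03 * k,
                                       height_m = 1.60 * k))$left, 1.60 * k))
  for (nm in c("SL", "MH", "RL", "MHD"))
    expect_equal(f2[[nm]], f1[[nm]], tolerance = 0.02)
  # velocities scale with the trajectory and normalize out too
  expect_equal(f2[["MPV"]], f1[["MPV"]], tolerance = 0.05)
  expect_equal(f2[["MVV"]], f1[["MVV"]], tolerance = 0.05)
})

test_that("feature extraction is deterministic", {
  trial <- generate_imu_trial(signal_gen_spec(n_cycles = 8))  # short trial
  f1 <- suppressWarnings(extract_trial_features(trial$left, 1.6))
  f2 <- suppressWarnings(extract_trial_features(trial$left, 1.6))
  expect_identical(f1, f2)
})

test_that("subject aggregation is a flat mean over cycles", {
  pc <- data.frame(subject_id = c("a", "a", "b"),
                   SL = c(0.7, 0.8, 0.5), GD = c(1.0, 1.2, 1.4))
  agg <- aggregate_subjects(pc)
  expect_equal(agg$GD[agg$subject_id == "a"], 1.1)
  expect_equal(agg$SL[agg$subject_id == "b"], 0.5)
  # single cycle -> identity
  one <- aggregate_subjects(data.frame(subject_id = "z", SL = 0.61))
  expect_equal(one$SL, 0.61)
  expect_error(aggregate_subjects(pc[0, ]), class = "gaitscore_feature_error")
  # many cycles equal the flat mean of all rows
  set.seed(5)
  big <- data.frame(subject_id = "s",
                    SL = runif(60), GD = runif(60), MSV = runif(60))
  agg2 <- aggregate_subjects(big)
  expect_equal(agg2$MSV, mean(big$MSV), tolerance = 1e-12)
})

test_that("healthy-reference standardization behaves like a z-score", {
  set.seed(9)
  tab <- data.frame(group = c(rep("healthy", 10), rep("pd", 3)),
                    SL = c(rnorm(10, 10, 2), 14, 10, 6),
                    GD = c(rnorm(10, 1, 0.1), 1.2, 1.0, 0.8))
  z <- standardize_features(tab, features = c("SL", "GD"))
  hz <- z[z$group == "healthy", ]
  expect_equal(mean(hz$SL), 0, tolerance = 1e-12)
  expect_equal(stats::sd(hz$SL), 1, tolerance = 1e-12)
  # a value one-sigma-x2 above the healthy mean scores z = 2
  mu <- attr(z, "center")[["SL"]]; sdv <- attr(z, "scale")[["SL"]]
  tab2 <- tab; tab2$SL[11] <- mu + 2 * sdv
  z2 <- standardize_features(tab2, features = c("SL", "GD"))
  expect_equal(z2$SL[11], 2, tolerance = 1e-12)

  const <- tab; const$SL <- 5
  expect_error(standardize_features(const, features = c("SL", "GD")),
               class = "gaitscore_feature_error")
})
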