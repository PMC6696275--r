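test_that("slope reproduces exact affine and flat responses", {
  e <- seq(0.1, 0.9, length.out = 200)
  expect_equal(slope(e, 2 * e + 1), 2, tolerance = 1e-12)
  expect_equal(slope(e, rep(0.4, 200)), 0, tolerance = 1e-12)
  expect_error(slope(rep(0.5, 200), e), class = "occl_degenerate_error")
  expect_error(slope(e[1], 0.2), class = "occl_insufficient_data_error")
})

test_that("slope matches the grid-search least-squares oracle", {
  set.seed(21)
  for (i in 1:20) {
    a_true <- runif(1, -30, 30)
    e <- runif(200)
    f <- a_true * e + runif(1, -5, 5) + rnorm(200, 0, 0.3)
    oracle <- grid_ls_slope(e, f)
    expect_equal(slope(e, f), oracle$a, tolerance = 10 * oracle$step)
  }
})

test_that("fold_mean_slope averages per-run slopes", {
  expect_equal(fold_mean_slope(affine_session(a = -16, K = 6L)$runs[1:5]),
               -16, tolerance = 1e-9)
  # mixed slopes: build runs with different couplings and average by hand
  u <- (0:199) / 199
  ramp <- 0.06 + 0.5 * u
  runs <- lapply(c(1, 2, 3, 4, 5), function(a)
    occl_run(ear = 0.1 + (ramp - 0.06) / a, emg = ramp, force = ramp))
  expect_equal(fold_mean_slope(runs), 3, tolerance = 1e-9)
  flat <- occl_run(ear = rep(0.5, 200), emg = ramp, force = ramp,
                   run_index = 4L)
  err <- expect_error(fold_mean_slope(list(runs[[1]], flat)),
                      class = "occl_degenerate_error")
  expect_match(conditionMessage(err), "run 4")
})

test_that("anchored prediction evaluates f~ = a(e - e0) + f0", {
  expect_equal(predict_force(c(0.1, 0.2, 0.3), -10, 0.1, 0.5),
               c(0.5, -0.5, -1.5))
  expect_equal(predict_force(rep(0.3, 5), 7, 0.3, 0.2), rep(0.2, 5))
  expect_equal(predict_force(runif(5), 0, 0.1, 0.9), rep(0.9, 5))
})

test_that("rmse and nrmse follow their definitions", {
  f <- runif(50)
  expect_equal(rmse(f, f), 0)
  expect_equal(rmse(f, f + 0.3), 0.3)
  set.seed(2)
  g <- runif(50)
  expect_equal(rmse(f, g), sqrt(sum((f - g)^2) / 50))
  expect_error(rmse(f, g[1:10]), class = "occl_range_error")

  expect_equal(nrmse(0, 0.9, 0.1), 0)
  expect_equal(nrmse(0.0338, 0.5390, 0), 0.0338 / 0.5390)
  # scale invariance
  expect_equal(nrmse(2 * 0.04, 2 * 0.6, 2 * 0.1), nrmse(0.04, 0.6, 0.1))
  expect_error(nrmse(0.1, 0.5, 0.5), class = "occl_degenerate_error")
  expect_error(estimated_width(0.1, 0.2), class = "occl_range_error")
  expect_equal(estimated_width(0.7, 0.7), 0)
})

test_that("occl_fit trains on the non-excluded runs and predicts anchored", {
  s <- affine_session(a = -12, K = 6L)
  fit <- occl_fit(s, exclude = 3L)
  expect_setequal(fit$train_runs, setdiff(1:6, 3L))
  expect_equal(unname(coef(fit)), -12, tolerance = 1e-9)
  test_run <- s$runs[[3L]]
  pred <- predict(fit, test_run)
  expect_equal(pred, test_run$force, tolerance = 1e-8)
  # bare series requires anchors
  expect_error(predict(fit, test_run$ear), class = "occl_range_error")
  expect_equal(predict(fit, test_run$ear, e0 = test_run$ear[1],
                       f0 = test_run$force[1]),
               pred)
  expect_error(occl_fit(s, exclude = 9L), class = "occl_range_error")
})

test_that("noise-free cross-validation recovers the generating slope exactly", {
  p <- subject_params(slope = -16.1, drift_sd = 0, noise_ear_sd = 0,
                      noise_emg_sd = 0, noise_force_sd = 0,
                      peak_jitter_sd = 0, quantize = FALSE, seed = 4L)
  cv <- cross_validate(generate_session(p))
  expect_equal(unname(cv$summary["a_bar_mean"]), -16.1, tolerance = 1e-9)
  expect_equal(cv$folds$rmse, rep(0, 6), tolerance = 1e-9)
  expect_equal(cv$folds$nrmse, rep(0, 6), tolerance = 1e-9)
})

test_that("drift shifts ear offsets but anchoring keeps recovery exact", {
  # per-run offset drift alone (no per-sample noise) changes e0 between
  # runs yet the anchored predictor absorbs it exactly
  p <- subject_params(slope = -16.1, drift_sd = 0.01, noise_ear_sd = 0,
                      noise_emg_sd = 0, noise_force_sd = 0,
                      peak_jitter_sd = 0, quantize = FALSE, seed = 8L)
  cv <- cross_validate(generate_session(p))
  expect_gt(diff(range(cv$folds$e0)), 0)
  expect_equal(cv$folds$rmse, rep(0, 6), tolerance = 1e-9)
})

test_that("two-run sessions cross-validate with single-run training sets", {
  s <- affine_session(a = 5, K = 2L)
  cv <- cross_validate(s)
  expect_equal(nrow(cv$folds), 2L)
  expect_equal(cv$folds$a_bar, rep(5, 2), tolerance = 1e-9)
})

test_that("cross-validation summary averages each fold column independently", {
  s <- generate_session(subject_params(seed = 31), subject_id = "avg")
  cv <- cross_validate(s)
  expect_equal(unname(cv$summary["rmse_mean"]), mean(cv$folds$rmse))
  expect_equal(unname(cv$summary["nrmse_mean"]), mean(cv$folds$nrmse))
  expect_equal(unname(cv$summary["width_mean"]), mean(cv$folds$width))
  expect_equal(unname(cv$summary["a_bar_sd"]), sd(cv$folds$a_bar))
  # the averaged NRMSE is deliberately NOT rmse_mean / width_mean
  expect_equal(cv$folds$nrmse, cv$folds$rmse / cv$folds$width)
  # anchor identity: the first estimate equals the anchor force exactly
  for (k in seq_len(cv$K))
    expect_identical(cv$estimates[[k]][1L], cv$folds$f0[k])
  # residuals method is measured minus estimated
  r <- residuals(cv)
  expect_equal(dim(r), c(200L, 6L))
  expect_equal(r[, 2], s$runs[[2]]$force - cv$estimates[[2]])
})

test_that("slope attenuates toward zero as ear-channel noise grows", {
  scales <- c(0, 0.003, 0.01)
  rec <- vapply(seq_along(scales), function(i) {
    got <- vapply(1:20, function(s) {
      p <- subject_params(slope = -16.1, noise_ear_sd = scales[i],
                          noise_force_sd = 0, quantize = FALSE,
                          seed = 500L + s)
      unname(cross_validate(generate_session(p))$summary["a_bar_mean"])
    }, numeric(1))
    mean(abs(got))
  }, numeric(1))
  expect_true(all(diff(rec) < 0))
})
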