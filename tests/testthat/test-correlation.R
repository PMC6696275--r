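test_that("pearson matches hand-computed and affine-exact cases", {
  x <- c(0.2, 0.5, 0.9, 0.4)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -2 * x + 5), -1)
  # 3-point product-moment value: sqrt(27/28), computed by hand
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 4)), sqrt(27 / 28),
               tolerance = 1e-12)
  expect_error(pearson(x, rep(0.3, 4)), class = "occl_degenerate_error")
  expect_error(pearson(x[1], x[1]), class = "occl_insufficient_data_error")
  expect_error(pearson(x, x[1:3]), class = "occl_range_error")
})

test_that("partial correlation follows the first-order recursion", {
  # independent control leaves the coefficient unchanged
  expect_equal(partial_correlation(0.7, 0, 0), 0.7)
  # correlation fully explained by the control vanishes
  expect_equal(partial_correlation(0.6 * 0.5, 0.6, 0.5), 0)
  expect_error(partial_correlation(0.5, 1, 0.2),
               class = "occl_degenerate_error")
  expect_error(partial_correlation(1.5, 0.2, 0.2),
               class = "occl_range_error")
})

test_that("partial correlation agrees with the residual-regression oracle", {
  set.seed(11)
  for (i in 1:200) {
    d <- random_correlated_triple(n = 40L)
    r <- stats::cor(cbind(d$x, d$y, d$z))
    got <- partial_correlation(r[1, 2], r[1, 3], r[2, 3])
    expect_equal(got, partial_cor_residual_oracle(d$x, d$y, d$z),
                 tolerance = 1e-10)
    expect_lte(abs(got), 1 + 1e-12)
  }
})

test_that("summarize_runs is the mean and n-1 standard deviation", {
  expect_equal(summarize_runs(rep(0.42, 6)), c(mean = 0.42, sd = 0))
  expect_equal(summarize_runs(c(0, 2)), c(mean = 1, sd = sqrt(2)))
  set.seed(5)
  v <- runif(6)
  got <- summarize_runs(v)
  expect_equal(got[["mean"]], sum(v) / 6)
  expect_equal(got[["sd"]], sqrt(sum((v - mean(v))^2) / 5))
  expect_error(summarize_runs(0.3), class = "occl_insufficient_data_error")
})

test_that("exact affine coupling gives |r| = 1 pairwise, degenerate partials", {
  s <- affine_session(a = -16, K = 4L)
  for (run in s$runs) {
    expect_equal(pearson(run$ear, run$force), -1)
    expect_equal(pearson(run$ear, run$emg), -1)
    expect_equal(pearson(run$emg, run$force), 1)
  }
  # perfectly coupled channels leave the partial coefficient undefined (0/0)
  expect_error(correlation_table(s), class = "occl_degenerate_error")
})

test_that("vanishing noise drives pairwise coefficients to |mean_r| = 1, sd_r = 0", {
  p <- subject_params(noise_ear_sd = 1e-6, noise_emg_sd = 1e-6,
                      noise_force_sd = 1e-6, drift_sd = 0,
                      quantize = FALSE, seed = 44L)
  ct <- correlation_table(generate_session(p))
  pe <- ct[ct$statistic == "pearson", ]
  expect_equal(abs(pe$mean_r), rep(1, 3), tolerance = 1e-6)
  expect_equal(pe$sd_r, rep(0, 3), tolerance = 1e-6)
  # negative coupling: ear-force and ear-emg negative, emg-force positive
  m <- setNames(pe$mean_r, pe$pair)
  expect_lt(m[["ear_force"]], 0)
  expect_lt(m[["ear_emg"]], 0)
  expect_gt(m[["emg_force"]], 0)
})

test_that("flipping the ear channel flips only ear-involved coefficients", {
  s <- generate_session(subject_params(seed = 9), subject_id = "flip")
  ct <- correlation_table(s)
  ct_flip <- correlation_table(transform_session(s, ear = function(e) 1 - e))
  for (stat in c("pearson", "partial")) {
    a <- ct[ct$statistic == stat, ]
    b <- ct_flip[ct_flip$statistic == stat, ]
    for (p in a$pair) {
      sgn <- if (grepl("ear", p)) -1 else 1
      expect_equal(b$mean_r[b$pair == p], sgn * a$mean_r[a$pair == p],
                   tolerance = 1e-9)
      expect_equal(b$sd_r[b$pair == p], a$sd_r[a$pair == p],
                   tolerance = 1e-9)
    }
  }
})

test_that("channel correlations attenuate as independent noise grows", {
  scales <- c(0.001, 0.005, 0.02)
  mean_abs_r <- vapply(seq_along(scales), function(i) {
    p <- subject_params(noise_ear_sd = scales[i], seed = 100L)
    ct <- correlation_table(generate_session(p))
    abs(ct$mean_r[ct$statistic == "pearson" & ct$pair == "ear_force"])
  }, numeric(1))
  expect_true(all(diff(mean_abs_r) < 0))
})

test_that("degenerate channels are reported with subject and run identity", {
  ramp <- seq(0.06, 0.6, length.out = 200)
  flat <- occl_run(ear = rep(0.5, 200), emg = ramp, force = ramp,
                   run_index = 2L)
  ok <- occl_run(ear = rev(ramp), emg = ramp, force = ramp, run_index = 1L)
  s <- occl_session("Z", list(ok, flat))
  err <- expect_error(correlation_table(s), class = "occl_degenerate_error")
  expect_match(conditionMessage(err), "subject Z, run 2")
})
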