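test_that("colony ratios divide by the control replicate mean", {
  expect_equal(colony_ratio(c(30, 40), c(90, 100, 110)), c(0.3, 0.4))
  ctrl <- c(80, 100, 120)
  expect_equal(mean(colony_ratio(ctrl, ctrl)), 1)
  expect_equal(colony_ratio(c(0, 0), ctrl), c(0, 0))
  expect_error(colony_ratio(c(1, 2), c(0, 0)), "positive")
})

test_that("the expected double ratio is the product of single means", {
  expect_equal(expected_double_ratio(0.5, 0.6), 0.30)
  expect_equal(expected_double_ratio(1.0, 0.62), 0.62)
  expect_equal(expected_double_ratio(1, 1), 1)
  expect_equal(expected_double_ratio(c(0.4, 0.6), c(0.5, 0.7)), 0.5 * 0.6)
})

test_that("observed equal to expected is never called significant", {
  ctrl <- rep(100, 6)
  a <- rep(50, 6)
  b <- rep(60, 6)
  d <- rep(30, 6)  # exactly e_a * e_b * control
  res <- test_interaction(d, a, b, ctrl)
  expect_equal(res$difference, 0)
  expect_true(res$degenerate)
  expect_false(res$significant)
})

test_that("a clear alleviating interaction matches the t-test formula", {
  # with noise-free singles and control the expected ratio is the constant
  # 0.30, and the delta-method test reduces to the one-sample t-test
  ctrl <- rep(100, 6)
  a <- rep(50, 6)
  b <- rep(60, 6)
  d <- c(60, 62, 58)
  res <- test_interaction(d, a, b, ctrl)
  obs <- d / 100
  t_ref <- (mean(obs) - 0.30) / (sd(obs) / sqrt(3))
  expect_equal(res$expected, 0.30)
  expect_equal(res$statistic, t_ref, tolerance = 1e-9)
  expect_equal(res$df, 2, tolerance = 1e-9)
  expect_equal(res$p_value, 2 * pt(-abs(t_ref), 2), tolerance = 1e-9)
  expect_true(res$significant)
  expect_gt(res$difference, 0)  # more colonies than expected: alleviating

  one <- test_interaction(d, a, b, ctrl, method = "one_sample")
  expect_equal(one$statistic, t_ref, tolerance = 1e-9)
})

test_that("every statistic is invariant to count rescaling", {
  set.seed(10)
  ctrl <- rlnorm(6, log(100), 0.1)
  a <- rlnorm(6, log(40), 0.1)
  b <- rlnorm(6, log(55), 0.1)
  d <- rlnorm(6, log(30), 0.1)
  r1 <- test_interaction(d, a, b, ctrl)
  r2 <- test_interaction(d * 7, a * 7, b * 7, ctrl * 7)
  expect_equal(r2$observed_ratios, r1$observed_ratios)
  expect_equal(r2$expected, r1$expected)
  expect_equal(r2$statistic, r1$statistic, tolerance = 1e-12)
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-12)
})

test_that("table-level analysis resolves pairs against their singles", {
  cfg <- colony_sim_config(single_effects = c(a = 0.5, b = 0.6, c = 0.7),
                           interaction_gamma = c("a:b" = 2, "a:c" = 1),
                           cv = 0.05, seed = 3)
  counts <- generate_colony_counts(cfg)
  res <- epistasis_analysis(counts)
  expect_setequal(res$pair, c("a+b", "a+c"))
  expect_true(res$significant[res$pair == "a+b"])
  expect_gt(res$difference[res$pair == "a+b"], 0)
  # missing single is an explicit error
  broken <- counts[counts$condition != "single:c", ]
  expect_error(epistasis_analysis(broken), "missing single")
  expect_error(epistasis_analysis(counts[counts$condition != "control", ]),
               "control")
})

test_that("the delta test is calibrated and the one-sample form is not", {
  null_delta <- epistasis_calibration(n_pairs = 400, gamma = 1, seed = 2,
                                      method = "delta")
  expect_gt(null_delta$rejection_rate, 0.01)
  expect_lt(null_delta$rejection_rate, 0.09)
  null_one <- epistasis_calibration(n_pairs = 400, gamma = 1, seed = 2,
                                    method = "one_sample")
  expect_gt(null_one$rejection_rate, 0.15)
  power <- epistasis_calibration(n_pairs = 200, gamma = 2, seed = 3)
  expect_gte(power$rejection_rate, 0.8)
})
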