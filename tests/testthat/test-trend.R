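test_that("noiseless lines are recovered exactly from printed parameters", {
  # published intercept/slope pairs reused as generating values
  pairs <- rbind(
    c(0.77, 1.94e-4), c(0.81, 3.77e-4), c(0.78, 2.50e-4), c(0.76, 1.31e-4),
    c(0.80, 1.15e-4), c(0.80, 5.65e-5), c(0.80, 7.40e-5), c(0.78, 1.50e-4),
    c(0.79, -6.15e-5), c(0.78, 7.76e-5), c(0.80, 1.21e-4),
    c(1.42, 6.51e-3), c(1.40, 4.36e-3),
    c(0.30, 1.01e-3), c(-0.21, 8.33e-4), c(0.12, -9.81e-4))
  cal <- make_calendar(185, 158, seed = 9)
  for (i in seq_len(nrow(pairs))) {
    s <- simulate_outcome_series(cal, ground_truth(pairs[i, 1], pairs[i, 2]))
    fit <- fit_linear_trend(s)
    expect_equal(fit$intercept, pairs[i, 1], tolerance = 1e-10)
    expect_equal(fit$slope, pairs[i, 2], tolerance = 1e-10)
  }
})

test_that("degenerate series give zero slope or errors", {
  cal <- make_calendar(50, 40, seed = 2)
  s <- simulate_outcome_series(cal, ground_truth(intercept = 5))
  fit <- fit_linear_trend(s)
  expect_identical(fit$slope, 0)
  expect_identical(fit$F, 0)
  expect_identical(fit$p, 1)
  expect_error(fit_linear_trend(c(1, 2)), "at least 3")
  expect_error(fit_linear_trend(c(1, 2, 3), weeks = c(4, 4, 4)), "same week")
})

test_that("the slope estimate is unbiased on noisy lines", {
  cal <- make_calendar(185, 158, seed = 3)
  true_slope <- 1.94e-4
  tr <- ground_truth(0.77, true_slope)
  slopes <- vapply(1:500, function(i) {
    s <- simulate_outcome_series(cal, ground_truth(0.77, true_slope,
                                                   noise_sd = 0.02,
                                                   seed = 1000 + i))
    fit_linear_trend(s)$slope
  }, numeric(1))
  se_mean <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - true_slope), se_mean * 3)
  expect_lt(abs(mean(slopes) - true_slope) / sd(slopes), 1)
})

test_that("trend q-values reproduce the standalone adjustment exactly", {
  cal <- make_calendar(100, 80, seed = 4)
  series <- lapply(1:6, function(i)
    simulate_outcome_series(cal, ground_truth(slope = i * 1e-4,
                                              noise_sd = 0.05,
                                              seed = 20 + i)))
  names(series) <- paste0("n", 1:6)
  ts <- temporal_structure(series)
  expect_identical(ts$trend$q, adjust_pvalues(ts$trend$p, "fdr_bh"))
})

test_that("permutation p-values use the add-one estimator", {
  set.seed(5)
  y <- c(100, rnorm(29))          # statistic: first element is the max
  r <- permutation_null(y, function(v) v[1] == 100 && all(v[-1] < 100),
                        n_iter = 1000, seed = 6)
  # observed statistic TRUE (1); permutations almost never put 100 first
  expect_lt(r$p, 0.05)
  r2 <- permutation_null(rnorm(20), max, n_iter = 1000, seed = 7)
  expect_identical(r2$p, 1)        # max is permutation-invariant
  wk <- 0:19
  r3 <- permutation_null(wk + rnorm(20, sd = 1e-6),
                         function(v) abs(cor(v, wk)), n_iter = 1000,
                         seed = 8)
  expect_equal(r3$p, 1 / 1001, tolerance = 1e-12)
  expect_error(permutation_null(rnorm(10), mean, n_iter = 0), "at least 1")
})
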