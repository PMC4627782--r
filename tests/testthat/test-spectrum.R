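test_that("an annual sinusoid peaks at the annual frequency", {
  cal <- make_calendar(185, 158, seed = 1)
  s <- simulate_outcome_series(cal, ground_truth(annual_amplitude = 1))
  sp <- robust_spectrum(s, target_frequency = 1 / 52.18)
  expect_lt(abs(sp$peak_frequency - 0.0192), 5e-5)
  gt <- fisher_g_test(sp)
  expect_true(gt$target_is_peak)
  expect_lt(gt$p, 1e-6)
})

test_that("no single frequency dominates white noise persistently", {
  cal <- make_calendar(120, 100, seed = 2)
  hits <- matrix(0, 20, length(robust_spectrum(
    simulate_outcome_series(cal, ground_truth(noise_sd = 1, seed = 1)))$power))
  for (i in 1:20) {
    s <- simulate_outcome_series(cal, ground_truth(noise_sd = 1,
                                                   seed = 300 + i))
    sp <- robust_spectrum(s)
    hits[i, ] <- sp$power > 3 * stats::median(sp$power)
  }
  expect_lt(max(colMeans(hits)), 0.6)
})

test_that("constant series raise the flat-spectrum flag", {
  cal <- make_calendar(60, 50, seed = 3)
  s <- simulate_outcome_series(cal, ground_truth(intercept = 1))
  sp <- robust_spectrum(s)
  expect_true(sp$flat)
  expect_true(all(sp$power == 0))
  gt <- fisher_g_test(sp)
  expect_identical(gt$p, 1)
  expect_error(robust_spectrum(rnorm(5)), "at least 8")
})

test_that("with no missing weeks the spectrum matches the periodogram", {
  set.seed(4)
  for (i in 1:50) {
    n <- sample(c(32, 50, 64), 1)
    y <- rnorm(n)
    sp <- robust_spectrum(y, weeks = 0:(n - 1), total_weeks = n)
    pg <- bf_periodogram(y)
    m <- min(length(sp$power), length(pg))
    ratio <- sp$power[seq_len(m)] / pg[seq_len(m)]
    expect_lt(max(abs(ratio - ratio[1])), 1e-8)
  }
})

test_that("the Fisher g statistic and exact null behave as defined", {
  spec <- c(rep(1e-9, 10), 5, rep(1e-9, 10))
  gt <- fisher_g_test(spec)
  expect_gt(gt$g, 0.999)
  expect_lt(gt$p, 1e-10)

  flat <- rep(2, 25)
  expect_equal(fisher_g_test(flat)$g, 1 / 25, tolerance = 1e-12)

  # exact tail formula against direct Monte Carlo of exponential shares
  set.seed(5)
  m <- 10
  sims <- matrix(rexp(m * 40000), ncol = m)
  g_sim <- apply(sims, 1, function(v) max(v) / sum(v))
  for (x in c(0.25, 0.35, 0.5)) {
    expect_lt(abs(mean(g_sim > x) - rsnlong:::fisher_g_pvalue(x, m)),
              4 * sqrt(0.25 / 40000) + 0.003)
  }
})

test_that("rank transform and off-grid targets are handled", {
  cal <- make_calendar(100, 90, seed = 6)
  s <- simulate_outcome_series(cal, ground_truth(annual_amplitude = 1,
                                                 noise_sd = 0.1, seed = 7))
  sp <- robust_spectrum(s, target_frequency = 1 / 52.18,
                        rank_transform = TRUE)
  expect_false(is.na(sp$target_bin))
  expect_equal(sp$frequency[sp$target_bin], 1 / 52.18, tolerance = 1e-12)
  # snapping recorded when testing a spectrum without that exact bin
  sp2 <- robust_spectrum(s)
  gt <- fisher_g_test(sp2, target_frequency = 1 / 52.18)
  expect_false(is.na(gt$snapped_frequency))
})
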