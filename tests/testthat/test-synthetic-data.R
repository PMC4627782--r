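test_that("calendars have the right span, endpoints and reproducibility", {
  cal <- make_calendar(185, 158, seed = 7)
  expect_s3_class(cal, "session_calendar")
  expect_length(cal$observed_weeks, 158)
  expect_identical(cal$observed_weeks[1], 0L)
  expect_identical(max(cal$observed_weeks), 184L)
  expect_true(all(diff(cal$observed_weeks) >= 1))

  full <- make_calendar(10, 10)
  expect_identical(full$observed_weeks, 0:9)

  expect_identical(make_calendar(185, 158, seed = 3)$observed_weeks,
                   make_calendar(185, 158, seed = 3)$observed_weeks)
  expect_error(make_calendar(10, 11), "exceed")
  expect_error(make_calendar(10, 0), "at least 1")
})

test_that("noiseless series follow the closed-form mean function exactly", {
  cal <- make_calendar(185, 158, seed = 1)
  s <- simulate_outcome_series(cal, ground_truth(0.77, 1.94e-4))
  expected <- 0.77 + 1.94e-4 * cal$observed_weeks
  expect_equal(s$values, expected, tolerance = 1e-15)

  flat <- simulate_outcome_series(cal, ground_truth(intercept = 3))
  expect_true(all(flat$values == 3))

  seasonal <- simulate_outcome_series(
    cal, ground_truth(intercept = 1, slope = 2e-3, annual_amplitude = 0.5,
                      annual_phase = 0.7))
  t <- cal$observed_weeks
  expect_equal(seasonal$values,
               1 + 2e-3 * t + 0.5 * sin(2 * pi * t / 52.18 + 0.7),
               tolerance = 1e-15)
})

test_that("ARMA noise reproduces its theoretical autocovariance", {
  cal <- make_calendar(4000, 4000)
  s <- simulate_outcome_series(cal, ground_truth(ar = 0.6, noise_sd = 1,
                                                 seed = 21))
  emp <- stats::acf(s$values, lag.max = 3, plot = FALSE)$acf[2:4]
  expect_equal(emp, 0.6^(1:3), tolerance = 6 / sqrt(4000))

  s2 <- simulate_outcome_series(cal, ground_truth(ar = 0.5, ma = 0.4,
                                                  noise_sd = 2, seed = 22))
  theo <- stats::ARMAacf(ar = 0.5, ma = 0.4, lag.max = 2)[2:3]
  emp2 <- stats::acf(s2$values, lag.max = 2, plot = FALSE)$acf[2:3]
  expect_equal(emp2, unname(theo), tolerance = 6 / sqrt(4000))
})

test_that("generators are reproducible under a fixed seed and validated", {
  cal <- make_calendar(100, 80, seed = 5)
  tr <- ground_truth(ar = 0.4, noise_sd = 1, seed = 9)
  expect_identical(simulate_outcome_series(cal, tr)$values,
                   simulate_outcome_series(cal, tr)$values)
  expect_error(ground_truth(ar = 1.2), "non-stationary")
  expect_error(ground_truth(annual_period = 0), "positive")
  expect_error(ground_truth(ar = c(0.1, 0.1, 0.1, 0.1)), "at most 3")
})

test_that("simulated sessions have the advertised rank and spectra", {
  st <- toy_study(seed = 11, n_sources = 3, snr = Inf, baseline = 0)
  y <- rsnlong:::flatten_session(st$sessions[[1]], st$mask)
  expect_identical(qr(y)$rank, 3L)

  st2 <- toy_study(seed = 12, n_sources = 5, snr = 10, baseline = 0,
                   n_frames = 80)
  y2 <- rsnlong:::flatten_session(st2$sessions[[1]], st2$mask)
  ev <- eigen(crossprod(scale(t(y2), scale = FALSE)), symmetric = TRUE,
              only.values = TRUE)$values
  expect_gt(ev[5] / ev[6], 5)

  a <- toy_study(seed = 13, snr = 4)
  b <- toy_study(seed = 13, snr = 4)
  expect_identical(a$sessions, b$sessions)

  cal <- make_calendar(4, 4)
  expect_error(simulate_sessions(cal, n_sources = 50, n_frames = 40),
               "smaller")
})

test_that("motion, covariate and phantom generators honour their contracts", {
  expect_true(all(simulate_motion(20, drift_sd = 0, seed = 1) == 0))
  rp <- simulate_motion(50, drift_sd = 0.05, seed = 2)
  expect_identical(dim(rp), c(50L, 6L))
  expect_true(all(rp[1, ] == 0))

  cal <- make_calendar(120, 100, seed = 3)
  cov0 <- simulate_covariate(cal, amplitude = 0, noise_sd = 0)
  expect_true(stats::sd(cov0$value) == 0)
  expect_identical(nrow(cov0), 7L * 119L + 7L)

  ph <- simulate_phantom(cal, level = 500, noise_sd = 0)
  expect_true(all(ph$values == 500))
})
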