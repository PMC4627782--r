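test_that("framewise displacement follows its definition", {
  expect_true(all(framewise_displacement(matrix(0, 10, 6))$fd == 0))

  rot <- rbind(rep(0, 6), c(0, 0, 0, 1, 0, 0))
  expect_identical(framewise_displacement(rot)$fd, c(0, 50))

  trans <- rbind(rep(0, 6), c(1, 2, 3, 0, 0, 0))
  expect_identical(framewise_displacement(trans)$fd, c(0, 6))

  expect_error(framewise_displacement(matrix(0, 5, 5)), "6 columns")
  expect_error(framewise_displacement(matrix(0, 1, 6)), "at least 2")
})

test_that("FD matches the brute-force oracle and ignores constant offsets", {
  set.seed(11)
  for (i in 1:100) {
    rp <- matrix(rnorm(8 * 6, sd = 0.2), 8, 6)
    expect_equal(framewise_displacement(rp)$fd, bf_fd(rp),
                 tolerance = 1e-12)
    shifted <- sweep(rp, 2, rnorm(6), `+`)
    expect_equal(framewise_displacement(shifted)$fd,
                 framewise_displacement(rp)$fd, tolerance = 1e-12)
  }
})

test_that("realignment tables round-trip through the SPM text format", {
  rp <- simulate_motion(20, drift_sd = 0.05, seed = 3)
  path <- tempfile(fileext = ".txt")
  write.table(rp, path, row.names = FALSE, col.names = FALSE)
  rp2 <- read_realignment(path)
  expect_equal(unname(rp2), unname(rp), tolerance = 1e-12)
})

test_that("phantom series are trendless negative controls", {
  cal <- make_calendar(8, 6, seed = 5)
  vols <- lapply(1:6, function(i) array(7, dim = c(4, 4, 3, 5)))
  ph <- phantom_series(vols, cal)
  expect_true(all(ph$values == 7))
  fit <- fit_linear_trend(ph)
  expect_identical(fit$F, 0)

  cal2 <- make_calendar(120, 100, seed = 6)
  ps <- vapply(1:60, function(i) {
    s <- simulate_phantom(cal2, noise_sd = 5, seed = 600 + i)
    fit_linear_trend(s)$p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
  expect_error(phantom_series(list(), cal), "empty")
})

test_that("an injected scanner drift is recovered within its standard error", {
  cal <- make_calendar(185, 158, seed = 7)
  s <- simulate_outcome_series(cal, ground_truth(intercept = 1000,
                                                 slope = 0.05, noise_sd = 5,
                                                 seed = 8))
  chk <- confound_trend_check(s, n_perm = 500, seed = 9)
  expect_lt(abs(chk$slope - 0.05), 2 * chk$se_slope)
  expect_lt(chk$p_perm, 0.05)
})

test_that("weekly FD summaries align sessions to the calendar", {
  cal <- make_calendar(12, 9, seed = 10)
  motion <- lapply(1:9, function(i) simulate_motion(30, seed = i))
  fdw <- fd_weekly_series(motion, cal)
  expect_length(fdw$mean_fd$values, 9)
  expect_true(all(fdw$max_fd$values >= fdw$mean_fd$values))
})
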