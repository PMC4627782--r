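test_that("eta-squared matches hand-evaluated values and its error cases", {
  expect_identical(eta_squared(c(1, 5, 2, 7), c(1, 5, 2, 7)), 1)
  expect_equal(eta_squared(c(1, 2, 3), c(3, 2, 1)), 0)
  expect_equal(eta_squared(c(1, 2, 3), c(1, 2, 4)), 0.926829268292683,
               tolerance = 1e-12)
  expect_equal(eta_squared(c(1, 2, 3), c(1, 2, 4)),
               eta_squared(c(1, 2, 4), c(1, 2, 3)))
  expect_error(eta_squared(c(2, 2, 2), c(2, 2, 2)), "undefined")
})

test_that("eta-squared equals the brute-force oracle on random maps", {
  set.seed(101)
  for (i in 1:100) {
    a <- rnorm(40); b <- rnorm(40)
    expect_equal(eta_squared(a, b), bf_eta(a, b), tolerance = 1e-12)
    perm <- sample(40)
    expect_equal(eta_squared(a[perm], b[perm]), eta_squared(a, b),
                 tolerance = 1e-12)
  }
})

test_that("added noise can only lower expected spatial similarity", {
  set.seed(102)
  base <- rnorm(500)
  noise_levels <- c(0.1, 0.5, 1, 2)
  means <- vapply(noise_levels, function(s) {
    mean(vapply(1:40, function(i)
      eta_squared(base, base + rnorm(500, sd = s)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("overlap maps count supra-threshold sessions as percentages", {
  maps <- matrix(2, nrow = 6, ncol = 10)    # all sessions, all voxels z = 2
  expect_true(all(overlap_map(maps) == 100))

  half <- rbind(matrix(2, 79, 5), matrix(0, 79, 5))
  expect_true(all(overlap_map(half) == 50))

  low <- matrix(runif(80), 8, 10)
  expect_true(all(overlap_map(low, z_threshold = 2) == 0))
  expect_error(overlap_map(list()), "at least one")

  expect_equal(mean_map(list(c(0, 2), c(2, 4))), c(1, 3))
})

test_that("RMS magnitude follows its definition", {
  expect_identical(rms_percent_bold(rep(-3, 10)), 3)
  expect_equal(rms_percent_bold(c(3, 4)), sqrt(25 / 2), tolerance = 1e-15)
  expect_identical(rms_percent_bold(numeric(5)), 0)
  expect_error(rms_percent_bold(numeric(0)), "empty")
})

test_that("BNC matrices are correlations with flagged degeneracies", {
  t_idx <- seq(0, 2 * pi, length.out = 101)[-101]
  tc <- rbind(sin(t_idx), cos(t_idx), sin(t_idx), -sin(t_idx))
  m <- bnc_matrix(tc)
  expect_equal(m[1, 3], 1)
  expect_equal(m[1, 4], -1)
  expect_lt(abs(m[1, 2]), 1e-10)
  expect_identical(diag(unclass(m)), rep(1, 4))
  expect_equal(unclass(m), bf_cor_matrix(tc), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_warning(bnc_matrix(rbind(rep(1, 10), rnorm(10))), "constant")
})

test_that("outcome series from a fitted study line up with the calendar", {
  cal <- make_calendar(6, 5, seed = 2)
  st <- simulate_sessions(cal, n_sources = 3, dims = c(10, 10, 6),
                          n_frames = 50, snr = 10, seed = 3)
  fit <- gica(st, n_components = 3, seed = 1)
  out <- compute_outcomes(fit, cal)
  expect_length(out$eta_sq, 3)
  expect_length(out$bnc, 3)          # 3 choose 2
  expect_identical(out$eta_sq[[1]]$calendar$observed_weeks,
                   cal$observed_weeks)
  expect_true(all(vapply(out$eta_sq, function(s)
    all(s$values >= 0 & s$values <= 1), logical(1))))
  expect_true(all(vapply(out$rms_bold, function(s)
    all(s$values >= 0), logical(1))))
  expect_true(all(vapply(out$bnc, function(s)
    all(abs(s$values) <= 1), logical(1))))
})
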