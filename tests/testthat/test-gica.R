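test_that("MDL order selection recovers a constructed rank", {
  st <- toy_study(seed = 31, n_sources = 3, snr = 20, baseline = 0)
  y <- rsnlong:::flatten_session(st$sessions[[1]], st$mask)
  expect_identical(estimate_order_mdl(y), 3L)
  # agrees with an independent evaluation of the criterion over all orders
  lambda <- rsnlong:::time_cov_eigen(y)$values
  expect_identical(estimate_order_mdl(y), bf_mdl_order(lambda, ncol(y)))
})

test_that("MDL on pure white noise picks a trivial order, errors on constants", {
  set.seed(41)
  y <- matrix(rnorm(3000 * 40), 3000, 40)
  expect_lte(estimate_order_mdl(y), 2L)
  expect_error(estimate_order_mdl(matrix(1, 50, 10)), "constant")
})

test_that("PCA reduction captures variance and reconstructs exactly", {
  set.seed(42)
  y <- matrix(rnorm(400 * 6), 400, 6) %*% matrix(rnorm(6 * 30), 6, 30)
  red_full <- reduce_pca(y, 6)
  centred <- rsnlong:::time_cov_eigen(y)$centered
  expect_lt(max(abs(rsnlong:::reconstruct_pca(red_full) - t(centred))), 1e-8)

  y3 <- matrix(rnorm(400 * 3), 400, 3) %*% matrix(rnorm(3 * 30), 3, 30)
  expect_equal(reduce_pca(y3, 3)$explained_variance, 1, tolerance = 1e-12)
  expect_error(reduce_pca(y3, 31), "not in 1")
  # whitened output: unit covariance across voxels
  red <- reduce_pca(y, 4)
  expect_equal(tcrossprod(red$reduced) / (400 - 1), diag(4),
               tolerance = 1e-8)
})

test_that("default first-stage order is twice the group model order", {
  st <- toy_study(seed = 43, n_sources = 4, snr = 15, baseline = 0)
  fit <- gica(st, seed = 1)
  expect_identical(fit$session_k, 2L * fit$n_components)
})

test_that("Infomax separates super-Gaussian sources and is seed-stable", {
  set.seed(51)
  n <- 2000
  src <- rbind(rnorm(n)^3, rnorm(n)^3, rnorm(n)^3)  # super-Gaussian
  src <- src / apply(src, 1, sd)
  mixed <- matrix(rnorm(12), 4, 3) %*% src   # 4 observed mixtures
  red <- reduce_pca(t(mixed), 3)
  ica <- infomax_ica(red, 3, seed = 2)
  expect_true(ica$converged)
  expect_true(all(match_abs_cor(ica$sources, src) > 0.95))

  # identity mixing: sources recovered up to sign/permutation/scale
  red_id <- reduce_pca(t(rbind(src, rnorm(n) * 1e-3)), 3)
  ica_id <- infomax_ica(red_id, 3, seed = 3)
  expect_true(all(match_abs_cor(ica_id$sources, src) > 0.99))

  # two different seeds agree up to sign/permutation on clean data
  ica_b <- infomax_ica(red, 3, seed = 99)
  expect_true(all(match_abs_cor(ica$sources, ica_b$sources) > 0.99))
  # determinism for a fixed seed
  expect_identical(infomax_ica(red, 3, seed = 2)$sources, ica$sources)
  expect_error(infomax_ica(red, 5, seed = 1), "reduced dimension")
})

test_that("stability screen scores identifiable sources high, noise low", {
  st <- toy_study(seed = 61, n_sources = 3, snr = Inf, baseline = 0)
  mats <- lapply(st$sessions, rsnlong:::flatten_session, mask = st$mask)
  reds <- lapply(mats, reduce_pca, k = 3)   # noiseless sessions have rank 3
  grp <- concat_reduce(reds, 3)

  same <- stability_screen(grp, 3, n_runs = 2, seeds = c(7, 7))
  expect_true(all(same$stability_index > 0.95))

  # premise: these randomised runs all converge to the same decomposition
  runs <- lapply(1:4, function(s)
    suppressWarnings(infomax_ica(grp, 3, seed = s)))
  for (r in 2:4) {
    cc <- abs(stats::cor(t(runs[[1]]$sources), t(runs[[r]]$sources)))
    expect_true(all(apply(cc, 1, max) > 0.999))
  }
  stab <- stability_screen(grp, 3, n_runs = 4, seed = 1)
  expect_true(all(stab$stability_index > 0.9))

  set.seed(8)
  noise <- matrix(rnorm(7 * 800), 7, 800)
  noise_red <- reduce_pca(t(noise), 5)
  nstab <- stability_screen(noise_red, 5, n_runs = 4, seed = 11)
  expect_true(any(nstab$stability_index < nstab$threshold))
  expect_error(stability_screen(grp, 3, n_runs = 1), "at least 2")
})

test_that("GICA3 reproduces the aggregate map and the true time courses", {
  st <- toy_study(seed = 71, n_sources = 4, snr = Inf, baseline = 0,
                  n_sessions = 4)
  fit <- gica(st, n_components = 4, seed = 2)
  br <- fit$backrecon
  mean_maps <- Reduce(`+`, br$session_maps) / br$n_sessions
  expect_lt(max(abs(mean_maps - br$aggregate_maps)), 1e-6)

  for (i in seq_len(br$n_sessions)) {
    m <- match_abs_cor(t(fit$session_timecourses[[i]]),
                       t(st$true_timecourses[[i]]))
    expect_true(all(m > 0.95))
  }

  # with noise the identity still holds (it is algebraic)
  stn <- toy_study(seed = 72, n_sources = 4, snr = 5, n_sessions = 4)
  fitn <- gica(stn, n_components = 4, seed = 2)
  mean_n <- Reduce(`+`, fitn$backrecon$session_maps) /
    fitn$backrecon$n_sessions
  expect_lt(max(abs(mean_n - fitn$backrecon$aggregate_maps)), 1e-3)

  # a single-session group backreconstructs to the aggregate map itself
  one <- gica(list(rsnlong:::flatten_session(st$sessions[[1]], st$mask)),
              n_components = 4, session_k = 8, seed = 3)
  expect_lt(max(abs(one$backrecon$session_maps[[1]] -
                      one$backrecon$aggregate_maps)), 1e-8)
})

test_that("map z-scoring and percent-signal scaling follow their algebra", {
  z <- zscore_map(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(stats::sd(z), 1)
  already <- as.numeric(scale(rnorm(50)))
  expect_equal(zscore_map(already), already, tolerance = 1e-12)
  expect_error(zscore_map(rep(2, 10)), "constant")

  tc <- sin(seq(0, 4 * pi, length.out = 200))
  scaled <- scale_percent_signal(tc, rep(500, 20))
  expect_equal(rms_percent_bold(scaled),
               100 * sqrt(mean(tc^2)) / 500, tolerance = 1e-12)
  expect_error(scale_percent_signal(tc, rep(0, 10)), "positive")
})

test_that("the chain is invariant to voxel-order permutation", {
  st <- toy_study(seed = 81, n_sources = 3, snr = 10, baseline = 0)
  mats <- lapply(st$sessions, rsnlong:::flatten_session, mask = st$mask)
  fit <- gica(mats, n_components = 3, session_k = 6, seed = 4)
  set.seed(9)
  perm <- sample(nrow(mats[[1]]))
  fit_p <- gica(lapply(mats, function(m) m[perm, ]),
                n_components = 3, session_k = 6, seed = 4)
  expect_lt(max(abs(fit_p$aggregate_maps - fit$aggregate_maps[, perm])),
            1e-6)
})

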