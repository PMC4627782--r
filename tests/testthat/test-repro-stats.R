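test_that("CV follows its definition and flags near-zero means", {
  expect_equal(as.numeric(cv(rep(7, 10))), 0)
  x <- c(8, 10, 12)
  expect_equal(as.numeric(cv(x)), 100 * sd(x) / mean(x), tolerance = 1e-12)
  expect_error(cv(c(-1, 1)), "mean is zero")
  set.seed(1)
  noisy <- rnorm(50, mean = 0.1, sd = 1)
  expect_true(attr(cv(noisy), "near_zero_mean"))
  expect_false(attr(cv(c(8, 10, 12)), "near_zero_mean"))
  set.seed(2)
  for (i in 1:100) {
    v <- rnorm(20, mean = 5)
    expect_equal(as.numeric(cv(v)), bf_cv(v), tolerance = 1e-12)
  }
})

test_that("the equal-variance F-test matches its closed form", {
  x <- rnorm(30)
  r <- variance_ratio_test(x, x)
  expect_equal(r$F, 1)
  expect_equal(r$p, 1)

  set.seed(3)
  a <- rnorm(40); a <- (a - mean(a)) / sd(a) * 2   # var 4
  b <- rnorm(25); b <- (b - mean(b)) / sd(b)       # var 1
  r2 <- variance_ratio_test(a, b)
  expect_equal(r2$F, 4, tolerance = 1e-12)
  expect_equal(r2$p, 2 * min(pf(4, 39, 24), 1 - pf(4, 39, 24)),
               tolerance = 1e-12)
  expect_error(variance_ratio_test(1, rnorm(5)), "at least 2")
  expect_error(variance_ratio_test(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("the F-test holds its nominal level under the null", {
  set.seed(4)
  rej <- mean(vapply(1:2000, function(i) {
    variance_ratio_test(rnorm(30), rnorm(30))$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.05 - 1.96 * sqrt(0.05 * 0.95 / 2000))
  expect_lt(rej, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 2000))
})

test_that("p-value adjustment matches hand-computed and oracle values", {
  expect_equal(adjust_pvalues(0.03, "fdr_bh"), 0.03)
  expect_equal(adjust_pvalues(0.03, "bonferroni"), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "fdr_bh"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(rep(0.01, 4), "bonferroni"), rep(0.04, 4))
  expect_error(adjust_pvalues(c(0.1, 1.2)), "0, 1")

  set.seed(5)
  for (i in 1:100) {
    p <- runif(sample(3:20, 1))
    q <- adjust_pvalues(p, "fdr_bh")
    expect_equal(q, bf_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q[order(p)] == cummax(q[order(p)])))
  }
})

test_that("halved longitudinal SD is flagged with good power at study sizes", {
  set.seed(6)
  hits <- vapply(1:200, function(i) {
    lon <- replicate(3, rnorm(158, sd = 0.5), simplify = FALSE)
    ref <- replicate(3, rnorm(20, sd = 1), simplify = FALSE)
    names(lon) <- names(ref) <- paste0("n", 1:3)
    cmp <- compare_reproducibility(lon, ref, method = "bonferroni")
    cmp$direction[1] == "longitudinal-more-reproducible"
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})

test_that("summary tables carry mean, SD, CV and the subset option", {
  series <- list(a = c(1, 2, 3, 4), b = c(10, 10, 10, 12))
  tab <- repro_summary(series)
  expect_identical(tab$network, c("a", "b"))
  expect_equal(tab$cv[1], 100 * sd(series$a) / mean(series$a))
  sub <- repro_summary(series, subset_first = 3)
  expect_equal(sub$mean[1], 2)
})
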