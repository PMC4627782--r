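#' Linear trend of a weekly outcome series
#'
#' Ordinary least squares of the outcome values on the calendar week index
#' (weeks with missed scans simply contribute no rows).  The slope's
#' significance is assessed by the F statistic on `(1, n - 2)` degrees of
#' freedom.
#'
#' @param series An `outcome_series`, or a numeric vector with `weeks`.
#' @param weeks Week indices for a plain numeric `series`.
#' @return An object of class `trend_fit`: `intercept`, `slope` (per week),
#'   `F`, `p`, `se_slope`, `n`, `fitted`, `residuals`, `weeks`, `values`.
#' @examples
#' cal <- make_calendar(185, 158, seed = 1)
#' s <- simulate_outcome_series(cal, ground_truth(0.77, 1.94e-4))
#' fit_linear_trend(s)
#' @export
fit_linear_trend <- function(series, weeks = NULL) {
  y <- series_values(series)
  t <- weeks %||% series_weeks(series)
  stopifnot(length(y) == length(t), all(is.finite(y)), all(is.finite(t)))
  n <- length(y)
  if (n < 3L) stop_invalid("need at least 3 observed weeks")
  sxx <- sum((t - mean(t))^2)
  if (sxx == 0) stop_invalid("all observations are in the same week")
  slope <- sum((t - mean(t)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(t)
  fitted <- intercept + slope * t
  res <- y - fitted
  rss <- sum(res^2)
  if (rss <= 0) {                     # perfect fit
    fstat <- if (slope == 0) 0 else Inf
    p <- if (slope == 0) 1 else 0
    se <- 0
  } else {
    s2 <- rss / (n - 2L)
    se <- sqrt(s2 / sxx)
    fstat <- (slope / se)^2
    p <- stats::pf(fstat, 1, n - 2L, lower.tail = FALSE)
  }
  structure(
    list(intercept = intercept, slope = slope, F = fstat, p = p,
         se_slope = se, n = n, fitted = fitted, residuals = res,
         weeks = t, values = y),
    class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("Linear trend (value ~ week)\n")
  cat(sprintf("  intercept %.4g, slope %.4g / week\n", x$intercept, x$slope))
  cat(sprintf("  F(1, %d) = %.4g, p = %.3g\n", x$n - 2L, x$F, x$p))
  invisible(x)
}

#' @export
coef.trend_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.trend_fit <- function(object, ...) object$residuals

#' @export
fitted.trend_fit <- function(object, ...) object$fitted

#' @export
plot.trend_fit <- function(x, ...) {
  graphics::plot(x$weeks, x$values, pch = 16, cex = 0.6,
                 xlab = "week", ylab = "value", ...)
  graphics::abline(x$intercept, x$slope, col = "red3", lwd = 2)
  invisible(x)
}

#' Permutation null for an arbitrary series statistic
#'
#' Re-evaluates `statistic_fn` on `n_iter` random permutations of the values
#' across the observed weeks and returns the add-one permutation p-value
#' `(1 + #{permuted >= observed}) / (1 + n_iter)` -- the guard against
#' spurious parametric significance.
#'
#' @param series An `outcome_series` or numeric vector.
#' @param statistic_fn Function of a numeric vector returning a scalar;
#'   larger values count as more extreme (pass e.g. an absolute statistic).
#' @param n_iter Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @return List with `p`, `observed`, `n_iter`.
#' @export
permutation_null <- function(series, statistic_fn, n_iter = 1000L,
                             seed = NULL) {
  y <- series_values(series)
  if (length(y) < 3L) stop_invalid("need at least 3 observations")
  if (n_iter < 1L) stop_invalid("`n_iter` must be at least 1")
  observed <- statistic_fn(y)
  perm <- with_seed(seed, vapply(seq_len(n_iter), function(i)
    statistic_fn(sample(y)), numeric(1)))
  list(p = (1 + sum(perm >= observed)) / (1 + n_iter),
       observed = observed, n_iter = as.integer(n_iter))
}
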