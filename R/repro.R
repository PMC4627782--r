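#' Coefficient of variation
#'
#' Dispersion relative to the mean, `100 * sd / mean` (sample SD, n-1
#' denominator), the reproducibility summary used for weekly outcome series.
#' CV is artificially inflated when the mean is close to zero; when
#' `|mean| < 2 * sd` the result carries a `near_zero_mean` attribute set to
#' `TRUE` so downstream reports can surface the caveat (the SD should then be
#' reported alongside).
#'
#' @param x Numeric vector, length at least 2.
#' @return The CV in percent, with a `near_zero_mean` attribute.
#' @examples
#' cv(c(8, 10, 12))
#' @export
cv <- function(x) {
  stopifnot(length(x) >= 2L, all(is.finite(x)))
  m <- mean(x)
  if (m == 0) stop_invalid("undefined CV: mean is zero")
  s <- stats::sd(x)
  structure(100 * s / m, near_zero_mean = abs(m) < 2 * s)
}

#' Equal-variance F-test between two outcome series
#'
#' Tests whether two datasets' outcome series have equal variance:
#' `F = var(x) / var(y)` with a two-sided p-value from the F distribution on
#' `(n_x - 1, n_y - 1)` degrees of freedom.  Used to compare the longitudinal
#' single-subject dataset's reproducibility against a multi-session reference
#' dataset.
#'
#' @param x,y Numeric vectors (e.g. longitudinal and reference series), both
#'   of length at least 2 and with positive variance.
#' @return An object of class `variance_test`: `F`, `df`, `p`.
#' @export
variance_ratio_test <- function(x, y) {
  x <- series_values(x); y <- series_values(y)
  if (length(x) < 2L || length(y) < 2L)
    stop_invalid("both series need at least 2 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop_invalid("undefined F-test: zero variance")
  ht <- stats::var.test(x, y)
  structure(
    list(F = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value),
    class = "variance_test")
}

#' @export
print.variance_test <- function(x, ...) {
  cat(sprintf("Equal-variance F-test: F = %.4g on (%d, %d) df, p = %.3g\n",
              x$F, x$df[1], x$df[2], x$p))
  invisible(x)
}

#' Multiplicity correction of p-values
#'
#' Benjamini--Hochberg step-up FDR or Bonferroni adjustment, applied per
#' outcome measure across the family of tested networks (or network pairs).
#'
#' @param p Numeric vector of p-values in \eqn{[0, 1]}.
#' @param method `"fdr_bh"` or `"bonferroni"`.
#' @return Adjusted p-values (same length, monotone, capped at 1).
#' @export
adjust_pvalues <- function(p, method = c("fdr_bh", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop_invalid("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = switch(method, fdr_bh = "BH",
                                     bonferroni = "bonferroni"))
}

#' Reproducibility summary table for a set of outcome series
#'
#' Mean, SD and CV per network for one dataset, optionally restricted to the
#' first `subset_first` sessions (the robustness check matching a smaller
#' reference dataset's session count).
#'
#' @param series Named list of `outcome_series` (or numeric vectors), one per
#'   network.
#' @param subset_first Optional count: use only the first N sessions.
#' @return A data frame with `network`, `mean`, `sd`, `cv`,
#'   `near_zero_mean`.
#' @export
repro_summary <- function(series, subset_first = NULL) {
  vals <- lapply(series, series_values)
  if (!is.null(subset_first))
    vals <- lapply(vals, function(v) utils::head(v, subset_first))
  cvs <- lapply(vals, cv)
  data.frame(
    network = names(series) %||% seq_along(series),
    mean = vapply(vals, mean, numeric(1)),
    sd = vapply(vals, stats::sd, numeric(1)),
    cv = vapply(cvs, as.numeric, numeric(1)),
    near_zero_mean = vapply(cvs, function(z)
      isTRUE(attr(z, "near_zero_mean")), logical(1)),
    row.names = NULL)
}

#' Compare reproducibility between two datasets across networks
#'
#' Runs the equal-variance F-test per network between a longitudinal dataset
#' and a reference dataset, corrects across the family of networks, and
#' labels the direction of any significant difference.
#'
#' @param longitudinal,reference Named lists of series (same names/order).
#' @param method Correction method; Bonferroni by default for the F-test
#'   family.
#' @param alpha Significance level applied to the corrected p-values.
#' @param subset_first Optional count: restrict the longitudinal series to
#'   their first N sessions before testing.
#' @return A data frame with `network`, `F`, `p`, `q`, `direction`
#'   (`"longitudinal-more-reproducible"`, `"longitudinal-less-reproducible"`
#'   or `"n.s."`).
#' @export
compare_reproducibility <- function(longitudinal, reference,
                                    method = c("bonferroni", "fdr_bh"),
                                    alpha = 0.05, subset_first = NULL) {
  method <- match.arg(method)
  stopifnot(length(longitudinal) == length(reference))
  lv <- lapply(longitudinal, series_values)
  if (!is.null(subset_first))
    lv <- lapply(lv, function(v) utils::head(v, subset_first))
  rv <- lapply(reference, series_values)
  tests <- Map(variance_ratio_test, lv, rv)
  p <- vapply(tests, function(t) t$p, numeric(1))
  q <- adjust_pvalues(p, method)
  f <- vapply(tests, function(t) t$F, numeric(1))
  direction <- ifelse(q >= alpha, "n.s.",
                      ifelse(f < 1, "longitudinal-more-reproducible",
                             "longitudinal-less-reproducible"))
  data.frame(network = names(longitudinal) %||% seq_along(longitudinal),
             F = f, p = p, q = q, direction = direction, row.names = NULL)
}
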