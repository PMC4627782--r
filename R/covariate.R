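#' Correlate an outcome series with a dated external covariate
#'
#' Matches a daily covariate series (e.g. recorded daily maximum
#' temperature) to each session's acquisition date by nearest day, computes
#' the Pearson correlation with the weekly outcome values, and assesses it
#' with a permutation test (statistic `|r|`, add-one p-value), the guard the
#' seasonal analysis uses against spurious correlation.
#'
#' @param series An `outcome_series` (its calendar supplies the session
#'   dates).
#' @param covariate Data frame with `date` (Date) and `value` columns, one
#'   row per day.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed for the permutations.
#' @return An object of class `covariate_test`: `r`, `p_perm`, `n_pairs`,
#'   `matched` (the matched covariate values).
#' @export
correlate_covariate <- function(series, covariate, n_perm = 1000L,
                                seed = NULL) {
  stopifnot(inherits(series, "outcome_series"),
            is.data.frame(covariate), all(c("date", "value") %in%
                                            names(covariate)))
  dates <- series$calendar$dates
  cd <- as.Date(covariate$date)
  span <- range(cd)
  keep <- dates >= span[1] - 3 & dates <= span[2] + 3
  if (sum(keep) < 3L)
    stop_invalid("fewer than 3 sessions fall within the covariate's dates")
  y <- series$values[keep]
  matched <- covariate$value[
    vapply(dates[keep], function(d) which.min(abs(cd - d)), integer(1))]
  r <- stats::cor(y, matched)
  perm <- permutation_null(y, function(v) abs(stats::cor(v, matched)),
                           n_iter = n_perm, seed = seed)
  structure(
    list(r = r, p_perm = perm$p, n_pairs = length(y), matched = matched),
    class = "covariate_test")
}

#' @export
print.covariate_test <- function(x, ...) {
  cat(sprintf("Covariate correlation: r = %.3f over %d matched sessions\n",
              x$r, x$n_pairs))
  cat(sprintf("  permutation p = %.3g\n", x$p_perm))
  invisible(x)
}
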