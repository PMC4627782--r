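#' Weekly session calendar with missing weeks
#'
#' Builds the acquisition calendar of a longitudinal weekly imaging study: a
#' study span of `total_weeks` calendar weeks of which `n_observed` carry an
#' acquired session.  Week indices count calendar weeks from the first session
#' (week 0), so missed scans leave gaps in the index sequence rather than
#' compressing it.  When `n_observed >= 2` the first and last weeks are always
#' observed (the study span is anchored at both ends) and the missing weeks are
#' drawn uniformly at random from the interior.
#'
#' @param total_weeks Number of calendar weeks spanned by the study.
#' @param n_observed Number of weeks with an acquired session
#'   (`1 <= n_observed <= total_weeks`).
#' @param seed Optional integer seed making the missing-week pattern
#'   reproducible.
#' @param start_date Date of the week-0 session; used to attach calendar dates
#'   to sessions (daily covariates are matched against these).
#'
#' @return An object of class `session_calendar`: a list with `total_weeks`,
#'   `observed_weeks` (strictly increasing 0-based integer week indices),
#'   `n_observed`, `start_date` and `dates`.
#' @examples
#' cal <- make_calendar(185, 158, seed = 1)
#' cal$n_observed
#' @export
make_calendar <- function(total_weeks, n_observed = total_weeks, seed = NULL,
                          start_date = as.Date("2009-12-07")) {
  stopifnot(length(total_weeks) == 1L, is.finite(total_weeks),
            total_weeks >= 1, total_weeks == round(total_weeks),
            length(n_observed) == 1L, is.finite(n_observed),
            n_observed == round(n_observed))
  if (n_observed < 1)
    stop_invalid("`n_observed` must be at least 1")
  if (n_observed > total_weeks)
    stop_invalid("`n_observed` (%d) cannot exceed `total_weeks` (%d)",
                 n_observed, total_weeks)
  start_date <- as.Date(start_date)
  observed <- if (n_observed == total_weeks) {
    seq_len(total_weeks) - 1L
  } else if (n_observed >= 2L) {
    interior <- with_seed(seed, sort(sample(seq_len(total_weeks - 2L),
                                            n_observed - 2L)))
    c(0L, as.integer(interior), total_weeks - 1L)
  } else {
    0L
  }
  structure(
    list(total_weeks = as.integer(total_weeks),
         observed_weeks = as.integer(observed),
         n_observed = as.integer(n_observed),
         start_date = start_date,
         dates = start_date + 7L * as.integer(observed)),
    class = "session_calendar")
}

#' @export
print.session_calendar <- function(x, ...) {
  cat(sprintf("Session calendar: %d of %d weeks observed (%d missed)\n",
              x$n_observed, x$total_weeks, x$total_weeks - x$n_observed))
  cat(sprintf("  week 0 on %s, week %d on %s\n",
              format(x$start_date), x$total_weeks - 1L,
              format(x$start_date + 7L * (x$total_weeks - 1L))))
  invisible(x)
}

# 0/1 mask over the full weekly grid
observed_mask <- function(calendar) {
  m <- logical(calendar$total_weeks)
  m[calendar$observed_weeks + 1L] <- TRUE
  m
}
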