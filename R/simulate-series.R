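#' Simulate a weekly outcome-measure series on a session calendar
#'
#' Evaluates the generating model of a [ground_truth()] on the full weekly
#' grid of a calendar -- linear trend plus annual sinusoid plus ARMA noise --
#' and keeps the values at the observed weeks only.  The ARMA noise is
#' generated by direct recursion with a 500-sample burn-in so the retained
#' stretch is (practically) stationary.  The ground truth is attached to the
#' result so recovery can be scored later.
#'
#' @param calendar A [make_calendar()] object.
#' @param truth A [ground_truth()] object.
#' @param measure_kind Label for the outcome measure the series represents
#'   (`"eta_sq"`, `"rms_bold"`, `"bnc"`, or any other tag).
#' @param network Network (or network-pair) label.
#'
#' @return An object of class `outcome_series`: list with `calendar`, `values`
#'   (one per observed week), `measure_kind`, `network`, `truth`.
#' @examples
#' cal <- make_calendar(185, 158, seed = 1)
#' s <- simulate_outcome_series(cal, ground_truth(0.77, 1.94e-4), "eta_sq")
#' head(as.data.frame(s))
#' @export
simulate_outcome_series <- function(calendar, truth,
                                    measure_kind = "eta_sq", network = NA) {
  stopifnot(inherits(calendar, "session_calendar"),
            inherits(truth, "ground_truth"))
  t_full <- seq_len(calendar$total_weeks) - 1
  mean_fn <- truth$intercept + truth$slope * t_full +
    truth$annual_amplitude *
      sin(2 * pi * t_full / truth$annual_period + truth$annual_phase)
  noise <- if (truth$noise_sd > 0) {
    with_seed(truth$seed,
              arma_recursion(calendar$total_weeks, truth$ar, truth$ma,
                             truth$noise_sd))
  } else {
    numeric(calendar$total_weeks)
  }
  values <- (mean_fn + noise)[calendar$observed_weeks + 1L]
  outcome_series(values, calendar, measure_kind, network, truth)
}

# Direct ARMA(p,q) recursion in the phi/theta convention with `burn` samples
# of burn-in discarded.
arma_recursion <- function(n, ar, ma, sd, burn = 500L) {
  p <- length(ar); q <- length(ma)
  total <- n + burn
  e <- stats::rnorm(total, sd = sd)
  y <- numeric(total)
  for (t in seq_len(total)) {
    v <- e[t]
    if (p) for (j in seq_len(min(p, t - 1L))) v <- v + ar[j] * y[t - j]
    if (q) for (j in seq_len(min(q, t - 1L))) v <- v + ma[j] * e[t - j]
    y[t] <- v
  }
  y[(burn + 1L):total]
}

#' Construct an outcome series
#'
#' Low-level constructor pairing per-session values with a calendar; used by
#' the simulator and by the outcome-measure stage.
#'
#' @param values Numeric vector, one value per observed week.
#' @param calendar A [make_calendar()] object with `n_observed ==
#'   length(values)`.
#' @param measure_kind,network Labels (see [simulate_outcome_series()]).
#' @param truth Optional [ground_truth()] attached for bookkeeping.
#' @return An object of class `outcome_series`.
#' @export
outcome_series <- function(values, calendar, measure_kind = "value",
                           network = NA, truth = NULL) {
  stopifnot(inherits(calendar, "session_calendar"))
  values <- as.numeric(values)
  if (length(values) != calendar$n_observed)
    stop_invalid("series has %d values but the calendar has %d observed weeks",
                 length(values), calendar$n_observed)
  structure(
    list(values = values, calendar = calendar, measure_kind = measure_kind,
         network = network, truth = truth),
    class = "outcome_series")
}

#' @export
print.outcome_series <- function(x, ...) {
  lab <- if (all(is.na(x$network))) "" else
    paste0(" [", paste(x$network, collapse = "/"), "]")
  cat(sprintf("Weekly outcome series '%s'%s: %d sessions over %d weeks\n",
              x$measure_kind, lab, x$calendar$n_observed,
              x$calendar$total_weeks))
  cat(sprintf("  mean %.4g, sd %.4g\n", mean(x$values), stats::sd(x$values)))
  if (!is.null(x$truth)) cat("  (simulated; ground truth attached)\n")
  invisible(x)
}

#' @export
as.data.frame.outcome_series <- function(x, ...) {
  data.frame(week_index = x$calendar$observed_weeks,
             date_iso = format(x$calendar$dates),
             value = x$values)
}

#' @export
plot.outcome_series <- function(x, ...) {
  graphics::plot(x$calendar$observed_weeks, x$values, type = "b", pch = 16,
                 cex = 0.6, xlab = "week", ylab = x$measure_kind, ...)
  invisible(x)
}

#' Simulate a daily covariate series (e.g. daily maximum temperature)
#'
#' Generates a daily annual sinusoid plus white noise across the calendar
#' span, with calendar-aligned dates, emulating an external seasonal
#' covariate such as the daily maximum temperature recorded at the scanner's
#' city.
#'
#' @param calendar A [make_calendar()] object (fixes the date span).
#' @param mean,amplitude Mean level and annual amplitude, in covariate units
#'   (defaults emulate a mid-Atlantic daily maximum temperature in Celsius).
#' @param phase Phase in radians; the default puts the minimum in
#'   mid-January for a study starting in early December.
#' @param noise_sd Day-to-day noise standard deviation.
#' @param period_days Seasonal period in days.
#' @param seed Optional integer seed.
#' @return A data frame with `date` and `value`, one row per day.
#' @export
simulate_covariate <- function(calendar, mean = 17, amplitude = 12,
                               phase = -pi / 2 - 2 * pi * 40 / 365.25,
                               noise_sd = 4, period_days = 365.25,
                               seed = NULL) {
  stopifnot(inherits(calendar, "session_calendar"), period_days > 0)
  days <- seq(0L, 7L * (calendar$total_weeks - 1L) + 6L)
  value <- mean + amplitude * sin(2 * pi * days / period_days + phase)
  if (noise_sd > 0)
    value <- value + with_seed(seed, stats::rnorm(length(days), sd = noise_sd))
  data.frame(date = calendar$start_date + days, value = value)
}

#' Simulate a realignment-parameter (motion) table
#'
#' Random-walk motion traces in the SPM realignment convention: three
#' translations in millimetres followed by three rotations in radians, one
#' row per frame, first frame at zero.
#'
#' @param n_frames Number of frames.
#' @param drift_sd Per-frame standard deviation of the translational random
#'   walk (mm).
#' @param rot_sd Per-frame standard deviation of the rotational random walk
#'   (radians); defaults to `drift_sd / 50` so rotations displace the
#'   50 mm-radius head surface about as much as the translations.
#' @param seed Optional integer seed.
#' @return A numeric `n_frames x 6` matrix with columns
#'   `tx, ty, tz, rx, ry, rz`.
#' @export
simulate_motion <- function(n_frames, drift_sd = 0.02, rot_sd = drift_sd / 50,
                            seed = NULL) {
  stopifnot(n_frames >= 1)
  sds <- rep(c(drift_sd, rot_sd), each = 3L)
  rp <- with_seed(seed, {
    steps <- matrix(stats::rnorm(6L * n_frames), n_frames, 6L)
    steps <- sweep(steps, 2L, sds, `*`)
    steps[1L, ] <- 0
    apply(steps, 2L, cumsum)
  })
  rp <- matrix(rp, n_frames, 6L)
  colnames(rp) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  rp
}

#' Simulate a weekly phantom-intensity series
#'
#' The scanner-stability phantom is trendless by construction: a constant
#' intensity level plus white noise, one value per observed week.  It serves
#' as a negative control for the trend analysis.
#'
#' @param calendar A [make_calendar()] object.
#' @param level Constant mean intensity (scanner units).
#' @param noise_sd Week-to-week noise standard deviation.
#' @param seed Optional integer seed.
#' @return An `outcome_series` with `measure_kind = "phantom"`.
#' @export
simulate_phantom <- function(calendar, level = 1000, noise_sd = 5,
                             seed = NULL) {
  v <- level + with_seed(seed, stats::rnorm(calendar$n_observed,
                                            sd = noise_sd))
  outcome_series(v, calendar, measure_kind = "phantom",
                 truth = ground_truth(intercept = level, noise_sd = noise_sd,
                                      seed = seed))
}
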