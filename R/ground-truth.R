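#' Generating model for a weekly outcome series
#'
#' Bundles the parameters of the generating model used by
#' [simulate_outcome_series()]:
#' \deqn{y_t = \beta_0 + \beta_1 t + A \sin(2\pi t / P + \phi) + \epsilon_t}
#' with \eqn{t} the calendar week index and \eqn{\epsilon_t} ARMA(p,q) noise
#' driven by Gaussian innovations of standard deviation `noise_sd`.
#'
#' AR and MA coefficients use the standard textbook convention also used by
#' [stats::arima()]: \eqn{\epsilon_t = \sum_j \phi_j \epsilon_{t-j} + e_t +
#' \sum_j \theta_j e_{t-j}}.  Fitted persistence models ([fit_arma()]) report
#' coefficients in the flipped AR-sign convention
#' \eqn{y_t + a_1 y_{t-1} + \dots = e_t + c_1 e_{t-1} + \dots}, so a
#' generating `ar = 0.5` corresponds to a fitted `a1 = -0.5`.
#'
#' @param intercept,slope Linear trend, in outcome units and outcome units per
#'   week.
#' @param annual_amplitude Amplitude of the annual sinusoid (outcome units).
#' @param annual_phase Phase of the annual sinusoid (radians).
#' @param annual_period Period of the seasonal component, in weeks; the
#'   default 52.18 is one calendar year (365.25 / 7 days).
#' @param ar,ma Autoregressive and moving-average coefficients of the noise
#'   (at most 3 each); the AR polynomial must be stationary and the MA
#'   polynomial invertible.
#' @param noise_sd Innovation standard deviation (outcome units).
#' @param seed Optional integer seed stored with the truth and used when the
#'   series is simulated.
#'
#' @return An object of class `ground_truth`.
#' @examples
#' ground_truth(intercept = 0.77, slope = 1.94e-4, noise_sd = 0.02)
#' @export
ground_truth <- function(intercept = 0, slope = 0, annual_amplitude = 0,
                         annual_phase = 0, annual_period = 52.18,
                         ar = numeric(), ma = numeric(), noise_sd = 0,
                         seed = NULL) {
  stopifnot(length(annual_period) == 1L, is.finite(annual_period))
  if (annual_period <= 0) stop_invalid("`annual_period` must be positive")
  if (length(ar) > 3L || length(ma) > 3L)
    stop_invalid("at most 3 AR and 3 MA coefficients are supported")
  if (length(ar) && !poly_stationary(ar))
    stop_invalid("AR coefficients are non-stationary (root inside unit circle)")
  if (length(ma) && !poly_stationary(ma))
    stop_invalid("MA coefficients are non-invertible (root inside unit circle)")
  if (noise_sd < 0) stop_invalid("`noise_sd` must be non-negative")
  structure(
    list(intercept = intercept, slope = slope,
         annual_amplitude = annual_amplitude, annual_phase = annual_phase,
         annual_period = annual_period,
         ar = as.numeric(ar), ma = as.numeric(ma),
         noise_sd = noise_sd, seed = seed),
    class = "ground_truth")
}

# TRUE when all roots of 1 - coef[1] z - coef[2] z^2 - ... lie outside the
# unit circle (stationarity of an AR part / invertibility of an MA part in
# the phi/theta convention).
poly_stationary <- function(coef) {
  if (!length(coef)) return(TRUE)
  all(Mod(polyroot(c(1, -coef))) > 1)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Generating model for a weekly outcome series\n")
  cat(sprintf("  mean: %.4g + %.4g * week", x$intercept, x$slope))
  if (x$annual_amplitude != 0)
    cat(sprintf(" + %.4g * sin(2*pi*week/%.4g + %.3g)",
                x$annual_amplitude, x$annual_period, x$annual_phase))
  cat("\n")
  cat(sprintf("  noise: ARMA(%d,%d), innovation sd %.4g\n",
              length(x$ar), length(x$ma), x$noise_sd))
  if (length(x$ar)) cat("  ar (phi):", signif(x$ar, 4), "\n")
  if (length(x$ma)) cat("  ma (theta):", signif(x$ma, 4), "\n")
  invisible(x)
}
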