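#' ARMA persistence model for a weekly outcome series with missing weeks
#'
#' Fits low-order ARMA models to a weekly outcome series on its irregular
#' calendar, by separate estimation of the AR and MA parts (the
#' reduced-statistics route that stays well-behaved when maximum likelihood
#' would struggle with missing samples):
#'
#' 1. a long AR(L) model is fitted by Burg's recursion pooled over the
#'    maximal runs of consecutive observed weeks (no imputation or
#'    zero-filling; each reflection coefficient also records how many
#'    prediction pairs informed it);
#' 2. for every candidate order pair `(p, q)` starting values are derived
#'    from the long-AR representation by Durbin's method (the MA polynomial
#'    from a Yule--Walker fit to the long-AR coefficient sequence of the
#'    AR-filtered process, the AR polynomial by convolution);
#' 3. each candidate is refined and scored in reflection-coefficient space:
#'    it minimises the model error
#'    \eqn{\sum_k n_k (\hat r_k - r_k(\theta))^2}, where \eqn{\hat r_k} are
#'    the pooled Burg reflection coefficients, \eqn{r_k(\theta)} those
#'    implied by the candidate, and \eqn{n_k} the number of prediction pairs
#'    at order `k` (so the mismatch is on a chi-square scale);
#' 4. the order is selected by that model error plus a BIC-type penalty
#'    `(p + q) * log(mean(n_k))`; the selected model's innovation variance
#'    is the quadratic form of its truncated AR(\eqn{\infty}) filter against
#'    the long-AR-implied autocovariance.
#'
#' The returned model is stationary and invertible.  Coefficients are
#' reported in the convention
#' \deqn{y_t + a_1 y_{t-1} + a_2 y_{t-2} + a_3 y_{t-3} =
#'       e_t + c_1 e_{t-1} + c_2 e_{t-2} + c_3 e_{t-3},}
#' i.e. `a_k` is the negative of the textbook AR coefficient
#' \eqn{\phi_k}, while `c_k` equals the textbook \eqn{\theta_k}.
#'
#' Trend and annual seasonality are removed by regression before persistence
#' is estimated (both on by default, since trend, periodicity and
#' persistence are reported as separate structures); disable with the flags.
#'
#' @param series An `outcome_series` or numeric vector (then `weeks`).
#' @param max_p,max_q Largest AR and MA orders considered (at most 3).
#' @param detrend,deseasonalize Remove a fitted line / annual sine-cosine
#'   pair before estimation.
#' @param annual_period Seasonal period in weeks for the deseasonalizer.
#' @param long_ar_order Order `L` of the long autoregression (default 12,
#'   capped by the available segment lengths).
#' @param weeks Week indices for plain numeric input.
#' @return An object of class `arma_fit`: `p`, `q`, `ar` (the `a_k`), `ma`
#'   (the `c_k`), `sigma2`, `criterion` (selected value), `candidates`
#'   (full criterion table), `long_ar` (flipped-sign long-AR coefficients),
#'   `reflection` (pooled Burg reflection coefficients and their pair
#'   counts), `n_obs`, `convention`.
#' @examples
#' cal <- make_calendar(200, 200)
#' s <- simulate_outcome_series(cal, ground_truth(ar = 0.5, noise_sd = 1,
#'                                                seed = 4))
#' fit_arma(s)
#' @export
fit_arma <- function(series, max_p = 3L, max_q = 3L, detrend = TRUE,
                     deseasonalize = TRUE, annual_period = 52.18,
                     long_ar_order = 12L, weeks = NULL) {
  y <- series_values(series)
  t <- weeks %||% series_weeks(series)
  n <- length(y)
  if (n < 30L)
    stop_invalid("estimation-failure: need at least 30 observed weeks (got %d)",
                 n)
  stopifnot(max_p <= 3L, max_q <= 3L, max_p >= 0L, max_q >= 0L)
  x <- cbind(rep(1, n))
  if (detrend) x <- cbind(x, t)
  if (deseasonalize)
    x <- cbind(x, sin(2 * pi * t / annual_period),
               cos(2 * pi * t / annual_period))
  y <- stats::lm.fit(x, y)$residuals

  L <- max(as.integer(long_ar_order), max_p + max_q + 2L)
  bg <- burg_long_ar(y, t, L)
  L <- bg$order
  if (L < 3L)
    stop_invalid("estimation-failure: observed runs too short for a long AR")
  # short series support fewer parameters than the full candidate grid
  while (max_p + max_q + 2L > L && max_p + max_q > 0L) {
    if (max_q >= max_p) max_q <- max_q - 1L else max_p <- max_p - 1L
  }
  pi_long <- c(1, -bg$phi[[L + 1L]])
  w <- bg$n_pairs
  rhat <- bg$rc
  # autocovariance implied by the long AR (for Durbin starts and sigma^2)
  gam_ext <- ar_acvf(bg$phi[[L + 1L]], bg$v[L + 1L], 40L)
  gmat <- stats::toeplitz(gam_ext)
  qform <- function(a, c_) {
    piv <- arma_pi(a, c_, 40L)
    drop(piv %*% gmat %*% piv)
  }

  cands <- expand.grid(p = 0:max_p, q = 0:max_q)
  fits <- lapply(seq_len(nrow(cands)), function(i) {
    p <- cands$p[i]; q <- cands$q[i]
    cf <- tryCatch({
      if (q == 0L) {
        list(a = if (p > 0L) -bg$phi[[p + 1L]] else numeric(),
             c = numeric())
      } else {
        durbin_arma(gam_ext, p, q, long_order = min(L, 15L))
      }
    }, error = function(e) NULL)
    if (is.null(cf)) cf <- list(a = numeric(p), c = numeric(q))
    cf$a <- reflect_roots(cf$a)
    cf$c <- reflect_roots(cf$c)
    dfun <- function(par) {
      a <- par[seq_len(p)]; c_ <- par[p + seq_len(q)]
      if ((p > 0L && !monic_stable(a)) || (q > 0L && !monic_stable(c_)))
        return(1e12)
      rmod <- model_rc(a, c_, L)
      if (is.null(rmod)) return(1e12)
      sum(w * (rhat - rmod)^2)
    }
    if (p + q > 0L) {
      par0 <- c(cf$a, cf$c)
      if (dfun(par0) >= 1e12) par0 <- numeric(p + q)
      opt <- if (p + q == 1L)
        stats::optim(par0, dfun, method = "Brent", lower = -0.999,
                     upper = 0.999)
      else
        stats::optim(par0, dfun, method = "Nelder-Mead",
                     control = list(maxit = 400, reltol = 1e-9))
      cf$a <- opt$par[seq_len(p)]
      cf$c <- opt$par[p + seq_len(q)]
      dist <- opt$value
    } else {
      dist <- dfun(numeric(0))
    }
    s2 <- qform(cf$a, cf$c)
    if (!is.finite(dist) || dist >= 1e12 || !is.finite(s2) || s2 <= 0)
      return(list(p = p, q = q, a = numeric(), c = numeric(),
                  sigma2 = Inf, ic = Inf))
    ic <- dist + (p + q) * log(mean(w))
    list(p = p, q = q, a = cf$a, c = cf$c, sigma2 = s2, ic = ic)
  })
  ics <- vapply(fits, function(f)
    if (is.finite(f$ic)) f$ic else Inf, numeric(1))
  best <- fits[[which.min(ics)]]
  if (!is.finite(best$ic))
    stop_invalid("estimation-failure: no stationary candidate model")
  structure(
    list(p = best$p, q = best$q, ar = best$a, ma = best$c,
         sigma2 = best$sigma2, criterion = best$ic,
         candidates = data.frame(
           p = cands$p, q = cands$q,
           sigma2 = vapply(fits, `[[`, numeric(1), "sigma2"),
           ic = ics),
         long_ar = pi_long,
         reflection = list(rc = rhat, n_pairs = w),
         n_obs = n,
         convention = "y_t + a1 y_{t-1} + ... = e_t + c1 e_{t-1} + ..."),
    class = "arma_fit")
}

#' @export
print.arma_fit <- function(x, ...) {
  cat(sprintf("ARMA(%d,%d) persistence model (%d observed weeks)\n",
              x$p, x$q, x$n_obs))
  cat(" ", x$convention, "\n")
  if (x$p) cat("  a:", signif(x$ar, 4), "\n")
  if (x$q) cat("  c:", signif(x$ma, 4), "\n")
  if (!x$p && !x$q) cat("  white noise (no persistence)\n")
  cat(sprintf("  innovation variance %.4g, criterion %.4g\n",
              x$sigma2, x$criterion))
  invisible(x)
}

#' @export
coef.arma_fit <- function(object, ...) {
  out <- c(object$ar, object$ma)
  names(out) <- c(if (object$p) paste0("a", seq_len(object$p)),
                  if (object$q) paste0("c", seq_len(object$q)))
  out
}

# Long AR by Burg's recursion pooled over maximal runs of consecutive
# observed weeks.  Returns textbook-sign coefficient vectors for every order
# 0..order, prediction-error variances, reflection coefficients and the
# number of prediction pairs that informed each of them.
burg_long_ar <- function(y, t, L) {
  t <- as.integer(round(t - min(t)))
  y <- y - mean(y)
  segs <- split(y, cumsum(c(1L, diff(t) != 1L)))
  segs <- segs[lengths(segs) >= 2L]
  if (!length(segs)) stop_invalid("no consecutive-week runs in the data")
  f <- segs; b <- segs
  phi <- list(numeric(0))
  v <- mean(unlist(segs)^2)
  vs <- v
  rc_all <- numeric(0)
  n_pairs <- integer(0)
  for (k in seq_len(L)) {
    num <- 0; den <- 0; cnt <- 0L
    for (i in seq_along(f)) {
      ni <- length(f[[i]])
      if (ni <= k) next
      fk <- f[[i]][(k + 1L):ni]; bk <- b[[i]][k:(ni - 1L)]
      num <- num + sum(fk * bk)
      den <- den + sum(fk^2 + bk^2)
      cnt <- cnt + ni - k
    }
    if (den <= 0 || cnt < 10L) break
    rc <- max(min(2 * num / den, 0.998), -0.998)
    prev <- phi[[k]]
    phi[[k + 1L]] <- c(prev - rc * rev(prev), rc)
    vs <- c(vs, vs[k] * (1 - rc^2))
    rc_all <- c(rc_all, rc)
    n_pairs <- c(n_pairs, cnt)
    for (i in seq_along(f)) {
      ni <- length(f[[i]])
      if (ni <= k) next
      fk <- f[[i]][(k + 1L):ni]; bk <- b[[i]][k:(ni - 1L)]
      f[[i]][(k + 1L):ni] <- fk - rc * bk
      b[[i]][(k + 1L):ni] <- bk - rc * fk
    }
  }
  list(phi = phi, v = vs, order = length(rc_all), rc = rc_all,
       n_pairs = n_pairs)
}

# Autocovariance 0..len implied by a fitted AR(phi) with innovation
# variance v (textbook sign).
ar_acvf <- function(phi, v, len) {
  p <- length(phi)
  if (p == 0L) return(c(v, numeric(len)))
  rho <- unname(stats::ARMAacf(ar = phi, lag.max = len))
  g0 <- v / (1 - sum(phi * rho[2:(p + 1L)]))
  g0 * rho
}

# First L reflection coefficients of an ARMA(a, c) model (flipped sign
# convention): truncate its AR(inf) filter at order L and step down
# (reverse Levinson).  NULL when the step-down leaves |r| >= 1.
model_rc <- function(a, c_, L) {
  phi <- -arma_pi(a, c_, L)[-1L]      # textbook-sign AR(L) approximation
  rc <- numeric(L)
  for (k in L:1) {
    r <- phi[k]
    if (!is.finite(r) || abs(r) >= 1) return(NULL)
    rc[k] <- r
    if (k > 1L)
      phi <- (phi[seq_len(k - 1L)] + r * rev(phi[seq_len(k - 1L)])) /
        (1 - r^2)
  }
  rc
}

# Levinson-Durbin recursion on an autocovariance sequence; returns phi
# (textbook sign) for every order and the prediction-error variances.
# Stops early if the sequence degenerates; reflection coefficients are
# clamped so every fitted AR is stationary.
levinson <- function(acvf) {
  L <- length(acvf) - 1L
  if (anyNA(acvf)) {
    L <- min(which(is.na(acvf))) - 2L
    if (L < 1L) stop_invalid("too few valid autocovariance lags")
    acvf <- acvf[seq_len(L + 1L)]
  }
  phi <- vector("list", L + 1L)
  phi[[1L]] <- numeric()
  v <- numeric(L + 1L)
  v[1L] <- acvf[1L]
  order <- L
  for (k in seq_len(L)) {
    if (v[k] < 1e-8 * acvf[1L]) { order <- k - 1L; break }
    prev <- phi[[k]]
    num <- acvf[k + 1L] - if (k > 1L) sum(prev * acvf[k:2L]) else 0
    refl <- num / v[k]
    refl <- max(min(refl, 0.998), -0.998)
    new <- c(prev - refl * rev(prev), refl)
    phi[[k + 1L]] <- new
    v[k + 1L] <- v[k] * (1 - refl^2)
  }
  list(phi = phi, v = v, order = order)
}

# Durbin's reduced-statistics step for an ARMA(p, q) candidate, driven by an
# autocovariance sequence:
#   1. AR part by the extended Yule-Walker equations at lags q+1 .. q+p;
#   2. the AR-filtered process w_t = a(B) y_t is pure MA(q): its
#      autocovariance follows from gamma and a;
#   3. MA part by Durbin's method: fit a long AR to gamma_w, then solve the
#      Yule-Walker equations of the long-AR coefficient sequence itself.
durbin_arma <- function(gam_ext, p, q, long_order = 15L) {
  gam_at <- function(h) gam_ext[abs(h) + 1L]
  phi <- if (p > 0L) {
    m <- outer(seq_len(p), seq_len(p), function(i, j) gam_at(q + i - j))
    drop(solve(m, gam_at(q + seq_len(p))))
  } else numeric()
  a <- -phi
  aa <- c(1, a)
  gw <- vapply(0:long_order, function(h) {
    acc <- 0
    for (i in 0:p) for (j in 0:p)
      acc <- acc + aa[i + 1L] * aa[j + 1L] * gam_at(h + i - j)
    acc
  }, numeric(1))
  if (gw[1L] <= 0) stop_invalid("non-positive filtered variance")
  lev_w <- levinson(gw)
  s <- c(1, -lev_w$phi[[lev_w$order + 1L]])      # long-AR of the MA part
  len <- length(s)
  r <- vapply(0:q, function(j)
    sum(s[seq_len(len - j)] * s[seq_len(len - j) + j]), numeric(1))
  cc <- if (q == 1L) -r[2L] / r[1L] else
    -drop(solve(stats::toeplitz(r[seq_len(q)]), r[1L + seq_len(q)]))
  list(a = a, c = cc)
}

# Stability of a monic polynomial 1 + coef[1] z + ... (flipped convention):
# all roots outside the unit circle.
monic_stable <- function(coef) {
  if (!length(coef)) return(TRUE)
  all(Mod(polyroot(c(1, coef))) > 1)
}

# Reflect any root of 1 + coef[1] z + ... inside the unit circle to its
# reciprocal, keeping the polynomial real and monic.
reflect_roots <- function(coef, margin = 1.001) {
  if (!length(coef)) return(coef)
  r <- polyroot(c(1, coef))
  bad <- Mod(r) < 1
  if (!any(bad)) return(coef)
  r[bad] <- (margin / Mod(r[bad]))^2 * r[bad]   # reciprocal modulus, same arg
  pol <- 1
  for (root in r) pol <- convolve_poly(pol, c(1, -1 / root))
  Re(pol[-1L]) / Re(pol[1L])
}

convolve_poly <- function(a, b) {
  out <- rep(0 + 0i, length(a) + length(b) - 1L)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

# Truncated AR(inf) filter of an ARMA(a, c) model (flipped sign convention):
# pi_0 = 1, pi_k = a_k - sum_{j<=min(k,q)} c_j pi_{k-j}.
arma_pi <- function(a, c_, len) {
  p <- length(a); q <- length(c_)
  piv <- numeric(len + 1L)
  piv[1L] <- 1
  for (k in seq_len(len)) {
    v <- if (k <= p) a[k] else 0
    if (q) for (j in seq_len(min(q, k))) v <- v - c_[j] * piv[k - j + 1L]
    piv[k + 1L] <- v
  }
  piv
}
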