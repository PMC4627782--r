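# Independent brute-force oracles, written directly from the definitions and
# kept free of any package internals.

bf_eta <- function(a, b) {
  n <- length(a)
  m <- numeric(n); num <- 0
  for (i in seq_len(n)) m[i] <- (a[i] + b[i]) / 2
  grand <- sum(m) / n
  den <- 0
  for (i in seq_len(n)) {
    num <- num + (a[i] - m[i])^2 + (b[i] - m[i])^2
    den <- den + (a[i] - grand)^2 + (b[i] - grand)^2
  }
  1 - num / den
}

bf_fd <- function(rp, radius = 50) {
  n <- nrow(rp)
  fd <- numeric(n)
  for (t in 2:n) {
    s <- 0
    for (j in 1:3) s <- s + abs(rp[t, j] - rp[t - 1, j])
    for (j in 4:6) s <- s + radius * abs(rp[t, j] - rp[t - 1, j])
    fd[t] <- s
  }
  fd
}

bf_cv <- function(x) {
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / (length(x) - 1))
  100 * s / m
}

# Benjamini-Hochberg step-up by direct definition
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * p[ord[i]] / i)
    adj[ord[i]] <- running
  }
  adj
}

bf_cor_matrix <- function(tc) {
  k <- nrow(tc)
  out <- diag(k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    x <- tc[i, ]; y <- tc[j, ]
    out[i, j] <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  out
}

# classical periodogram at the Fourier frequencies j / n, j = 1..floor(n/2)
bf_periodogram <- function(y) {
  n <- length(y)
  y <- y - mean(y)
  js <- seq_len(floor(n / 2))
  vapply(js, function(j) {
    f <- j / n
    (sum(y * cos(2 * pi * f * (0:(n - 1))))^2 +
       sum(y * sin(2 * pi * f * (0:(n - 1))))^2) / n
  }, numeric(1))
}

# Wax-Kailath MDL evaluated directly, independent of the package's helper
bf_mdl_order <- function(lambda, n) {
  tol <- max(lambda) * 1e-12
  p <- sum(lambda > tol)
  lambda <- lambda[seq_len(p)]
  cost <- vapply(seq_len(p - 1), function(k) {
    tail <- lambda[(k + 1):p]
    gm <- exp(mean(log(tail))); am <- mean(tail)
    -n * (p - k) * log(gm / am) + 0.5 * k * (2 * p - k + 1) * log(n)
  }, numeric(1))
  which.min(cost)
}

# small toy study used across the GICA tests
toy_study <- function(seed, n_sessions = 3, n_sources = 4, snr = Inf,
                      dims = c(12, 12, 8), n_frames = 60, baseline = 0) {
  cal <- make_calendar(n_sessions, n_sessions)
  simulate_sessions(cal, n_sources = n_sources, dims = dims,
                    n_frames = n_frames, snr = snr, baseline = baseline,
                    seed = seed)
}

# best |correlation| match of each true source among recovered components
match_abs_cor <- function(recovered, truth) {
  cc <- abs(stats::cor(t(recovered), t(truth)))
  apply(cc, 2, max)
}
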