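#' Extended Infomax independent component analysis
#'
#' Unmixes whitened, reduced data into spatially independent sources using
#' the extended Infomax algorithm: full-batch natural-gradient updates with
#' sub/super-Gaussian switching, learning-rate annealing, at most `max_iter`
#' iterations and a tolerance on the weight change.  The decomposition is
#' deterministic for a fixed seed (the seed sets the random orthonormal
#' initialisation of the unmixing matrix).
#'
#' Sources are returned unit-normalised (unit standard deviation across
#' voxels) with the ICA sign indeterminacy resolved by flipping each
#' component so its skewness is positive.
#'
#' @param reduced A [reduce_pca()] / [concat_reduce()] result, or a whitened
#'   k \eqn{\times} samples matrix.
#' @param n_components Number of components; must equal the reduced
#'   dimension.
#' @param seed Integer seed for the initialisations.
#' @param max_iter,tol Iteration cap and convergence tolerance on the
#'   relative weight change.
#' @param lrate Initial learning rate.
#' @param restarts Number of random initialisations; the decomposition with
#'   the highest extended-Infomax pseudo-likelihood is kept (natural-
#'   gradient descent can stall in partial-mixing fixed points, so a few
#'   restarts make the estimator reliable).
#' @return An object of class `ica_decomposition`: `sources`
#'   (component \eqn{\times} voxel, unit sd), `unmixing`, `mixing`,
#'   `n_components`, `converged`, `iterations`, `kurtosis_signs`,
#'   `loglik`.  Non-convergence is flagged (`converged = FALSE`, with a
#'   warning), never silent.
#' @export
infomax_ica <- function(reduced, n_components, seed = 1, max_iter = 1000L,
                        tol = 1e-4, lrate = 0.1, restarts = 4L) {
  x <- if (inherits(reduced, c("pca_reduction", "group_reduction")))
    reduced$reduced else reduced
  stopifnot(is.matrix(x), restarts >= 1L)
  k <- nrow(x)
  if (n_components != k)
    stop_invalid("`n_components` (%d) must equal the reduced dimension (%d)",
                 n_components, k)
  best <- NULL
  for (r in seq_len(restarts)) {
    run <- infomax_once(x, seed = seed + (r - 1L) * 1000L,
                        max_iter = max_iter, tol = tol, lrate = lrate)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (!best$converged)
    warning(sprintf(
      "Infomax did not converge in %d iterations (last change %.3g)",
      max_iter, best$last_change))
  w <- best$w
  s <- w %*% x
  sds <- apply(s, 1L, stats::sd)
  flip <- ifelse(apply(s, 1L, skewness) < 0, -1, 1)
  scale <- flip / sds
  w <- w * scale                      # rowwise rescale/flip
  s <- s * scale
  structure(
    list(sources = s, unmixing = w, mixing = solve(w),
         n_components = as.integer(k), converged = best$converged,
         iterations = best$iterations, kurtosis_signs = best$signs,
         loglik = best$loglik),
    class = "ica_decomposition")
}

# One natural-gradient extended-Infomax descent from a random orthonormal
# initialisation.
infomax_once <- function(x, seed, max_iter, tol, lrate) {
  k <- nrow(x); n <- ncol(x)
  w <- with_seed(seed, qr.Q(qr(matrix(stats::rnorm(k * k), k, k))))
  ident <- diag(k)
  lr <- lrate
  prev_change <- Inf
  converged <- FALSE
  it <- 0L
  signs <- rep(1, k)
  while (it < max_iter) {
    it <- it + 1L
    u <- w %*% x
    y <- tanh(u)
    # sub/super-Gaussian switching (Lee, Girolami & Sejnowski)
    signs <- sign(rowMeans(1 - y^2) * rowMeans(u^2) - rowMeans(y * u))
    signs[signs == 0] <- 1
    grad <- (ident - (signs * y) %*% t(u) / n - u %*% t(u) / n) %*% w
    dw <- lr * grad
    if (!all(is.finite(dw))) {      # diverged: restart smaller
      lr <- lr / 2
      w <- with_seed(seed, qr.Q(qr(matrix(stats::rnorm(k * k), k, k))))
      prev_change <- Inf
      next
    }
    w <- w + dw
    change <- sqrt(sum(dw^2)) / sqrt(sum(w^2))
    if (change > prev_change) lr <- max(lr * 0.95, 1e-4)
    prev_change <- change
    if (change < tol) { converged <- TRUE; break }
  }
  u <- w %*% x
  ll <- determinant(w, logarithm = TRUE)$modulus -
    sum(rowMeans(u^2) / 2 + signs * rowMeans(log(cosh(u))))
  list(w = w, loglik = as.numeric(ll), converged = converged,
       iterations = it, signs = signs, last_change = prev_change)
}

skewness <- function(v) {
  v <- v - mean(v)
  m2 <- mean(v^2)
  if (m2 == 0) return(0)
  mean(v^3) / m2^1.5
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("Infomax ICA: %d components, %d iterations, %s\n",
              x$n_components, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Stability screen over randomised ICA restarts
#'
#' Reruns the Infomax decomposition from `n_runs` random initialisations,
#' matches components across runs by absolute spatial correlation, and scores
#' each component cluster by a compactness index in \eqn{[0, 1]}: the
#' within-cluster mean absolute correlation minus the maximum absolute
#' correlation to any other cluster (clamped to the unit interval) -- a
#' simplified version of the ICASSO cluster-quality index.  Components whose
#' index falls below `threshold` are flagged as unreliable.
#'
#' @param reduced Whitened reduced data (see [infomax_ica()]).
#' @param n_components Number of components.
#' @param n_runs Number of randomised restarts (at least 2).
#' @param seed Base seed; run `r` uses `seed + r - 1` unless `seeds` is given.
#' @param seeds Optional explicit per-run seeds (length `n_runs`).
#' @param threshold Flagging threshold on the index.
#' @return An object of class `ica_stability`: `stability_index` (per
#'   component of the reference run), `flagged`, `threshold`, `reference`
#'   (the first run's decomposition).
#' @export
stability_screen <- function(reduced, n_components, n_runs = 8, seed = 1,
                             seeds = NULL, threshold = 0.8) {
  if (n_runs < 2L) stop_invalid("`n_runs` must be at least 2")
  seeds <- seeds %||% (seed + seq_len(n_runs) - 1L)
  stopifnot(length(seeds) == n_runs)
  runs <- lapply(seeds, function(s)
    suppressWarnings(infomax_ica(reduced, n_components, seed = s)))
  k <- n_components
  # cluster j collects the component of each run matched to reference comp j
  members <- vector("list", k)
  ref <- runs[[1L]]$sources
  for (j in seq_len(k)) members[[j]] <- ref[j, , drop = FALSE]
  for (r in seq_len(n_runs)[-1L]) {
    cmat <- abs(stats::cor(t(ref), t(runs[[r]]$sources)))
    assign_idx <- greedy_match(cmat)
    for (j in seq_len(k))
      members[[j]] <- rbind(members[[j]],
                            runs[[r]]$sources[assign_idx[j], , drop = FALSE])
  }
  idx <- vapply(seq_len(k), function(j) {
    within <- abs(stats::cor(t(members[[j]])))
    w <- mean(within[upper.tri(within)])
    others <- do.call(rbind, members[-j])
    b <- max(abs(stats::cor(t(members[[j]]), t(others))))
    min(max(w - b, 0), 1)
  }, numeric(1))
  structure(
    list(stability_index = idx, flagged = idx < threshold,
         threshold = threshold, reference = runs[[1L]]),
    class = "ica_stability")
}

# Greedy one-to-one assignment maximising absolute correlation: returns, for
# each row (reference component), the matched column index.
greedy_match <- function(cmat) {
  k <- nrow(cmat)
  out <- integer(k)
  avail_r <- rep(TRUE, k); avail_c <- rep(TRUE, k)
  for (step in seq_len(k)) {
    m <- cmat
    m[!avail_r, ] <- -Inf; m[, !avail_c] <- -Inf
    pos <- arrayInd(which.max(m), dim(m))
    out[pos[1L]] <- pos[2L]
    avail_r[pos[1L]] <- FALSE; avail_c[pos[2L]] <- FALSE
  }
  out
}

#' @export
print.ica_stability <- function(x, ...) {
  cat(sprintf("ICA stability screen: %d components, threshold %.2f\n",
              length(x$stability_index), x$threshold))
  cat("  indices:", paste(sprintf("%.2f", x$stability_index),
                          collapse = " "), "\n")
  if (any(x$flagged))
    cat("  flagged:", which(x$flagged), "\n")
  invisible(x)
}
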