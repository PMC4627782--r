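# Two-stage PCA reduction and MDL order selection for the group-ICA chain.
#
# Conventions: a session's data matrix is in-mask voxels x time (x-fastest
# voxel order).  Voxels are treated as observations and (reduced) time points
# as variables, the spatial-ICA convention: each voxel's temporal mean and
# each frame's spatial mean are removed before the time-dimension covariance
# is formed.

# Centre a voxel x time matrix (each voxel's temporal mean, then each
# frame's spatial mean across voxels) and eigendecompose the time-dimension
# covariance.
time_cov_eigen <- function(y) {
  y <- y - rowMeans(y)
  y <- sweep(y, 2L, colMeans(y))
  n_vox <- nrow(y)
  ev <- eigen(crossprod(y) / (n_vox - 1), symmetric = TRUE)
  list(values = pmax(ev$values, 0), vectors = ev$vectors, centered = y)
}

#' Estimate the model order by the minimum description length criterion
#'
#' Applies the Wax--Kailath MDL criterion to the eigenvalue spectrum of a
#' session's time-dimension covariance to choose the number of signal
#' components, the order-selection step that fixes the dimensionality of the
#' group ICA.  The effective sample size is the number of frames; candidate
#' orders run over `1 .. p - 1` where `p` is the number of non-degenerate
#' eigenvalues.
#'
#' @param data In-mask voxel \eqn{\times} time matrix (or a 4D array plus
#'   `mask`).
#' @param mask Logical 3D array, required when `data` is a 4D array.
#' @return The selected order (integer).
#' @examples
#' y <- matrix(rnorm(300 * 3), 300, 3) %*% matrix(rnorm(3 * 40), 3, 40)
#' estimate_order_mdl(y + 0.05 * matrix(rnorm(300 * 40), 300, 40))
#' @export
estimate_order_mdl <- function(data, mask = NULL) {
  y <- as_data_matrix(data, mask)
  if (ncol(y) < 2L) stop_invalid("need at least 2 frames")
  if (stats::sd(as.numeric(y)) == 0)
    stop_invalid("estimation-failure: data are constant")
  lambda <- time_cov_eigen(y)$values
  crit <- mdl_criterion(lambda, n = ncol(y))
  which.min(crit)
}

# Wax-Kailath MDL cost over candidate orders 1..p_eff-1; index k of the
# returned vector is the cost of order k.
mdl_criterion <- function(lambda, n) {
  tol <- max(lambda) * 1e-12
  p <- max(sum(lambda > tol), 2L)
  lambda <- lambda[seq_len(p)]
  ks <- seq_len(p - 1L)
  vapply(ks, function(k) {
    tail <- lambda[(k + 1L):p]
    ratio <- mean(log(tail)) - log(mean(tail))   # log GM - log AM, <= 0
    -n * (p - k) * ratio + 0.5 * k * (2 * p - k + 1) * log(n)
  }, numeric(1))
}

#' First-stage (per-session) PCA reduction
#'
#' Reduces a session's time dimension to `k` whitened principal components.
#' The retained subspace captures the top-`k` variance of the time-dimension
#' covariance; the reduced data are whitened (unit variance per component
#' across voxels), which is the form the Infomax stage expects.
#'
#' @param data In-mask voxel \eqn{\times} time matrix (or 4D array plus
#'   `mask`).
#' @param k Number of components to retain.
#' @param mask Logical 3D array, required for 4D input.
#' @return An object of class `pca_reduction` with `basis` (time
#'   \eqn{\times} k), `sv` (singular values, i.e. square-root eigenvalues),
#'   `eigenvalues` (full spectrum), `reduced` (k \eqn{\times} voxel, whitened),
#'   `k`, `n_time`, `n_voxels`, `explained_variance`.
#' @export
reduce_pca <- function(data, k, mask = NULL) {
  y <- as_data_matrix(data, mask)
  if (k < 1 || k > min(dim(y)))
    stop_invalid("`k` = %d is not in 1..min(voxels, frames) = %d",
                 k, min(dim(y)))
  ev <- time_cov_eigen(y)
  tol <- max(ev$values) * 1e-12
  if (sum(ev$values > tol) < k)
    stop_invalid("`k` = %d exceeds the numerical rank (%d) of the data",
                 k, sum(ev$values > tol))
  sel <- seq_len(k)
  sv <- sqrt(ev$values[sel])
  basis <- ev$vectors[, sel, drop = FALSE]
  reduced <- (t(basis) %*% t(ev$centered)) / sv    # k x V, whitened
  structure(
    list(basis = basis, sv = sv, eigenvalues = ev$values,
         reduced = reduced, k = as.integer(k),
         n_time = ncol(y), n_voxels = nrow(y),
         explained_variance = sum(ev$values[sel]) / sum(ev$values)),
    class = "pca_reduction")
}

#' @export
print.pca_reduction <- function(x, ...) {
  cat(sprintf(
    "PCA reduction: %d voxels x %d frames -> %d components (%.1f%% variance)\n",
    x$n_voxels, x$n_time, x$k, 100 * x$explained_variance))
  invisible(x)
}

# Reconstruct the centred data (time x voxel) from a reduction -- used to
# verify that a full-rank reduction is lossless.
reconstruct_pca <- function(red) {
  red$basis %*% (red$sv * red$reduced)
}

#' Second-stage (group) PCA reduction of temporally concatenated sessions
#'
#' Stacks the per-session reduced data along the (reduced) temporal direction
#' and reduces the stack to `k` whitened group components, keeping the
#' session block structure needed by GICA3 backreconstruction.
#'
#' @param reductions List of [reduce_pca()] results over a common voxel set.
#' @param k Number of group components.
#' @return An object of class `group_reduction` with `basis`, `sv`,
#'   `eigenvalues`, `reduced` (k \eqn{\times} voxel, whitened), `k`,
#'   `session_rows` (list of row index vectors of each session's block in the
#'   stack), and `session_reductions`.
#' @export
concat_reduce <- function(reductions, k) {
  stopifnot(length(reductions) >= 1L,
            all(vapply(reductions, inherits, logical(1), "pca_reduction")))
  nv <- vapply(reductions, function(r) r$n_voxels, integer(1))
  if (length(unique(nv)) != 1L)
    stop_invalid("sessions have differing voxel counts")
  x <- do.call(rbind, lapply(reductions, function(r) r$reduced))
  if (k < 1 || k > nrow(x))
    stop_invalid("`k` = %d exceeds the stacked dimension %d", k, nrow(x))
  ev <- eigen(tcrossprod(x) / (ncol(x) - 1), symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  tol <- max(vals) * 1e-12
  if (sum(vals > tol) < k)
    stop_invalid("`k` = %d exceeds the numerical rank (%d) of the stack",
                 k, sum(vals > tol))
  sel <- seq_len(k)
  sv <- sqrt(vals[sel])
  basis <- ev$vectors[, sel, drop = FALSE]           # (sum k1) x k
  reduced <- (t(basis) %*% x) / sv                   # k x V, whitened
  ends <- cumsum(vapply(reductions, function(r) r$k, integer(1)))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  structure(
    list(basis = basis, sv = sv, eigenvalues = vals, reduced = reduced,
         k = as.integer(k),
         session_rows = Map(seq, starts, ends),
         session_reductions = reductions),
    class = "group_reduction")
}

#' @export
print.group_reduction <- function(x, ...) {
  cat(sprintf(
    "Group reduction: %d sessions stacked -> %d whitened components\n",
    length(x$session_rows), x$k))
  invisible(x)
}

# Accept a voxel x time matrix or a 4D array + mask.
as_data_matrix <- function(data, mask = NULL) {
  if (is.matrix(data)) {
    if (!all(is.finite(data))) stop_invalid("data contain non-finite values")
    return(data)
  }
  if (is.array(data) && length(dim(data)) == 4L) {
    if (is.null(mask)) stop_invalid("4D input needs a `mask`")
    return(flatten_session(data, mask))
  }
  stop_invalid("expected a voxel x time matrix or a 4D array with a mask")
}
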