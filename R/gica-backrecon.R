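#' GICA3 backreconstruction of session maps and time courses
#'
#' Recovers per-session spatial maps and time courses from the group ICA
#' decomposition.  With `M` sessions, first-stage reducing matrices
#' \eqn{F_i^-}, group reducing matrix \eqn{G^-} (partitioned into per-session
#' blocks \eqn{G_i^-}) and unmixing \eqn{W}, the GICA3 session map is
#' \deqn{S_i = M\, W\, G_i^-\, F_i^-\, Y_i}
#' and the session time course is \eqn{R_i = F_i\, G_i\, A} with
#' \eqn{A = W^{-1}}.  By construction the mean of the session maps equals the
#' aggregate map exactly, and \eqn{R_i S_i / M} reconstructs session `i`'s
#' reduced data.
#'
#' @param ica An [infomax_ica()] decomposition of the group-reduced data.
#' @param group A [concat_reduce()] result (carries the per-session blocks
#'   and the session reductions).
#' @return An object of class `backrecon_result`: `aggregate_maps`
#'   (component \eqn{\times} voxel), `session_maps` (list of
#'   component \eqn{\times} voxel matrices), `session_timecourses` (list of
#'   time \eqn{\times} component matrices, unscaled), `n_sessions`.
#' @export
backreconstruct_gica3 <- function(ica, group) {
  stopifnot(inherits(ica, "ica_decomposition"),
            inherits(group, "group_reduction"))
  if (ica$n_components != group$k)
    stop_invalid("decomposition has %d components but the reduction has %d",
                 ica$n_components, group$k)
  m <- length(group$session_rows)
  g_full <- group$basis %*% diag(group$sv, group$k)        # (sum k1) x k2
  ginv_full <- t(group$basis) / group$sv                   # k2 x (sum k1)
  maps <- vector("list", m)
  tcs <- vector("list", m)
  for (i in seq_len(m)) {
    rows <- group$session_rows[[i]]
    red_i <- group$session_reductions[[i]]
    maps[[i]] <- m * ica$unmixing %*%
      ginv_full[, rows, drop = FALSE] %*% red_i$reduced
    f_i <- red_i$basis %*% diag(red_i$sv, red_i$k)         # T x k1
    tcs[[i]] <- f_i %*% g_full[rows, , drop = FALSE] %*% ica$mixing
  }
  structure(
    list(aggregate_maps = ica$sources, session_maps = maps,
         session_timecourses = tcs, n_sessions = m),
    class = "backrecon_result")
}

#' @export
print.backrecon_result <- function(x, ...) {
  cat(sprintf(
    "GICA3 backreconstruction: %d sessions, %d components, %d voxels\n",
    x$n_sessions, nrow(x$aggregate_maps), ncol(x$aggregate_maps)))
  invisible(x)
}

#' Standardise spatial maps to z-score units
#'
#' Scales each map to zero mean and unit standard deviation over the in-mask
#' voxels.  Backreconstructed map values are regression weights, so the maps
#' are standardised to display units (the group-ICA toolbox display
#' convention) rather than put through a correlation-to-z transform, which is
#' undefined for weights outside \eqn{[-1, 1]}; the choice is recorded in the
#' pipeline metadata.
#'
#' @param map A numeric vector (one map) or component \eqn{\times} voxel
#'   matrix.
#' @return The standardised map(s), same shape as the input.
#' @export
zscore_map <- function(map) {
  if (is.matrix(map)) {
    return(t(apply(map, 1L, zscore_map)))
  }
  s <- stats::sd(map)
  if (!is.finite(s) || s == 0)
    stop_invalid("cannot z-score a constant map")
  (map - mean(map)) / s
}

#' Scale a backreconstructed time course to percent signal change
#'
#' Expresses a time course in percent of the session's mean signal:
#' `100 * timecourse / mean(session_voxel_means)`.
#'
#' @param timecourse Numeric vector or time \eqn{\times} component matrix in
#'   data units.
#' @param session_voxel_means Per-voxel temporal means of the session's raw
#'   data (or a single baseline value); their mean must be positive.
#' @return The time course in percent-signal-change units.
#' @export
scale_percent_signal <- function(timecourse, session_voxel_means) {
  baseline <- mean(session_voxel_means)
  if (!is.finite(baseline) || baseline <= 0)
    stop_invalid("mean session signal must be positive to express %% change")
  100 * timecourse / baseline
}

#' Run the full group-ICA chain on a longitudinal study
#'
#' Convenience driver composing the whole decomposition: per-session PCA
#' reduction (order `session_k`), temporal concatenation and second reduction
#' (order `n_components`), extended Infomax ICA, an optional stability screen
#' over randomised restarts, GICA3 backreconstruction, z-scoring of maps and
#' percent-signal-change scaling of time courses.
#'
#' When `n_components` is `NULL` the order is chosen as the median of the
#' per-session MDL estimates; `session_k` defaults to twice the chosen order
#' (robust-backreconstruction convention), capped at the session rank.
#'
#' @param x A `synthetic_study`, a list of in-mask voxel \eqn{\times} time
#'   matrices, or a list of 4D arrays (then `mask` is required).
#' @param mask Logical 3D array for 4D input.
#' @param n_components Group model order (`NULL` = MDL estimate).
#' @param session_k First-stage order (`NULL` = `2 * n_components`).
#' @param n_runs Restarts for the stability screen (`1` skips it).
#' @param seed Integer seed (initialisation and stability restarts).
#' @param stability_threshold Flagging threshold for the screen.
#' @return An object of class `gica_fit`: z-scored `aggregate_maps` and
#'   `session_maps`, percent-signal-change `session_timecourses`, the raw
#'   `backrecon` result, `stability` (or `NULL`), orders, convergence flag
#'   and metadata (`voxel_order`, `map_scaling`).
#' @export
gica <- function(x, mask = NULL, n_components = NULL, session_k = NULL,
                 n_runs = 1, seed = 1, stability_threshold = 0.8) {
  if (inherits(x, "synthetic_study")) {
    mask <- x$mask
    mats <- lapply(x$sessions, flatten_session, mask = mask)
  } else if (is.list(x)) {
    mats <- lapply(x, as_data_matrix, mask = mask)
  } else {
    stop_invalid("expected a synthetic_study or a list of sessions")
  }
  m <- length(mats)
  voxel_means <- lapply(mats, rowMeans)
  orders <- vapply(mats, estimate_order_mdl, numeric(1))
  k2 <- as.integer(n_components %||% max(2L, round(stats::median(orders))))
  n_time <- ncol(mats[[1L]])
  k1 <- as.integer(session_k %||% min(2L * k2, n_time - 1L))
  # noiseless or low-rank sessions cannot support the doubled order
  ranks <- vapply(mats, function(m2) {
    ev <- time_cov_eigen(m2)$values
    sum(ev > max(ev) * 1e-12)
  }, numeric(1))
  k1 <- as.integer(min(k1, min(ranks)))
  if (k1 < k2) stop_invalid("`session_k` (%d) below `n_components` (%d)",
                            k1, k2)
  reductions <- lapply(mats, reduce_pca, k = k1)
  group <- concat_reduce(reductions, k2)
  ica <- infomax_ica(group, k2, seed = seed)
  stab <- if (n_runs >= 2L)
    stability_screen(group, k2, n_runs = n_runs, seed = seed,
                     threshold = stability_threshold) else NULL
  br <- backreconstruct_gica3(ica, group)
  session_maps_z <- lapply(br$session_maps, zscore_map)
  # time courses in data units (unit-sd maps); expressed as percent signal
  # change when the session has a positive mean signal (zero-baseline
  # synthetic data stay in data units)
  tcs_pct <- lapply(seq_len(m), function(i) {
    amp <- apply(br$session_maps[[i]], 1L, stats::sd) / m
    tc <- sweep(br$session_timecourses[[i]], 2L, amp, `*`)
    if (mean(voxel_means[[i]]) > 0)
      tc <- scale_percent_signal(tc, voxel_means[[i]])
    tc
  })
  structure(
    list(aggregate_maps = zscore_map(br$aggregate_maps),
         session_maps = session_maps_z,
         session_timecourses = tcs_pct,
         backrecon = br, stability = stab, ica = ica,
         n_components = k2, session_k = k1, mdl_orders = orders,
         mask = mask, converged = ica$converged, seed = seed,
         voxel_order = "x-fastest within mask",
         map_scaling = "standardised to mean 0 / sd 1 over in-mask voxels"),
    class = "gica_fit")
}

#' @export
print.gica_fit <- function(x, ...) {
  cat(sprintf("Group ICA fit: %d sessions, %d components (session k = %d)\n",
              x$backrecon$n_sessions, x$n_components, x$session_k))
  cat(sprintf("  MDL session orders: median %.0f\n",
              stats::median(x$mdl_orders)))
  cat(sprintf("  Infomax: %s in %d iterations\n",
              if (x$converged) "converged" else "NOT converged",
              x$ica$iterations))
  if (!is.null(x$stability)) {
    cat(sprintf("  stability screen: %d of %d components flagged\n",
                sum(x$stability$flagged),
                length(x$stability$stability_index)))
  }
  invisible(x)
}
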