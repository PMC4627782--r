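#' Eta-squared spatial similarity of two maps
#'
#' The similarity index
#' \deqn{\eta^2 = 1 - \frac{\sum_i (a_i - m_i)^2 + (b_i - m_i)^2}
#'                         {\sum_i (a_i - \bar M)^2 + (b_i - \bar M)^2}}
#' with \eqn{m_i = (a_i + b_i)/2} the voxelwise mean image and \eqn{\bar M}
#' its grand mean.  Ranges from 0 (no similarity) to 1 (identical images);
#' unlike a correlation it is sensitive to differences in the actual values
#' at corresponding voxels, not only to their linear association.  Symmetric
#' in its arguments.
#'
#' @param a,b Numeric vectors of equal length (in-mask voxel values).
#' @return The similarity in \eqn{[0, 1]}.
#' @examples
#' eta_squared(c(1, 2, 3), c(3, 2, 1))   # 0
#' eta_squared(c(1, 2, 3), c(1, 2, 3))   # 1
#' @export
eta_squared <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L,
            all(is.finite(a)), all(is.finite(b)))
  m <- (a + b) / 2
  grand <- mean(m)
  denom <- sum((a - grand)^2 + (b - grand)^2)
  if (denom == 0)
    stop_invalid("undefined similarity: both maps are constant and equal")
  1 - sum((a - m)^2 + (b - m)^2) / denom
}

#' Voxelwise mean of a set of maps
#'
#' @param maps A list of equal-length numeric vectors, or a
#'   session \eqn{\times} voxel matrix.
#' @return The voxelwise mean map (numeric vector).
#' @export
mean_map <- function(maps) {
  maps <- as_map_matrix(maps)
  colMeans(maps)
}

#' Session overlap map
#'
#' Thresholds each session's z-scored map at `z_threshold`, sums the binary
#' maps and expresses the count as a percentage of sessions: the fraction of
#' the time each voxel is categorised as a member of the network.
#'
#' @param maps List of z-scored session maps or a session \eqn{\times} voxel
#'   matrix.
#' @param z_threshold Threshold applied to the z-scored maps (default 1).
#' @return An object of class `overlap_map`: per-voxel percentages in
#'   \eqn{[0, 100]} with the threshold and session count attached.
#' @export
overlap_map <- function(maps, z_threshold = 1) {
  maps <- as_map_matrix(maps)
  pct <- 100 * colMeans(maps > z_threshold)
  structure(pct, z_threshold = z_threshold, n_sessions = nrow(maps),
            class = "overlap_map")
}

#' @export
print.overlap_map <- function(x, ...) {
  cat(sprintf("Overlap map: %d sessions, z > %g; %.1f%% of voxels ever member\n",
              attr(x, "n_sessions"), attr(x, "z_threshold"),
              100 * mean(unclass(x) > 0)))
  invisible(x)
}

as_map_matrix <- function(maps) {
  if (is.list(maps)) {
    if (!length(maps)) stop_invalid("need at least one map")
    maps <- do.call(rbind, lapply(maps, as.numeric))
  }
  if (!is.matrix(maps) || nrow(maps) < 1L)
    stop_invalid("need at least one map")
  maps
}

#' Temporal fluctuation magnitude (RMS of a percent-signal-change series)
#'
#' The quadratic mean (root mean square) of a network time course expressed
#' in percent signal change.
#'
#' @param timecourse Numeric vector (one session's scaled time course).
#' @return The RMS magnitude (non-negative).
#' @examples
#' rms_percent_bold(c(3, 4))   # sqrt(25/2)
#' @export
rms_percent_bold <- function(timecourse) {
  if (!length(timecourse)) stop_invalid("empty time course")
  stopifnot(all(is.finite(timecourse)))
  sqrt(mean(timecourse^2))
}

#' Between-network connectivity matrix for one session
#'
#' Pearson correlation of the network time courses: a symmetric matrix with
#' unit diagonal.  Constant time courses yield `NA` correlations for their
#' pairs and are flagged with a warning.
#'
#' @param timecourses Component \eqn{\times} time matrix (one row per
#'   network), or time \eqn{\times} component with `time_in_rows = TRUE`.
#' @param time_in_rows Set when rows index time rather than networks.
#' @return An object of class `bnc_matrix` (a correlation matrix).
#' @export
bnc_matrix <- function(timecourses, time_in_rows = FALSE) {
  tc <- if (time_in_rows) timecourses else t(timecourses)
  stopifnot(is.matrix(tc), nrow(tc) >= 2L)
  sds <- apply(tc, 2L, stats::sd)
  if (any(sds == 0))
    warning(sprintf("%d constant time course(s): correlations undefined (NA)",
                    sum(sds == 0)))
  m <- suppressWarnings(stats::cor(tc))
  diag(m) <- 1
  structure(m, class = c("bnc_matrix", class(m)))
}

#' @export
print.bnc_matrix <- function(x, ...) {
  cat(sprintf("Between-network connectivity: %d networks\n", nrow(x)))
  print(round(unclass(x), 3), ...)
  invisible(x)
}

#' Weekly outcome-measure series from a group-ICA fit
#'
#' Computes the three network outcome measures for every session of a fitted
#' study and aligns them to the calendar as weekly series:
#' * spatial-map similarity: \eqn{\eta^2} of each session's z-scored network
#'   map against the study mean map (mean over all backreconstructed
#'   sessions of the run),
#' * temporal fluctuation magnitude: RMS of the percent-signal-change
#'   network time course,
#' * between-network connectivity: Pearson correlation of each network pair's
#'   time courses.
#'
#' @param fit A [gica()] result.
#' @param calendar The study's [make_calendar()]; `n_observed` must match the
#'   number of sessions.
#' @param components Which components to treat as networks (default all).
#' @param labels Optional network labels.
#' @return A list with `eta_sq` (list of `outcome_series` per network),
#'   `rms_bold` (same), `bnc` (list per network pair), `bnc_matrices` (per
#'   session), `mean_maps`, `overlap_maps`, `labels`.
#' @export
compute_outcomes <- function(fit, calendar, components = NULL,
                             labels = NULL) {
  stopifnot(inherits(fit, "gica_fit"), inherits(calendar, "session_calendar"))
  m <- fit$backrecon$n_sessions
  if (m != calendar$n_observed)
    stop_invalid("fit has %d sessions but the calendar has %d observed weeks",
                 m, calendar$n_observed)
  comp <- components %||% seq_len(fit$n_components)
  labels <- labels %||% sprintf("IC%02d", comp)
  k <- length(comp)

  ref_maps <- lapply(seq_along(comp), function(j)
    mean_map(lapply(fit$session_maps, function(sm) sm[comp[j], ])))
  eta <- lapply(seq_len(k), function(j) {
    vals <- vapply(fit$session_maps, function(sm)
      eta_squared(sm[comp[j], ], ref_maps[[j]]), numeric(1))
    outcome_series(vals, calendar, "eta_sq", labels[j])
  })
  rms <- lapply(seq_len(k), function(j) {
    vals <- vapply(fit$session_timecourses, function(tc)
      rms_percent_bold(tc[, comp[j]]), numeric(1))
    outcome_series(vals, calendar, "rms_bold", labels[j])
  })
  bmats <- lapply(fit$session_timecourses, function(tc)
    bnc_matrix(tc[, comp, drop = FALSE], time_in_rows = TRUE))
  pairs <- utils::combn(k, 2L)
  bnc <- lapply(seq_len(ncol(pairs)), function(pidx) {
    i <- pairs[1L, pidx]; j <- pairs[2L, pidx]
    vals <- vapply(bmats, function(bm) bm[i, j], numeric(1))
    outcome_series(vals, calendar, "bnc", c(labels[i], labels[j]))
  })
  overlap <- lapply(seq_len(k), function(j)
    overlap_map(lapply(fit$session_maps, function(sm) sm[comp[j], ])))
  names(eta) <- names(rms) <- names(overlap) <- labels
  names(bnc) <- apply(pairs, 2L, function(ij)
    paste(labels[ij], collapse = "/"))
  list(eta_sq = eta, rms_bold = rms, bnc = bnc, bnc_matrices = bmats,
       mean_maps = ref_maps, overlap_maps = overlap, labels = labels)
}
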