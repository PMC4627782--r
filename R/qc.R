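#' Framewise displacement from realignment parameters
#'
#' Summarises head motion per frame by framewise displacement: the sum of the
#' absolute values of the three differenced translational realignment
#' parameters plus the three differenced rotational parameters converted from
#' radians to millimetres on a sphere of radius `radius_mm` (default 50 mm,
#' the conventional brain radius):
#' \deqn{FD_t = \sum |\Delta d_{x,y,z}| + r \sum |\Delta \alpha,\beta,\gamma|.}
#' The first frame's FD is 0 by convention.
#'
#' @param realignment Frame \eqn{\times} 6 numeric matrix or data frame,
#'   columns ordered `tx, ty, tz` (mm) then `rx, ry, rz` (radians) -- the SPM
#'   `rp_*.txt` layout.
#' @param radius_mm Sphere radius for the rotation-to-displacement
#'   conversion.
#' @return An object of class `fd_series`: `fd` (per frame, mm), `mean_fd`,
#'   `max_fd`, `radius_mm`.
#' @examples
#' rp <- rbind(rep(0, 6), c(0, 0, 0, 1, 0, 0))
#' framewise_displacement(rp)$fd   # c(0, 50)
#' @export
framewise_displacement <- function(realignment, radius_mm = 50) {
  rp <- as.matrix(realignment)
  if (ncol(rp) != 6L)
    stop_invalid("realignment table must have exactly 6 columns (got %d)",
                 ncol(rp))
  if (nrow(rp) < 2L) stop_invalid("need at least 2 frames")
  stopifnot(all(is.finite(rp)), radius_mm > 0)
  d <- abs(diff(rp))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  structure(
    list(fd = fd, mean_fd = mean(fd), max_fd = max(fd),
         radius_mm = radius_mm),
    class = "fd_series")
}

#' @export
print.fd_series <- function(x, ...) {
  cat(sprintf(
    "Framewise displacement: %d frames, mean %.3g mm, max %.3g mm (r = %g mm)\n",
    length(x$fd), x$mean_fd, x$max_fd, x$radius_mm))
  invisible(x)
}

#' Read an SPM-style realignment parameter table
#'
#' Whitespace-delimited text with six columns per frame: three translations
#' in millimetres and three rotations in radians.
#'
#' @param path File path.
#' @return A frame \eqn{\times} 6 numeric matrix.
#' @export
read_realignment <- function(path) {
  rp <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(rp) != 6L)
    stop_invalid("expected 6 columns in %s (got %d)", path, ncol(rp))
  colnames(rp) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  rp
}

#' Weekly FD summary across a study's sessions
#'
#' @param motion_list List of realignment tables, one per session.
#' @param calendar The study calendar.
#' @param radius_mm Rotation-conversion radius.
#' @return List with `mean_fd` and `max_fd`, each an `outcome_series`.
#' @export
fd_weekly_series <- function(motion_list, calendar, radius_mm = 50) {
  fds <- lapply(motion_list, framewise_displacement, radius_mm = radius_mm)
  list(mean_fd = outcome_series(vapply(fds, `[[`, numeric(1), "mean_fd"),
                                calendar, "fd_mean"),
       max_fd = outcome_series(vapply(fds, `[[`, numeric(1), "max_fd"),
                               calendar, "fd_max"))
}

#' Weekly phantom intensity series from phantom volumes
#'
#' Mean in-mask signal intensity per session of a scanner-stability phantom,
#' aligned to the calendar -- the scanner-drift control series.
#'
#' @param volumes List of 4D arrays (or 3D arrays / matrices), one per
#'   session.
#' @param calendar The study calendar.
#' @param mask Optional logical array selecting phantom voxels.
#' @return An `outcome_series` with `measure_kind = "phantom"`.
#' @export
phantom_series <- function(volumes, calendar, mask = NULL) {
  if (!length(volumes)) stop_invalid("empty volume list")
  vals <- vapply(volumes, function(v) {
    if (!is.null(mask)) {
      d <- dim(v)
      flat <- matrix(v, prod(dim(mask)), length(v) / prod(dim(mask)))
      mean(flat[which(mask), ])
    } else mean(v)
  }, numeric(1))
  outcome_series(vals, calendar, "phantom")
}

#' Trend check for a confound series
#'
#' Linear-trend test plus permutation guard for a QC series (weekly FD or
#' phantom intensity): a confound-free study shows no significant trend in
#' either.
#'
#' @param series An `outcome_series` or numeric vector.
#' @param n_perm Permutations for the guard (0 skips it).
#' @param seed Optional integer seed.
#' @return The [fit_linear_trend()] result with a `p_perm` element added.
#' @export
confound_trend_check <- function(series, n_perm = 1000L, seed = NULL) {
  fit <- fit_linear_trend(series)
  if (n_perm > 0L) {
    wk <- series_weeks(series)
    fit$p_perm <- permutation_null(series, function(v)
      abs(stats::cor(v, wk)), n_iter = n_perm, seed = seed)$p
  }
  fit
}
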