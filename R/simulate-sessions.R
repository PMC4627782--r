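#' Simulate a toy longitudinal 4D fMRI study with known sources
#'
#' Builds a desk-scale stand-in for a weekly resting-state study: a set of
#' spatially compact, near-orthogonal source maps (Gaussian blobs inside an
#' ellipsoidal "brain" mask) mixed by session-specific smooth time courses,
#' plus Gaussian noise at a configurable signal-to-noise ratio and a constant
#' baseline.  Every generating quantity is retained so that source recovery by
#' the group-ICA chain can be scored exactly.
#'
#' Motion tables, a phantom intensity series and a daily covariate series are
#' generated alongside (from sub-seeds of `seed`) so the study object carries
#' every input the pipeline consumes.
#'
#' @param calendar A [make_calendar()] object; one 4D session per observed
#'   week.
#' @param n_sources Number of spatial sources (must be `< n_frames`).
#' @param dims Volume dimensions `c(x, y, z)`.
#' @param n_frames Frames (dynamics) per run; the study conditions use 200.
#' @param snr Ratio of in-mask signal RMS to noise standard deviation; `Inf`
#'   for noiseless data.
#' @param baseline Constant signal offset (scanner units) against which
#'   percent signal change is expressed.  Set to 0 for exactly low-rank data.
#' @param seed Integer seed; fixed seeds give byte-identical studies.
#'
#' @return An object of class `synthetic_study`: `calendar`, `sessions` (list
#'   of x\eqn{\times}y\eqn{\times}z\eqn{\times}t arrays), `mask` (logical 3D
#'   array), `true_sources` (source \eqn{\times} in-mask-voxel matrix,
#'   x-fastest voxel order), `true_timecourses` (list of frames
#'   \eqn{\times} source matrices), `motion_params`, `phantom_series`,
#'   `covariate_series`, `baseline`, `noise_sd`.
#' @examples
#' cal <- make_calendar(10, 8, seed = 1)
#' st <- simulate_sessions(cal, n_sources = 3, dims = c(10, 10, 6),
#'                         n_frames = 40, snr = 10, seed = 1)
#' dim(st$sessions[[1]])
#' @export
simulate_sessions <- function(calendar, n_sources = 5, dims = c(15, 15, 10),
                              n_frames = 200, snr = 10, baseline = 1000,
                              seed = NULL) {
  stopifnot(inherits(calendar, "session_calendar"),
            length(dims) == 3L, all(dims >= 4), n_frames >= 2)
  if (n_sources >= n_frames)
    stop_invalid("`n_sources` (%d) must be smaller than `n_frames` (%d)",
                 n_sources, n_frames)
  mask <- ellipsoid_mask(dims)
  n_sessions <- calendar$n_observed

  with_seed(seed, {
    sources <- blob_sources(dims, mask, n_sources)        # k x V (in-mask)
    tcs <- lapply(seq_len(n_sessions), function(i)
      smooth_timecourses(n_frames, n_sources))            # T x k, unit sd
    # common amplitude so that snr = rms(signal)/noise_sd is honest
    sig_rms <- sqrt(mean(vapply(tcs, function(tc)
      mean((tc %*% sources)^2), numeric(1))))
    noise_sd <- if (is.finite(snr)) sig_rms / snr else 0

    vox_idx <- which(mask)
    sessions <- lapply(seq_len(n_sessions), function(i) {
      vol <- array(baseline, dim = c(dims, n_frames))
      sig <- t(tcs[[i]] %*% sources)                      # V x T
      if (noise_sd > 0)
        sig <- sig + matrix(stats::rnorm(length(sig), sd = noise_sd),
                            nrow(sig), ncol(sig))
      flat <- matrix(vol, prod(dims), n_frames)
      flat[vox_idx, ] <- flat[vox_idx, ] + sig
      array(flat, dim = c(dims, n_frames))
    })
    motion <- lapply(seq_len(n_sessions), function(i)
      simulate_motion(n_frames, seed = NULL))

    structure(
      list(calendar = calendar, sessions = sessions, mask = mask,
           true_sources = sources, true_timecourses = tcs,
           motion_params = motion,
           phantom_series = simulate_phantom(calendar, seed = NULL),
           covariate_series = simulate_covariate(calendar, seed = NULL),
           baseline = baseline, noise_sd = noise_sd),
      class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  d <- dim(x$sessions[[1]])
  cat(sprintf(
    "Synthetic study: %d sessions of %dx%dx%d x %d frames, %d sources\n",
    length(x$sessions), d[1], d[2], d[3], d[4], nrow(x$true_sources)))
  cat(sprintf("  mask: %d voxels; noise sd %.4g; baseline %.4g\n",
              sum(x$mask), x$noise_sd, x$baseline))
  invisible(x)
}

ellipsoid_mask <- function(dims) {
  c0 <- (dims + 1) / 2
  r <- dims / 2
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  inside <- ((g$x - c0[1]) / r[1])^2 + ((g$y - c0[2]) / r[2])^2 +
    ((g$z - c0[3]) / r[3])^2 <= 1
  array(inside, dim = dims)
}

# Compact Gaussian blobs at well-separated in-mask centres; rows are unit-max
# maps over the in-mask voxels in x-fastest order.
blob_sources <- function(dims, mask, k, sigma = max(dims) / 10) {
  vox <- which(mask, arr.ind = TRUE)
  centres <- matrix(NA_real_, k, 3L)
  min_d <- max(dims) / 2.2
  repeat {
    cand <- vox[sample(nrow(vox), k), , drop = FALSE]
    d <- as.matrix(stats::dist(cand))
    if (k == 1L || min(d[upper.tri(d)]) >= min_d) { centres <- cand; break }
    min_d <- min_d * 0.95   # relax until k separated centres fit
  }
  S <- matrix(0, k, nrow(vox))
  for (s in seq_len(k)) {
    d2 <- rowSums(sweep(vox, 2L, centres[s, ])^2)
    v <- exp(-d2 / (2 * sigma^2))
    v[v < 0.05] <- 0                     # compact support
    S[s, ] <- v / max(v)
  }
  S
}

# Temporally smooth, roughly unit-sd session time courses (moving-average
# filtered white noise) -- generic full-rank mixing for the toy model.
smooth_timecourses <- function(n_frames, k, span = 5L) {
  raw <- matrix(stats::rnorm(n_frames * k), n_frames, k)
  kern <- rep(1 / span, span)
  sm <- apply(raw, 2L, function(v)
    stats::filter(v, kern, sides = 2L, circular = TRUE))
  sm <- matrix(as.numeric(sm), n_frames, k)
  sweep(sm, 2L, apply(sm, 2L, stats::sd), `/`)
}

# Flatten one 4D session to the in-mask voxel x time matrix (x-fastest order).
flatten_session <- function(vol, mask) {
  d <- dim(vol)
  stopifnot(length(d) == 4L, all(d[1:3] == dim(mask)))
  flat <- matrix(vol, prod(d[1:3]), d[4])
  flat[which(mask), , drop = FALSE]
}
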