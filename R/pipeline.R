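#' Configuration for an end-to-end study run
#'
#' Collects every knob of the pipeline in one validated object.  The
#' synthetic-study defaults reproduce the study conditions the package
#' emulates: a 185-week span with 158 observed weekly sessions of 200 frames
#' each, an annual target frequency of 1/52.18 per week, FDR correction
#' across networks, and a permutation guard with 1000 iterations.
#'
#' @param total_weeks,n_observed Calendar span and observed-session count.
#' @param n_sources,dims,n_frames,snr,baseline Synthetic-session parameters
#'   (see [simulate_sessions()]).
#' @param n_components,session_k Group-ICA orders (`NULL` = MDL-guided).
#' @param n_runs ICA restarts for the stability screen.
#' @param z_threshold Overlap-map threshold.
#' @param n_perm Permutation iterations for the guards.
#' @param max_arma_order Largest AR/MA order for persistence models.
#' @param target_frequency Periodicity target (per week).
#' @param correction `"fdr_bh"` or `"bonferroni"` for the trend and
#'   periodicity families.
#' @param seed Master seed; every stage derives its randomness from it.
#' @param write_volumes Also write the synthetic 4D sessions as NIfTI.
#' @return An object of class `study_config`.
#' @export
study_config <- function(total_weeks = 185, n_observed = 158,
                         n_sources = 5, dims = c(15, 15, 10),
                         n_frames = 200, snr = 10, baseline = 1000,
                         n_components = NULL, session_k = NULL, n_runs = 1,
                         z_threshold = 1, n_perm = 1000,
                         max_arma_order = 3, target_frequency = 1 / 52.18,
                         correction = c("fdr_bh", "bonferroni"), seed = 1,
                         write_volumes = FALSE) {
  correction <- match.arg(correction)
  cfg <- list(total_weeks = total_weeks, n_observed = n_observed,
              n_sources = n_sources, dims = dims, n_frames = n_frames,
              snr = snr, baseline = baseline, n_components = n_components,
              session_k = session_k, n_runs = n_runs,
              z_threshold = z_threshold, n_perm = n_perm,
              max_arma_order = max_arma_order,
              target_frequency = target_frequency, correction = correction,
              seed = seed, write_volumes = write_volumes)
  stopifnot(cfg$n_observed <= cfg$total_weeks, cfg$n_sources >= 2,
            cfg$n_frames > cfg$n_sources, length(cfg$dims) == 3,
            cfg$n_perm >= 0, cfg$target_frequency > 0,
            cfg$max_arma_order %in% 0:3)
  structure(cfg, class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study configuration\n")
  cat(sprintf("  calendar: %d/%d weeks; sessions: %dx%dx%d x %d frames\n",
              x$n_observed, x$total_weeks, x$dims[1], x$dims[2], x$dims[3],
              x$n_frames))
  cat(sprintf("  sources %d, snr %g; seed %d; correction %s\n",
              x$n_sources, x$snr, x$seed, x$correction))
  invisible(x)
}

#' Read / write a study configuration as YAML
#'
#' @param path YAML file.
#' @param config A [study_config()] object.
#' @return `read_study_config` returns a validated `study_config`.
#' @export
read_study_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals <- vals[names(vals) %in% names(formals(study_config))]
  if (!is.null(vals$dims)) vals$dims <- as.numeric(vals$dims)
  do.call(study_config, vals)
}

#' @rdname read_study_config
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 12L)
  invisible(path)
}

#' Temporal-structure tables for one outcome measure
#'
#' For a set of weekly outcome series (one per network or network pair),
#' computes the three temporal-structure analyses side by side: linear trend
#' (F-test, corrected across the family), annual periodicity (regression
#' spectrum + Fisher's exact g-test at the target frequency, corrected), and
#' ARMA persistence (selected orders and coefficients).
#'
#' @param series Named list of `outcome_series`.
#' @param target_frequency Periodicity target (per week).
#' @param correction Multiplicity correction across the family.
#' @param alpha Significance level on corrected p-values.
#' @param max_arma_order Largest AR/MA order.
#' @return A list of data frames `trend`, `periodicity`, `arma`; the trend
#'   table carries a `sign` column (+1/-1/0, the significant-trend matrix
#'   entry), the periodicity table a `significant` flag (significant g with
#'   the peak on the target bin), the ARMA table the selected orders and
#'   coefficients.
#' @export
temporal_structure <- function(series, target_frequency = 1 / 52.18,
                               correction = "fdr_bh", alpha = 0.05,
                               max_arma_order = 3) {
  nm <- names(series) %||% as.character(seq_along(series))
  trends <- lapply(series, fit_linear_trend)
  tq <- adjust_pvalues(vapply(trends, `[[`, numeric(1), "p"), correction)
  trend <- data.frame(
    network = nm,
    intercept = vapply(trends, `[[`, numeric(1), "intercept"),
    slope = vapply(trends, `[[`, numeric(1), "slope"),
    F = vapply(trends, `[[`, numeric(1), "F"),
    p = vapply(trends, `[[`, numeric(1), "p"),
    q = tq,
    sign = ifelse(tq < alpha,
                  sign(vapply(trends, `[[`, numeric(1), "slope")), 0),
    row.names = NULL)

  gt <- lapply(series, function(s)
    fisher_g_test(robust_spectrum(s, target_frequency = target_frequency)))
  pq <- adjust_pvalues(vapply(gt, `[[`, numeric(1), "p"), correction)
  periodicity <- data.frame(
    network = nm,
    g = vapply(gt, `[[`, numeric(1), "g"),
    p = vapply(gt, `[[`, numeric(1), "p"),
    q = pq,
    peak_frequency = vapply(gt, `[[`, numeric(1), "peak_frequency"),
    target_is_peak = vapply(gt, function(x)
      isTRUE(x$target_is_peak), logical(1)),
    significant = pq < alpha & vapply(gt, function(x)
      isTRUE(x$target_is_peak), logical(1)),
    row.names = NULL)

  armas <- lapply(series, function(s)
    tryCatch(fit_arma(s, max_p = max_arma_order, max_q = max_arma_order),
             error = function(e) NULL))
  pick <- function(f, what, i) if (is.null(f)) NA_real_ else
    if (length(f[[what]]) >= i) f[[what]][i] else 0
  arma <- data.frame(
    network = nm,
    p = vapply(armas, function(f) if (is.null(f)) NA_integer_ else f$p,
               integer(1)),
    q = vapply(armas, function(f) if (is.null(f)) NA_integer_ else f$q,
               integer(1)),
    a1 = vapply(armas, pick, numeric(1), what = "ar", i = 1),
    a2 = vapply(armas, pick, numeric(1), what = "ar", i = 2),
    a3 = vapply(armas, pick, numeric(1), what = "ar", i = 3),
    c1 = vapply(armas, pick, numeric(1), what = "ma", i = 1),
    c2 = vapply(armas, pick, numeric(1), what = "ma", i = 2),
    c3 = vapply(armas, pick, numeric(1), what = "ma", i = 3),
    sigma2 = vapply(armas, function(f)
      if (is.null(f)) NA_real_ else f$sigma2, numeric(1)),
    row.names = NULL)
  list(trend = trend, periodicity = periodicity, arma = arma)
}

#' Run the full pipeline end to end
#'
#' Executes every stage on a synthetic study and writes all result tables to
#' `out_dir`: synthetic generation, group ICA, outcome-measure series,
#' reproducibility summaries, temporal-structure tables per measure, and the
#' QC (motion / phantom / covariate) report.  Runs are deterministic for a
#' fixed config seed: every stage derives its randomness from it, and two
#' runs with the same config produce byte-identical tables.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created; existing files overwritten).
#' @return Invisibly, a list with the in-memory stage results (`study`,
#'   `fit`, `outcomes`, `repro`, `temporal`, `qc`, `files`).
#' @export
run_study <- function(config = study_config(), out_dir = tempfile("study_")) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  calendar <- make_calendar(config$total_weeks, config$n_observed,
                            seed = seed)
  study <- simulate_sessions(calendar, n_sources = config$n_sources,
                             dims = config$dims, n_frames = config$n_frames,
                             snr = config$snr, baseline = config$baseline,
                             seed = seed + 1L)
  if (config$write_volumes)
    write_study_nifti(study, file.path(out_dir, "volumes"))

  fit <- gica(study, n_components = config$n_components,
              session_k = config$session_k, n_runs = config$n_runs,
              seed = seed + 2L)
  out <- compute_outcomes(fit, calendar)

  repro <- list(eta_sq = repro_summary(out$eta_sq),
                rms_bold = repro_summary(out$rms_bold),
                bnc = repro_summary(out$bnc))
  temporal <- list(
    eta_sq = temporal_structure(out$eta_sq, config$target_frequency,
                                config$correction,
                                max_arma_order = config$max_arma_order),
    rms_bold = temporal_structure(out$rms_bold, config$target_frequency,
                                  config$correction,
                                  max_arma_order = config$max_arma_order),
    bnc = temporal_structure(out$bnc, config$target_frequency,
                             config$correction,
                             max_arma_order = config$max_arma_order))

  fdw <- fd_weekly_series(study$motion_params, calendar)
  qc <- list(
    fd_trend = confound_trend_check(fdw$mean_fd, n_perm = config$n_perm,
                                    seed = seed + 3L),
    phantom_trend = confound_trend_check(study$phantom_series,
                                         n_perm = config$n_perm,
                                         seed = seed + 4L),
    covariate = lapply(out$eta_sq, correlate_covariate,
                       covariate = study$covariate_series,
                       n_perm = config$n_perm, seed = seed + 5L))

  files <- write_run_tables(out_dir, config, calendar, out, repro, temporal,
                            fdw, qc)
  invisible(list(study = study, fit = fit, outcomes = out, repro = repro,
                 temporal = temporal, qc = qc, files = files,
                 out_dir = out_dir))
}

write_run_tables <- function(out_dir, config, calendar, out, repro,
                             temporal, fdw, qc) {
  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  files <- character()
  files <- c(files, wt(data.frame(week_index = calendar$observed_weeks,
                                  date_iso = format(calendar$dates)),
                       "calendar.tsv"))
  for (m in names(repro))
    files <- c(files, wt(repro[[m]], sprintf("repro_%s.tsv", m)))
  for (m in names(temporal)) {
    files <- c(files, wt(temporal[[m]]$trend, sprintf("trend_%s.tsv", m)))
    files <- c(files, wt(temporal[[m]]$periodicity,
                         sprintf("periodicity_%s.tsv", m)))
    files <- c(files, wt(temporal[[m]]$arma, sprintf("arma_%s.tsv", m)))
  }
  for (nm in names(out$eta_sq))
    files <- c(files, wt(as.data.frame(out$eta_sq[[nm]]),
                         sprintf("series_eta_sq_%s.tsv", nm)))
  files <- c(files, wt(data.frame(
    week_index = calendar$observed_weeks,
    mean_fd = fdw$mean_fd$values, max_fd = fdw$max_fd$values), "qc_fd.tsv"))
  files <- c(files, wt(data.frame(
    series = c("mean_fd", "phantom"),
    slope = c(qc$fd_trend$slope, qc$phantom_trend$slope),
    F = c(qc$fd_trend$F, qc$phantom_trend$F),
    p = c(qc$fd_trend$p, qc$phantom_trend$p),
    p_perm = c(qc$fd_trend$p_perm %||% NA, qc$phantom_trend$p_perm %||% NA)),
    "qc_trend.tsv"))
  files <- c(files, wt(data.frame(
    network = names(qc$covariate),
    r = vapply(qc$covariate, `[[`, numeric(1), "r"),
    p_perm = vapply(qc$covariate, `[[`, numeric(1), "p_perm")),
    "covariate_eta_sq.tsv"))
  cfg_path <- file.path(out_dir, "config.yaml")
  write_study_config(config, cfg_path)
  jsonlite::write_json(
    list(seed = config$seed,
         config_md5 = unname(tools::md5sum(cfg_path))),
    file.path(out_dir, "run_info.json"), auto_unbox = TRUE)
  c(files, cfg_path)
}
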