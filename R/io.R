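# On-disk formats: TSV for calendars/series/matrices, NIfTI for volumes and
# maps, JSON for ground truth and run metadata.

#' Write / read a weekly outcome series as TSV
#'
#' Columns `week_index`, `date_iso`, `value`, one row per observed week.
#'
#' @param series An `outcome_series`.
#' @param path Output file.
#' @return `write_series_tsv` returns `path` invisibly; `read_series_tsv`
#'   returns an `outcome_series` (the calendar is rebuilt from the week
#'   indices, with `total_weeks` spanning the recorded weeks).
#' @export
write_series_tsv <- function(series, path) {
  utils::write.table(as.data.frame(series), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_tsv
#' @export
read_series_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("week_index", "date_iso", "value") %in% names(df)))
  wk <- as.integer(df$week_index)
  start <- as.Date(df$date_iso[1]) - 7L * wk[1]
  cal <- make_calendar(max(wk) + 1L, length(wk), start_date = start)
  cal$observed_weeks <- wk
  cal$n_observed <- length(wk)
  cal$dates <- start + 7L * wk
  outcome_series(df$value, cal)
}

#' Write a labelled square matrix (e.g. a BNC matrix) as TSV
#'
#' @param m Matrix with row/column names.
#' @param path Output file.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(label = rownames(m) %||% seq_len(nrow(m)),
                   unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the sessions, mask and ground truth of a synthetic study to disk
#'
#' Sessions go out as 4D NIfTI (`session_###.nii.gz`), the mask as
#' `mask.nii.gz`, the calendar as TSV and the generating bookkeeping as a
#' JSON sidecar.
#'
#' @param study A [simulate_sessions()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study_nifti <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(study$sessions))
    RNifti::writeNifti(study$sessions[[i]],
                       file.path(dir, sprintf("session_%03d.nii.gz", i)))
  RNifti::writeNifti(array(as.numeric(study$mask), dim = dim(study$mask)),
                     file.path(dir, "mask.nii.gz"))
  utils::write.table(
    data.frame(week_index = study$calendar$observed_weeks,
               date_iso = format(study$calendar$dates)),
    file.path(dir, "calendar.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(
    list(n_sources = nrow(study$true_sources),
         baseline = study$baseline, noise_sd = study$noise_sd,
         voxel_order = "x-fastest within mask"),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read 4D NIfTI sessions and a mask into data matrices
#'
#' @param session_paths Character vector of 4D NIfTI files.
#' @param mask_path NIfTI mask volume (non-zero = in mask).
#' @return List with `sessions` (in-mask voxel \eqn{\times} time matrices,
#'   x-fastest order) and `mask` (logical array).
#' @export
read_sessions_nifti <- function(session_paths, mask_path) {
  mask <- RNifti::readNifti(mask_path) != 0
  sessions <- lapply(session_paths, function(p) {
    vol <- RNifti::readNifti(p)
    flatten_session(array(as.numeric(vol), dim = dim(vol)), mask)
  })
  list(sessions = sessions, mask = mask)
}

#' Write spatial maps as a 4D NIfTI stacked along the fourth dimension
#'
#' @param maps Component \eqn{\times} in-mask-voxel matrix.
#' @param mask Logical 3D array (defines the voxel order).
#' @param path Output file.
#' @export
write_maps_nifti <- function(maps, mask, path) {
  stopifnot(is.matrix(maps), ncol(maps) == sum(mask))
  d <- dim(mask)
  out <- array(0, dim = c(d, nrow(maps)))
  flat <- matrix(out, prod(d), nrow(maps))
  flat[which(mask), ] <- t(maps)
  RNifti::writeNifti(array(flat, dim = c(d, nrow(maps))), path)
  invisible(path)
}
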