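#' Read and write recordings as CSV
#'
#' The on-disk dialect mirrors what the companion recorder app stores: a
#' header row `time_s`, the 24 channel labels, `trigger`; one row per
#' sample; channel values in microvolts with six decimal places; trigger
#' codes 0 (none), 1 (eyes-open onset), 2 (eyes-closed onset). The time
#' column must advance uniformly at 1/fs; the sampling rate is inferred
#' from it on read and snapped to the exact 500, 250 or 500/3 Hz device
#' rates when within tolerance.
#'
#' @param rec An `eeg_recording`.
#' @param path File path.
#' @return `write_recording_csv()` returns `path` invisibly;
#'   `read_recording_csv()` returns an `eeg_recording`.
#' @export
write_recording_csv <- function(rec, path) {
  labels <- recording_channels(rec)
  out <- rec
  out$time_s <- sprintf("%.6f", rec$time_s)
  for (ch in labels) out[[ch]] <- sprintf("%.6f", rec[[ch]])
  readr::write_csv(as_tibble(out), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param permissive Accept (and ignore) extra metadata columns after
#'   `trigger`.
#' @export
read_recording_csv <- function(path, permissive = FALSE) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  expected <- c("time_s", montage_labels(), "trigger")
  if (!permissive && ncol(tbl) != length(expected))
    abort(sprintf("malformed file: expected %d columns, found %d",
                  length(expected), ncol(tbl)))
  if (!identical(names(tbl)[seq_along(expected)], expected))
    abort("malformed header: expected time_s, the 24 montage labels, trigger")
  tbl <- tbl[, expected]
  dt <- diff(tbl$time_s)
  if (any(abs(dt - stats::median(dt)) > 2e-6))
    abort("non-uniform timestamps")
  fs <- 1 / stats::median(dt)
  for (known in c(500, 250, 500 / 3))
    if (abs(fs - known) < 0.01) fs <- known
  new_eeg_recording(as.matrix(tbl[montage_labels()]), fs,
                    trigger = as.integer(tbl$trigger))
}
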