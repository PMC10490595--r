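#' EEG recording containers
#'
#' A recording is a tibble with a `time_s` column, one column per channel
#' (microvolts), and an integer `trigger` column marking condition onsets
#' (0 = none, 1 = eyes-open onset, 2 = eyes-closed onset). The sampling rate
#' is carried in the `fs` attribute; for the 500/3 Hz telemetry rate the
#' attribute stores the exact rational value and [recording_fs_reported()]
#' gives the conventional rounded figure (167).
#'
#' @param data Numeric matrix, samples x channels, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param labels Channel labels, one per column of `data`.
#' @param trigger Integer vector of per-sample trigger codes (default all 0).
#' @return An `eeg_recording` tibble.
#' @export
new_eeg_recording <- function(data, fs, labels = montage_labels(),
                              trigger = integer(nrow(data))) {
  stopifnot(is.matrix(data), ncol(data) == length(labels),
            length(trigger) == nrow(data), fs > 0)
  tbl <- as_tibble(as.data.frame(data, optional = TRUE), .name_repair = "minimal")
  names(tbl) <- labels
  out <- tibble(time_s = (seq_len(nrow(data)) - 1) / fs)
  out <- dplyr::bind_cols(out, tbl)
  out$trigger <- as.integer(trigger)
  attr(out, "fs") <- fs
  class(out) <- c("eeg_recording", class(out))
  out
}

#' @rdname new_eeg_recording
#' @param rec An `eeg_recording`.
#' @export
recording_fs <- function(rec) attr(rec, "fs")

#' @rdname new_eeg_recording
#' @export
recording_fs_reported <- function(rec) as.integer(round(attr(rec, "fs")))

#' @rdname new_eeg_recording
#' @export
recording_channels <- function(rec) setdiff(names(rec), c("time_s", "trigger"))

#' @rdname new_eeg_recording
#' @export
recording_matrix <- function(rec) {
  as.matrix(rec[recording_channels(rec)])
}

#' Condition onset events of a recording
#'
#' @param rec An `eeg_recording`.
#' @return Tibble with `sample` (0-based index), `time_s`, and `condition`
#'   (`"eyes_open"` or `"eyes_closed"`).
#' @export
recording_events <- function(rec) {
  idx <- which(rec$trigger != 0L)
  tibble(
    sample = idx - 1L,
    time_s = rec$time_s[idx],
    condition = ifelse(rec$trigger[idx] == 2L, "eyes_closed", "eyes_open")
  )
}
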