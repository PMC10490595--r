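#' Encode front-end frames into a telemetry stream
#'
#' Runs the closed-loop delta encoder over the quantized frames and
#' serializes the result as an offline stream: one configuration message,
#' then—once per second—a shift-update message immediately followed by the
#' first data packet encoded with the new shifts, plus the remaining data
#' packets of that second (one packet per sample).
#'
#' @param frames An `eeg_frames` tibble from [run_frontend()].
#' @param codec A [codec_config()]; its `fs_out` must match the frame rate.
#' @param battery_mV,filter_mask Values stored in the configuration message.
#' @return An `eeg_stream` raw vector with attributes `bit_length`,
#'   `fs_out`, `gain`, `n_frames`, `shifts` (per-update shift table) and
#'   `clipped` (per-channel clip counts).
#' @export
telemetry_encode <- function(frames, codec = codec_config(),
                             battery_mV = 3700L, filter_mask = 0L) {
  labels <- setdiff(names(frames), c("time_s", "trigger"))
  fs_rep <- attr(frames, "fs_reported")
  if (!is.null(fs_rep) && fs_rep != codec$fs_out)
    abort(sprintf("codec fs_out (%d) does not match frame rate (%d)",
                  codec$fs_out, fs_rep))
  gain <- attr(frames, "gain") %||% 8L
  counts <- as.matrix(frames[labels])
  storage.mode(counts) <- "integer"
  res <- cpp_encode_stream(counts, codec$bit_length, codec$fs_out,
                           codec$ema_lambda, codec$headroom,
                           GAIN_CODES[[as.character(gain)]],
                           RATE_CODES[[as.character(codec$fs_out)]],
                           as.integer(filter_mask), as.integer(battery_mV))
  stream <- res$stream
  attr(stream, "bit_length") <- codec$bit_length
  attr(stream, "fs_out") <- codec$fs_out
  attr(stream, "gain") <- gain
  attr(stream, "n_frames") <- res$n_frames
  attr(stream, "shifts") <- res$shifts
  attr(stream, "clipped") <- res$clipped
  class(stream) <- "eeg_stream"
  stream
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decode a telemetry stream back into count frames
#'
#' A stateful decoder over the offline stream: the configuration message
#' fixes gain/rate/bit length, shift updates resynchronize the per-channel
#' shifts, and each data packet advances the per-channel reconstruction.
#' On a lossless stream the reconstruction equals the encoder's exactly.
#'
#' @param stream An `eeg_stream` raw vector (or any raw vector in the
#'   offline stream format).
#' @return An `eeg_frames` tibble of reconstructed counts with `fs`,
#'   `fs_reported`, `gain`, `total_dropped` and `shift_at` attributes. The
#'   trigger column is zero (condition markers travel outside the link).
#' @export
telemetry_decode <- function(stream) {
  res <- cpp_decode_stream(as.raw(stream))
  gain <- as.integer(names(GAIN_CODES)[match(res$gain_code, GAIN_CODES)])
  rate <- as.integer(names(RATE_CODES)[match(res$rate_code, RATE_CODES)])
  fs <- if (!is.na(rate) && rate == 167L) 500 / 3 else 250
  counts <- res$counts
  colnames(counts) <- montage_labels()
  out <- tibble(time_s = (seq_len(nrow(counts)) - 1) / fs)
  out <- dplyr::bind_cols(out, as_tibble(as.data.frame(counts)))
  out$trigger <- integer(nrow(counts))
  attr(out, "fs") <- fs
  attr(out, "fs_reported") <- rate
  attr(out, "gain") <- gain
  attr(out, "bit_length") <- res$bit_length
  attr(out, "battery_mV") <- res$battery_mV
  attr(out, "total_dropped") <- res$total_dropped
  attr(out, "shift_at") <- res$shift_at
  class(out) <- c("eeg_frames", class(out))
  out
}

#' Full acquisition round trip: front end, telemetry link, reconstruction
#'
#' Convenience wrapper chaining [run_frontend()], [telemetry_encode()],
#' [telemetry_decode()] and [frames_to_recording()]. Condition triggers are
#' reattached from the front-end output (they are recorded alongside the
#' link, not inside it).
#'
#' @param rec A 500 Hz [new_eeg_recording()].
#' @param config A [filter_config()].
#' @param codec A [codec_config()]; defaults to the rate implied by
#'   `config$downsample_factor`.
#' @return The decoded microvolt `eeg_recording` at the output rate, with
#'   attributes `stream_bytes` (serialized size) and `clipped`.
#' @export
transmit_recording <- function(rec, config = filter_config(),
                               codec = NULL) {
  frames <- run_frontend(rec, config)
  if (is.null(codec))
    codec <- codec_config(fs_out = attr(frames, "fs_reported"))
  stream <- telemetry_encode(frames, codec)
  decoded <- telemetry_decode(stream)
  decoded$trigger <- frames$trigger
  attr(decoded, "fs") <- attr(frames, "fs") # exact rational rate
  out <- frames_to_recording(decoded)
  attr(out, "stream_bytes") <- length(stream)
  attr(out, "clipped") <- attr(stream, "clipped")
  out
}
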