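#' Adaptive delta codec configuration
#'
#' The telemetry link transmits per-channel differences between the current
#' sample and the last *encoded* value (closed-loop DPCM), right-shifted by a
#' per-channel 4-bit shift code and clipped to a signed 10-, 14- or 16-bit
#' integer. A floating average (exponential moving average of absolute
#' differences) is tracked per channel; once per second it selects the shift
#' so that `headroom` times the average magnitude fits in the transmittable
#' range.
#'
#' @param bit_length Transmitted value width: 10, 14 or 16 bits.
#' @param fs_out Output sample rate (250 or 167); sets the shift-update
#'   cadence (one update per `fs_out` samples) and the default smoothing
#'   weight.
#' @param ema_lambda Smoothing weight of the floating average
#'   (`A <- (1 - lambda) * A + lambda * |d|`); default `1/fs_out`
#'   (about a 1 s time constant).
#' @param headroom Safety factor of the shift selection (>= 1).
#' @return A `codec_config` list.
#' @export
codec_config <- function(bit_length = 10, fs_out = 250,
                         ema_lambda = 1 / fs_out, headroom = 8) {
  if (!bit_length %in% c(10L, 14L, 16L))
    abort("bit_length must be 10, 14 or 16")
  if (!fs_out %in% c(250L, 167L)) abort("fs_out must be 250 or 167")
  if (ema_lambda <= 0 || ema_lambda > 1) abort("ema_lambda must be in (0, 1]")
  if (headroom < 1) abort("headroom must be >= 1")
  cfg <- list(bit_length = as.integer(bit_length), fs_out = as.integer(fs_out),
              ema_lambda = ema_lambda, headroom = headroom)
  class(cfg) <- "codec_config"
  cfg
}

#' Fresh encoder / decoder state
#'
#' Reconstructions start at zero, so the first encoded frame is a difference
#' from zero; combined with the front-end high-pass (near-zero-mean signals)
#' the startup transient is bounded. The decoder starts unsynchronized and
#' must receive a shift table (see [decoder_apply_shifts()]) before decoding.
#'
#' @param config A [codec_config()].
#' @param n_channels Number of channels.
#' @return An `encoder_state` / `decoder_state` list.
#' @export
codec_reset <- function(config, n_channels = 24) {
  structure(list(
    r = numeric(n_channels), A = numeric(n_channels),
    s = integer(n_channels), samples_since_update = 0L,
    packet_id = 0L, dropped_since_last = 0L
  ), class = "encoder_state")
}

#' @rdname codec_reset
#' @export
decoder_reset <- function(config, n_channels = 24) {
  structure(list(
    r = numeric(n_channels), s = integer(n_channels),
    last_packet_id = NA_integer_, cumulative_dropped = 0L,
    synced = FALSE
  ), class = "decoder_state")
}

#' @rdname codec_reset
#' @param state A `decoder_state`.
#' @param shifts Integer vector of per-channel shifts in `[0, 15]`.
#' @param ref_packet_id Packet id from which the shifts apply.
#' @export
decoder_apply_shifts <- function(state, shifts, ref_packet_id = 0L) {
  stopifnot(all(shifts >= 0 & shifts <= 15))
  state$s <- as.integer(shifts)
  state$synced <- TRUE
  state
}

# round-half-away-from-zero of d / 2^s for integer-valued d
shift_round <- function(d, s) {
  half <- ifelse(s > 0, 2^(s - 1), 0)
  sign(d) * ((abs(d) + half) %/% 2^s)
}

#' Encode one multichannel frame
#'
#' Per channel: `d = counts - r`; the transmitted value is
#' `q = clip(round(d / 2^s), -2^(n-1), 2^(n-1)-1)` with half-away-from-zero
#' rounding; the reconstruction advances by `q * 2^s` (so encoder and
#' decoder reconstructions agree exactly on a lossless stream); the floating
#' average absorbs `|d|`.
#'
#' @param state An `encoder_state`.
#' @param counts Numeric vector of signed 24-bit counts, one per channel.
#' @param config A [codec_config()].
#' @return `list(deltas, state)`: the clipped quantized differences and the
#'   updated state (packet id advanced mod 16).
#' @export
encode_frame <- function(state, counts, config) {
  stopifnot(length(counts) == length(state$r))
  n <- config$bit_length
  d <- counts - state$r
  q <- shift_round(d, state$s)
  q <- pmin(pmax(q, -2^(n - 1)), 2^(n - 1) - 1)
  state$r <- state$r + q * 2^state$s
  state$A <- (1 - config$ema_lambda) * state$A + config$ema_lambda * abs(d)
  state$samples_since_update <- state$samples_since_update + 1L
  state$packet_id <- (state$packet_id + 1L) %% 16L
  list(deltas = q, state = state)
}

#' Select the per-channel shift code from the floating average
#'
#' The shift is the smallest value such that `headroom` times the floating
#' average still fits in the transmittable `bit_length - 1` magnitude bits:
#' `s = max(0, min(15, bitlength(ceil(A * headroom)) - (bit_length - 1)))`
#' with `bitlength(0) = 0`. Monotonically non-decreasing in `A`.
#'
#' @param A Non-negative floating average (counts), vectorised.
#' @param bit_length Transmitted width (10, 14 or 16).
#' @param headroom Safety factor.
#' @return Integer shifts in `[0, 15]`.
#' @export
update_shift <- function(A, bit_length, headroom = 8) {
  stopifnot(all(A >= 0))
  bl <- bitlength(ceiling(A * headroom))
  pmax(0L, pmin(15L, bl - (as.integer(bit_length) - 1L)))
}

#' Decode one frame of quantized differences
#'
#' @param state A `decoder_state` (synchronized).
#' @param deltas Quantized differences as transmitted.
#' @param config A [codec_config()].
#' @return `list(counts, state)`: the reconstructed sample and updated state.
#' @export
decode_frame <- function(state, deltas, config) {
  if (!state$synced)
    abort("decoder unsynchronized: no shift table received",
          class = "eegstream_unsynchronized")
  state$r <- state$r + deltas * 2^state$s
  list(counts = state$r, state = state)
}
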