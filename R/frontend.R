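#' Front-end filter and acquisition configuration
#'
#' Mirrors the on-board processing defaults: a 60 Hz order-6 Butterworth
#' low-pass, a 46-54 Hz order-4 Butterworth band-stop notch, analog gain 8,
#' block-average downsampling by 2 (250 Hz) or 3 (166.67 Hz, reported 167),
#' and a first-order 0.5 Hz high-pass applied after downsampling.
#'
#' @param lowpass_cutoff,lowpass_order Low-pass corner (Hz) and order.
#' @param notch_band,notch_order Band-stop edges (Hz) and order.
#' @param highpass_cutoff First-order high-pass corner (Hz), applied at the
#'   output rate.
#' @param downsample_factor 2 or 3.
#' @param gain Analog gain, one of 1, 2, 4, 8.
#' @return A `filter_config` list.
#' @export
filter_config <- function(lowpass_cutoff = 60, lowpass_order = 6,
                          notch_band = c(46, 54), notch_order = 4,
                          highpass_cutoff = 0.5,
                          downsample_factor = 2, gain = 8) {
  if (!downsample_factor %in% c(2L, 3L))
    abort("downsample_factor must be 2 or 3")
  if (!gain %in% c(1L, 2L, 4L, 8L)) abort("gain must be one of 1, 2, 4, 8")
  cfg <- list(lowpass_cutoff = lowpass_cutoff, lowpass_order = lowpass_order,
              notch_band = notch_band, notch_order = notch_order,
              highpass_cutoff = highpass_cutoff,
              downsample_factor = as.integer(downsample_factor),
              gain = as.integer(gain))
  class(cfg) <- "filter_config"
  cfg
}

#' Design the front-end IIR filters
#'
#' Butterworth designs for the low-pass and band-stop notch at the internal
#' rate, and a first-order Butterworth high-pass at the post-downsampling
#' output rate. All returned filters are stable (poles strictly inside the
#' unit circle).
#'
#' @param config A [filter_config()].
#' @param fs Internal sampling rate in Hz (500).
#' @return List with elements `lowpass`, `notch`, `highpass` (each a list
#'   with `b`, `a` polynomial coefficients), plus `fs` and `fs_out` (exact,
#'   possibly non-integer).
#' @export
design_filters <- function(config = filter_config(), fs = 500) {
  nyq <- fs / 2
  if (config$lowpass_cutoff >= nyq || any(config$notch_band >= nyq))
    abort("filter cutoffs must be below the Nyquist frequency")
  fs_out <- fs / config$downsample_factor
  if (config$highpass_cutoff >= fs_out / 2)
    abort("high-pass cutoff must be below the output Nyquist frequency")
  lp <- signal::butter(config$lowpass_order, config$lowpass_cutoff / nyq,
                       type = "low")
  bs <- signal::butter(config$notch_order, config$notch_band / nyq,
                       type = "stop")
  hp <- signal::butter(1, config$highpass_cutoff / (fs_out / 2), type = "high")
  out <- list(lowpass = list(b = lp$b, a = lp$a),
              notch = list(b = bs$b, a = bs$a),
              highpass = list(b = hp$b, a = hp$a),
              fs = fs, fs_out = fs_out)
  for (f in c("lowpass", "notch", "highpass")) {
    poles <- polyroot(rev(out[[f]]$a))
    if (any(Mod(poles) >= 1))
      abort(paste("designed", f, "filter is unstable"))
  }
  out
}

#' Complex frequency response of a digital filter
#'
#' @param filt List with `b`, `a` coefficients.
#' @param freqs Frequencies in Hz at which to evaluate.
#' @param fs Sampling rate in Hz.
#' @return Complex response; take `20*log10(Mod(.))` for dB.
#' @export
filter_response <- function(filt, freqs, fs) {
  w <- exp(-1i * 2 * pi * freqs / fs)
  num <- outer(w, seq_along(filt$b) - 1, `^`) %*% filt$b
  den <- outer(w, seq_along(filt$a) - 1, `^`) %*% filt$a
  as.vector(num / den)
}

#' Block-average downsampling
#'
#' Averages non-overlapping blocks of `factor` consecutive samples; a
#' trailing partial block is dropped. A 500 Hz input yields 250 Hz
#' (factor 2) or 500/3 Hz (factor 3, reported as 167 Hz).
#'
#' @param x Numeric vector or samples-x-channels matrix.
#' @param factor 2 or 3.
#' @return Downsampled vector/matrix of `floor(n / factor)` samples.
#' @export
downsample_avg <- function(x, factor) {
  if (!factor %in% c(2L, 3L)) abort("factor must be 2 or 3")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  if (nrow(x) < factor) abort("input shorter than one block")
  nb <- nrow(x) %/% factor
  x <- x[seq_len(nb * factor), , drop = FALSE]
  out <- 0
  for (k in seq_len(factor))
    out <- out + x[seq(k, by = factor, length.out = nb), , drop = FALSE]
  out <- out / factor
  if (vec) as.vector(out) else out
}

TWO23 <- 8388608  # 2^23

#' 24-bit ADC quantization
#'
#' `counts = round(v * gain * 2^23 / 2.5)` for a 2.5 V reference, clipped to
#' the signed 24-bit range (clipping is the defined overflow behaviour).
#' [dequantize()] inverts within one LSB: `|v - v_hat| <= 2.5 / (gain * 2^24)`
#' volts for in-range inputs.
#'
#' @param v Voltage (volts).
#' @param gain Analog gain, one of 1, 2, 4, 8.
#' @return Integer-valued counts (stored as doubles; range exceeds 16-bit).
#' @export
quantize <- function(v, gain) {
  if (!gain %in% c(1L, 2L, 4L, 8L)) abort("gain must be one of 1, 2, 4, 8")
  counts <- round(v * gain * TWO23 / 2.5)
  pmin(pmax(counts, -TWO23), TWO23 - 1)
}

#' @rdname quantize
#' @param counts Signed 24-bit counts.
#' @export
dequantize <- function(counts, gain) {
  counts * 2.5 / (gain * TWO23)
}

# -- stateful streaming engine -------------------------------------------

# One IIR section applied causally with carried input/output tails, so
# chunked processing is bit-identical to one-shot processing.
iir_section_new <- function(filt) {
  list(b = filt$b, a = filt$a,
       x_tail = rep(0, length(filt$b) - 1),
       y_tail = rep(0, length(filt$a) - 1))
}

iir_section_run <- function(sec, x) {
  nb <- length(sec$b)
  v <- stats::filter(c(sec$x_tail, x), sec$b, method = "convolution", sides = 1)
  if (nb > 1) v <- v[-seq_len(nb - 1)]
  if (length(sec$a) > 1) {
    y <- as.numeric(stats::filter(v, -sec$a[-1], method = "recursive",
                                  init = rev(sec$y_tail)))
  } else y <- as.numeric(v)
  if (nb > 1) sec$x_tail <- utils::tail(c(sec$x_tail, x), nb - 1)
  if (length(sec$a) > 1) sec$y_tail <- utils::tail(c(sec$y_tail, y), length(sec$a) - 1)
  list(sec = sec, y = y)
}

#' Streaming front-end processor
#'
#' `frontend_state()` initialises per-channel filter state (zero initial
#' conditions, emulating a causal firmware chain); `frontend_process()`
#' consumes a chunk of raw samples (microvolts, samples x channels) and
#' returns the quantized output frames produced so far. Chunked processing
#' is exactly identical to one-shot processing.
#'
#' @param config A [filter_config()].
#' @param n_channels Number of channels.
#' @param fs Input rate (Hz).
#' @return For `frontend_state()`: an opaque state list. For
#'   `frontend_process()`: `list(state, counts)` where `counts` is a matrix
#'   of signed 24-bit counts (possibly 0 rows).
#' @export
frontend_state <- function(config = filter_config(), n_channels = 24, fs = 500) {
  filts <- design_filters(config, fs)
  list(config = config, fs = fs, fs_out = filts$fs_out,
       lp = replicate(n_channels, iir_section_new(filts$lowpass), simplify = FALSE),
       bs = replicate(n_channels, iir_section_new(filts$notch), simplify = FALSE),
       hp = replicate(n_channels, iir_section_new(filts$highpass), simplify = FALSE),
       carry = matrix(numeric(0), ncol = n_channels),
       n_channels = n_channels)
}

#' @rdname frontend_state
#' @param state State from `frontend_state()` or a previous call.
#' @param chunk Matrix of raw samples (microvolts), samples x channels.
#' @export
frontend_process <- function(state, chunk) {
  stopifnot(ncol(chunk) == state$n_channels)
  factor <- state$config$downsample_factor
  filtered <- matrix(0, nrow = nrow(chunk), ncol = ncol(chunk))
  for (ch in seq_len(state$n_channels)) {
    r1 <- iir_section_run(state$lp[[ch]], chunk[, ch]); state$lp[[ch]] <- r1$sec
    r2 <- iir_section_run(state$bs[[ch]], r1$y); state$bs[[ch]] <- r2$sec
    filtered[, ch] <- r2$y
  }
  buf <- rbind(state$carry, filtered)
  nb <- nrow(buf) %/% factor
  if (nb > 0) {
    ds <- downsample_avg(buf[seq_len(nb * factor), , drop = FALSE], factor)
    if (is.null(dim(ds))) ds <- matrix(ds, ncol = state$n_channels)
    state$carry <- buf[seq_len(nrow(buf)) > nb * factor, , drop = FALSE]
    out <- matrix(0, nrow = nb, ncol = state$n_channels)
    for (ch in seq_len(state$n_channels)) {
      r3 <- iir_section_run(state$hp[[ch]], ds[, ch]); state$hp[[ch]] <- r3$sec
      out[, ch] <- r3$y
    }
    counts <- quantize(out * 1e-6, state$config$gain)
  } else {
    state$carry <- buf
    counts <- matrix(numeric(0), ncol = state$n_channels)
  }
  list(state = state, counts = counts)
}

#' Run the full front end over a recording
#'
#' Applies low-pass, notch, block-average downsampling, first-order
#' high-pass and 24-bit quantization, in that order, with zero initial
#' conditions (causal single pass). Trigger onsets are carried over to the
#' output rate.
#'
#' @param rec An [new_eeg_recording()] at 500 Hz (microvolts).
#' @param config A [filter_config()].
#' @return An `eeg_frames` tibble: `time_s`, one integer count column per
#'   channel, `trigger`; attributes `fs` (exact output rate), `fs_reported`
#'   (250 or 167) and `gain`.
#' @export
run_frontend <- function(rec, config = filter_config()) {
  labels <- recording_channels(rec)
  st <- frontend_state(config, n_channels = length(labels), fs = recording_fs(rec))
  res <- frontend_process(st, recording_matrix(rec))
  counts <- res$counts
  factor <- config$downsample_factor
  fs_out <- recording_fs(rec) / factor

  trig_in <- which(rec$trigger != 0L)
  trigger <- integer(nrow(counts))
  trig_out <- (trig_in - 1L) %/% factor + 1L
  keep <- trig_out <= nrow(counts)
  trigger[trig_out[keep]] <- rec$trigger[trig_in[keep]]

  out <- tibble(time_s = (seq_len(nrow(counts)) - 1) / fs_out)
  cm <- as_tibble(as.data.frame(counts, optional = TRUE), .name_repair = "minimal")
  names(cm) <- labels
  out <- dplyr::bind_cols(out, cm)
  out$trigger <- trigger
  attr(out, "fs") <- fs_out
  attr(out, "fs_reported") <- as.integer(round(fs_out))
  attr(out, "gain") <- config$gain
  class(out) <- c("eeg_frames", class(out))
  out
}

#' Convert decoded counts back to a microvolt recording
#'
#' @param frames An `eeg_frames` tibble (or any tibble of counts with
#'   `time_s`/`trigger`), with `fs` and `gain` attributes.
#' @param gain Gain override; defaults to the `gain` attribute.
#' @return An `eeg_recording` tibble in microvolts.
#' @export
frames_to_recording <- function(frames, gain = attr(frames, "gain")) {
  labels <- setdiff(names(frames), c("time_s", "trigger"))
  uv <- dequantize(as.matrix(frames[labels]), gain) * 1e6
  new_eeg_recording(uv, attr(frames, "fs"), labels,
                    trigger = frames$trigger)
}
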