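#' Configuration for the synthetic resting-state session generator
#'
#' Defaults emulate the alternating eyes-open / eyes-closed protocol used to
#' validate the acquisition chain: a 20-minute session of 2-minute condition
#' blocks starting eyes-closed, sampled internally at 500 Hz. Eyes-closed
#' blocks carry a waxing-and-waning ~10 Hz alpha oscillation on the occipital
#' channels (O1, OZ, O2, POZ); eyes-open blocks carry 1.5-3.5 Hz delta
#' activity on the prefrontal/frontal channels plus blink and saccade
#' transients dominant on FP1/FPZ/FP2; every channel receives 50 Hz line
#' interference and 1/f background noise.
#'
#' @param duration_s Session length in seconds; must be a positive multiple
#'   of `block_s`.
#' @param block_s Length of one condition block in seconds.
#' @param fs_internal Internal ADC rate in Hz; fixed at 500.
#' @param channel_labels The 24 montage labels, in recording order.
#' @param seed Integer seed; identical configurations generate identical
#'   sessions.
#' @param alpha_freq,alpha_amp_uV Alpha oscillation frequency (Hz) and mean
#'   amplitude (microvolts).
#' @param delta_band,delta_amp_uV Delta band edges (Hz) and rms amplitude of
#'   the frontal eyes-open delta component (microvolts).
#' @param blink_rate_hz,blink_amp_uV Blink rate during eyes-open blocks
#'   (events per second) and blink peak amplitude (microvolts).
#' @param line_freq,line_amp_uV Mains interference frequency (Hz) and
#'   amplitude (microvolts).
#' @param noise_rms_uV Total rms of the 1/f background per channel
#'   (microvolts).
#' @return A `session_config` list.
#' @export
session_config <- function(duration_s = 1200, block_s = 120, fs_internal = 500,
                           channel_labels = montage_labels(), seed = 1L,
                           alpha_freq = 10, alpha_amp_uV = 20,
                           delta_band = c(1.5, 3.5), delta_amp_uV = 15,
                           blink_rate_hz = 0.25, blink_amp_uV = 120,
                           line_freq = 50, line_amp_uV = 5,
                           noise_rms_uV = 10) {
  cfg <- list(
    duration_s = duration_s, block_s = block_s, fs_internal = fs_internal,
    channel_labels = channel_labels, seed = seed,
    alpha_freq = alpha_freq, alpha_amp_uV = alpha_amp_uV,
    delta_band = delta_band, delta_amp_uV = delta_amp_uV,
    blink_rate_hz = blink_rate_hz, blink_amp_uV = blink_amp_uV,
    line_freq = line_freq, line_amp_uV = line_amp_uV,
    noise_rms_uV = noise_rms_uV
  )
  validate_session_config(cfg)
  class(cfg) <- "session_config"
  cfg
}

validate_session_config <- function(cfg) {
  if (cfg$fs_internal != 500) abort("fs_internal is fixed at 500 Hz")
  if (cfg$duration_s <= 0 || cfg$block_s <= 0 ||
      abs(cfg$duration_s / cfg$block_s - round(cfg$duration_s / cfg$block_s)) > 1e-9)
    abort("duration_s must be a positive multiple of block_s")
  unknown <- setdiff(cfg$channel_labels, montage_labels())
  if (length(unknown) > 0)
    abort(paste("unknown channel labels:", paste(unknown, collapse = ", ")))
  if (length(cfg$channel_labels) != 24 || anyDuplicated(cfg$channel_labels) > 0)
    abort("channel_labels must be 24 distinct montage labels")
  amps <- c(cfg$alpha_amp_uV, cfg$delta_amp_uV, cfg$blink_amp_uV,
            cfg$line_amp_uV, cfg$noise_rms_uV)
  if (any(amps < 0)) abort("amplitudes must be non-negative")
  if (length(cfg$delta_band) != 2 || cfg$delta_band[1] >= cfg$delta_band[2])
    abort("delta_band must be an increasing frequency pair")
  invisible(cfg)
}

# Channels carrying each synthetic component.
ALPHA_CHANNELS <- c("O1", "O2", "OZ", "POZ")
DELTA_CHANNELS <- c("FP1", "FPZ", "FP2", "F7", "F3", "FZ", "F4", "F8")
BLINK_WEIGHTS <- c(FP1 = 1, FPZ = 1, FP2 = 1,
                   F7 = 0.3, F3 = 0.3, FZ = 0.3, F4 = 0.3, F8 = 0.3)
SACCADE_WEIGHTS <- c(FP1 = 1, FPZ = 1, FP2 = 1,
                     F7 = 0.5, F3 = 0.5, FZ = 0.5, F4 = 0.5, F8 = 0.5)

#' Generate a synthetic resting-state session
#'
#' @param config A [session_config()].
#' @return An [new_eeg_recording()] tibble at the internal 500 Hz rate with
#'   condition onsets in the `trigger` column (first block eyes-closed,
#'   first onset at sample 0).
#' @examples
#' rec <- generate_session(session_config(duration_s = 60, block_s = 30))
#' recording_events(rec)
#' @export
generate_session <- function(config = session_config()) {
  validate_session_config(config)
  fs <- config$fs_internal
  n <- round(config$duration_s * fs)
  block_n <- round(config$block_s * fs)
  n_blocks <- n %/% block_n
  labels <- config$channel_labels

  # odd blocks (1st, 3rd, ...) are eyes-closed
  block_cond <- rep(c("eyes_closed", "eyes_open"), length.out = n_blocks)
  cond <- rep(block_cond, each = block_n)
  closed <- cond == "eyes_closed"
  open <- !closed
  trigger <- integer(n)
  trigger[1 + (seq_len(n_blocks) - 1) * block_n] <-
    ifelse(block_cond == "eyes_closed", 2L, 1L)

  t <- (seq_len(n) - 1) / fs
  data <- matrix(0, nrow = n, ncol = 24, dimnames = list(NULL, labels))

  with_private_seed(config$seed, {
    # 1/f background, independent per channel
    if (config$noise_rms_uV > 0) {
      for (ch in seq_len(24)) {
        data[, ch] <- data[, ch] +
          one_over_f_noise(n, fs, config$noise_rms_uV)
      }
    }

    # common-phase mains interference on every channel
    if (config$line_amp_uV > 0) {
      phi <- runif(1, 0, 2 * pi)
      line <- config$line_amp_uV * sin(2 * pi * config$line_freq * t + phi)
      data <- data + line
    }

    # occipital alpha with slow stochastic amplitude modulation, eyes-closed only
    if (config$alpha_amp_uV > 0) {
      env <- gaussian_envelope(n, fs, tau = 1)
      alpha <- config$alpha_amp_uV * env *
        sin(2 * pi * config$alpha_freq * t + runif(1, 0, 2 * pi))
      alpha[open] <- 0
      for (ch in intersect(ALPHA_CHANNELS, labels))
        data[, ch] <- data[, ch] + alpha
    }

    # frontal delta during eyes-open, independent band-limited noise per channel
    if (config$delta_amp_uV > 0) {
      bp <- signal::butter(4, config$delta_band / (fs / 2), type = "pass")
      for (ch in intersect(DELTA_CHANNELS, labels)) {
        z <- as.numeric(signal::filtfilt(bp, rnorm(n)))
        z <- z / stats::sd(z) * config$delta_amp_uV
        z[closed] <- 0
        data[, ch] <- data[, ch] + z
      }
    }

    # blink and saccade transients during eyes-open blocks, accumulated as
    # shared event trains and then weighted onto the frontal channels
    if (config$blink_amp_uV > 0) {
      blink_train <- numeric(n)
      sac_train <- numeric(n)
      for (b in which(block_cond == "eyes_open")) {
        b0 <- (b - 1) * block_n   # 0-based block start
        # one saccade within 1 s of the eyes-open onset
        sac <- saccade_waveform(fs, 0.7 * config$blink_amp_uV)
        s0 <- b0 + round(runif(1, 0.1, 1 - length(sac) / fs) * fs)
        sac_train <- add_transient(sac_train, sac, s0)
        # Poisson blink train
        n_blinks <- rpois(1, config$blink_rate_hz * config$block_s)
        if (n_blinks > 0) {
          starts <- sort(runif(n_blinks, 0, config$block_s - 0.5))
          for (st in starts) {
            w <- generate_blink(fs, runif(1, 0.3, 0.5), config$blink_amp_uV)
            blink_train <- add_transient(blink_train, w, b0 + round(st * fs))
          }
        }
      }
      for (ch in intersect(names(BLINK_WEIGHTS), labels))
        data[, ch] <- data[, ch] + BLINK_WEIGHTS[[ch]] * blink_train +
          SACCADE_WEIGHTS[[ch]] * sac_train
    }
  })

  new_eeg_recording(data, fs, labels, trigger)
}

# Add waveform w (starting at 0-based sample s0) into an event train.
add_transient <- function(train, w, s0) {
  idx <- (s0 + 1):min(s0 + length(w), length(train))
  train[idx] <- train[idx] + w[seq_along(idx)]
  train
}

#' Biphasic blink transient
#'
#' The classic frontal blink artifact: a dominant narrow positive
#' deflection followed by a wider, shallower undershoot (two Gaussian
#' lobes on `u = t / duration`, the undershoot scaled for an exactly
#' zero-mean sampled waveform). The template is analytic in `u`, so the
#' peak time in seconds does not depend on the sampling rate, and it is
#' normalized so the sampled peak magnitude equals `amp_uV`.
#'
#' @param fs Sampling rate in Hz (> 0).
#' @param duration_s Blink duration in seconds, within `[0.3, 0.5]`.
#' @param amp_uV Peak amplitude in microvolts.
#' @return Numeric waveform of `round(fs * duration_s)` samples.
#' @examples
#' w <- generate_blink(500, 0.4, 120)
#' length(w)
#' max(abs(w))
#' @export
generate_blink <- function(fs, duration_s, amp_uV) {
  if (fs <= 0) abort("fs must be positive")
  if (duration_s < 0.3 || duration_s > 0.5)
    abort("blink duration must lie in [0.3, 0.5] s")
  n <- round(fs * duration_s)
  u <- (seq_len(n) - 1) / n
  g1 <- exp(-((u - 0.35) / 0.12)^2)
  g2 <- exp(-((u - 0.72) / 0.32)^2)
  w <- g1 - (sum(g1) / sum(g2)) * g2
  w / max(abs(w)) * amp_uV
}

# Brief high-frequency damped oscillation marking an eye movement at
# condition onset (20 Hz burst, 200 ms).
saccade_waveform <- function(fs, amp_uV) {
  n <- round(0.2 * fs)
  tt <- (seq_len(n) - 1) / fs
  w <- sin(2 * pi * 20 * tt) * exp(-tt / 0.05)
  w / max(abs(w)) * amp_uV
}

# Spectrally shaped Gaussian noise with power ~ 1/f above 0.1 Hz (flat
# below, so the variance stays finite for long sessions), scaled to the
# requested rms.
one_over_f_noise <- function(n, fs, rms) {
  z <- rnorm(n)
  zf <- fft(z)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)           # two-sided spectrum folding
  scale <- 1 / sqrt(pmax(f, 0.1))
  scale[1] <- 0                  # no DC
  x <- Re(fft(zf * scale, inverse = TRUE)) / n
  x / stats::sd(x) * rms
}

# Slow positive amplitude envelope: unit-variance Gaussian noise smoothed
# with a Gaussian kernel of width tau seconds (FFT circular convolution on
# a padded vector), mapped to mean ~1, sd 0.5, clipped at zero
# (waxing-waning alpha spindles).
gaussian_envelope <- function(n, fs, tau = 1) {
  half <- round(4 * tau * fs)
  k <- exp(-0.5 * ((-half:half) / (tau * fs))^2)
  k <- k / sum(k)
  m <- n + 2 * half
  z <- rnorm(m)
  kp <- numeric(m)
  kp[1:(half + 1)] <- k[(half + 1):(2 * half + 1)]
  kp[(m - half + 1):m] <- k[1:half]
  sm <- Re(fft(fft(z) * fft(kp), inverse = TRUE)) / m
  sm <- sm[(half + 1):(half + n)]
  sm <- (sm - mean(sm)) / stats::sd(sm)
  pmax(0, 1 + 0.5 * sm)
}
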