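#' Canonical frequency bands
#'
#' @return Tibble with `band`, `low`, `high` (Hz): Delta 1-4, Theta 4-8,
#'   Alpha 8-12, Beta 12-30. Bands are integrated over `[low, high)`.
#' @export
eeg_bands <- function() {
  tibble(band = c("delta", "theta", "alpha", "beta"),
         low = c(1, 4, 8, 12), high = c(4, 8, 12, 30))
}

#' Preprocess a decoded recording
#'
#' Zero-phase 1-30 Hz Butterworth band-pass, per-channel baseline (whole
#' recording mean) subtraction, and bad-channel removal: channels whose
#' robust SD (MAD) exceeds `bad_sd_factor` times the median robust SD across
#' channels, or is zero, are dropped and recorded in the `bad_channels`
#' attribute.
#'
#' @param rec An `eeg_recording` (typically the decoded 250 or 167 Hz
#'   output of [transmit_recording()]).
#' @param low,high Band edges in Hz.
#' @param order Butterworth order (applied forwards and backwards).
#' @param bad_sd_factor Robust-SD multiple above which a channel is bad.
#' @param remove_bad Set `FALSE` to keep all channels (no rejection).
#' @return The filtered recording; attribute `bad_channels` lists removals.
#' @export
preprocess <- function(rec, low = 1, high = 30, order = 4,
                       bad_sd_factor = 5, remove_bad = TRUE) {
  fs <- recording_fs(rec)
  labels <- recording_channels(rec)
  x <- recording_matrix(rec)
  x <- sweep(x, 2, colMeans(x)) # baseline correction
  bp <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  for (ch in seq_along(labels))
    x[, ch] <- as.numeric(signal::filtfilt(bp, x[, ch]))

  bad <- character(0)
  if (remove_bad) {
    rsd <- apply(x, 2, stats::mad)
    bad <- labels[rsd == 0 | rsd > bad_sd_factor * median(rsd)]
    if (length(bad) == length(labels))
      abort("all channels rejected as bad; check the recording")
    x <- x[, !(labels %in% bad), drop = FALSE]
    labels <- setdiff(labels, bad)
  }
  out <- new_eeg_recording(x, fs, labels, trigger = rec$trigger)
  attr(out, "bad_channels") <- bad
  out
}

#' Segment a recording into fixed-length condition epochs
#'
#' Within each condition block, consecutive non-overlapping epochs of
#' `epoch_len_s` seconds; the trailing remainder of each block is dropped,
#' and blocks shorter than one epoch contribute nothing (with a warning).
#'
#' @param rec A preprocessed `eeg_recording` with trigger events.
#' @param epoch_len_s Epoch length in seconds.
#' @return An `eeg_epochs` tibble: `condition`, `epoch`, `start_s`, and a
#'   `signal` list-column of channels x samples matrices; attributes `fs`,
#'   `labels`, `epoch_len_s`.
#' @export
epoch_recording <- function(rec, epoch_len_s = 15) {
  fs <- recording_fs(rec)
  ev <- recording_events(rec)
  if (nrow(ev) == 0) abort("recording has no condition events")
  nsamp <- round(epoch_len_s * fs)
  x <- t(recording_matrix(rec)) # channels x samples
  bounds <- c(ev$sample, nrow(rec)) # 0-based block boundaries
  rows <- list()
  short_blocks <- 0L
  for (i in seq_len(nrow(ev))) {
    block_len <- bounds[i + 1] - bounds[i]
    k <- block_len %/% nsamp
    if (k == 0) {
      short_blocks <- short_blocks + 1L
      next
    }
    for (j in seq_len(k)) {
      s0 <- bounds[i] + (j - 1) * nsamp # 0-based epoch start
      rows[[length(rows) + 1L]] <- tibble(
        condition = ev$condition[i],
        start_s = s0 / fs,
        signal = list(x[, (s0 + 1):(s0 + nsamp), drop = FALSE]))
    }
  }
  if (short_blocks > 0)
    warn(sprintf("%d condition block(s) shorter than one epoch were skipped",
                 short_blocks))
  if (length(rows) == 0) abort("no complete epochs could be formed")
  out <- bind_rows(rows)
  out$epoch <- seq_len(nrow(out))
  out <- out[, c("condition", "epoch", "start_s", "signal")]
  attr(out, "fs") <- fs
  attr(out, "labels") <- recording_channels(rec)
  attr(out, "epoch_len_s") <- epoch_len_s
  class(out) <- c("eeg_epochs", class(out))
  out
}

#' Reject high-amplitude epochs
#'
#' Removes epochs in which any channel's peak-to-peak amplitude exceeds the
#' threshold (default 250 microvolts, which passes the generator's default
#' blink morphology while catching gross artifacts). Order is retained.
#'
#' @param epochs An `eeg_epochs` tibble.
#' @param ptp_threshold_uV Peak-to-peak rejection threshold in microvolts.
#' @return The surviving epochs; attribute `n_rejected` counts removals.
#' @export
reject_bad_epochs <- function(epochs, ptp_threshold_uV = 250) {
  ptp <- purrr::map_dbl(epochs$signal, function(m)
    max(apply(m, 1, function(v) diff(range(v)))))
  keep <- ptp <= ptp_threshold_uV
  if (!any(keep)) abort("all epochs rejected; raise the threshold")
  out <- epochs[keep, , drop = FALSE]
  for (a in c("fs", "labels", "epoch_len_s"))
    attr(out, a) <- attr(epochs, a)
  attr(out, "n_rejected") <- sum(!keep)
  class(out) <- unique(c("eeg_epochs", class(out)))
  out
}

hanning_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

# Sine tapers (Riedel & Sidorenko): orthonormal multitaper family that
# needs no external dependency; used by the optional multitaper mode.
sine_tapers <- function(n, k) {
  sapply(seq_len(k), function(j)
    sqrt(2 / (n + 1)) * sin(pi * j * seq_len(n) / (n + 1)))
}

#' Power spectral density of epoched data
#'
#' Per epoch and channel, a single Hanning-tapered FFT periodogram with
#' density scaling (microvolts squared per Hz, one-sided); frequency
#' resolution is the reciprocal epoch length (about 0.067 Hz at 15 s).
#' `taper = "multitaper"` averages `n_tapers` orthonormal sine tapers
#' instead.
#'
#' @param epochs An `eeg_epochs` tibble.
#' @param taper `"hanning"` (default) or `"multitaper"`.
#' @param n_tapers Number of sine tapers for the multitaper mode.
#' @param fmax Keep only frequencies up to `fmax` Hz (NULL for the full
#'   grid up to Nyquist).
#' @return An `eeg_psd` object: list with `freqs`, `info` (condition /
#'   epoch / channel per row), `power` (rows aligned with `info`, columns
#'   are frequencies), and `taper`.
#' @export
compute_psd <- function(epochs, taper = c("hanning", "multitaper"),
                        n_tapers = 5, fmax = NULL) {
  taper <- match.arg(taper)
  fs <- attr(epochs, "fs")
  labels <- attr(epochs, "labels")
  if (nrow(epochs) < 1) abort("at least one epoch is required")
  n <- ncol(epochs$signal[[1]])
  if (n < 2) abort("epochs must contain at least 2 samples")
  tapers <- if (taper == "hanning") matrix(hanning_window(n), ncol = 1)
            else sine_tapers(n, n_tapers)
  nf <- n %/% 2 + 1
  freqs <- (seq_len(nf) - 1) * fs / n
  keep_f <- if (is.null(fmax)) rep(TRUE, nf) else freqs <= fmax

  one_sided <- function(P) {
    P[2:(nf - 1 + n %% 2)] <- 2 * P[2:(nf - 1 + n %% 2)]
    P
  }
  info <- tidyr::expand_grid(
    epochs[, c("condition", "epoch")],
    channel = labels)
  power <- matrix(0, nrow = nrow(info), ncol = sum(keep_f))
  row <- 1L
  for (e in seq_len(nrow(epochs))) {
    sig <- epochs$signal[[e]]
    for (ch in seq_along(labels)) {
      acc <- 0
      for (k in seq_len(ncol(tapers))) {
        w <- tapers[, k]
        X <- fft(sig[ch, ] * w)[seq_len(nf)]
        acc <- acc + one_sided(Mod(X)^2 / (fs * sum(w^2)))
      }
      power[row, ] <- (acc / ncol(tapers))[keep_f]
      row <- row + 1L
    }
  }
  structure(list(freqs = freqs[keep_f], info = info, power = power,
                 taper = taper, fs = fs),
            class = "eeg_psd")
}

#' Integrated band power
#'
#' Trapezoidal integral of the PSD over `[low, high)` per epoch and channel.
#'
#' @param psd An `eeg_psd` from [compute_psd()].
#' @param low,high Band edges in Hz.
#' @return Tibble with `condition`, `epoch`, `channel`, `power`
#'   (microvolts squared).
#' @export
band_power <- function(psd, low, high) {
  sel <- which(psd$freqs >= low & psd$freqs < high)
  if (length(sel) < 2) abort("band contains fewer than two frequency bins")
  f <- psd$freqs[sel]
  w <- trapezoid_weights(f)
  out <- psd$info
  out$power <- as.vector(psd$power[, sel, drop = FALSE] %*% w)
  out
}

trapezoid_weights <- function(f) {
  n <- length(f)
  w <- numeric(n)
  w[1] <- (f[2] - f[1]) / 2
  w[n] <- (f[n] - f[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (f[3:n] - f[1:(n - 2)]) / 2
  w
}

# connected components of the subgraph induced by `members` (logical) in a
# symmetric adjacency matrix; returns a list of integer index vectors
connected_components <- function(adj, members) {
  idx <- which(members)
  comps <- list()
  seen <- logical(nrow(adj))
  for (v in idx) {
    if (seen[v]) next
    queue <- v
    seen[v] <- TRUE
    comp <- integer(0)
    while (length(queue) > 0) {
      u <- queue[1]
      queue <- queue[-1]
      comp <- c(comp, u)
      nb <- which(adj[u, ] & members & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# pooled-variance independent-samples t statistics for every channel and
# every permutation at once; g is an n x n_perm 0/1 matrix of group-1
# membership (column sums all equal n1)
perm_t_stats <- function(X, g, n1, n2) {
  sum1 <- crossprod(X, g)               # channels x perms
  sumsq1 <- crossprod(X^2, g)
  tot <- colSums(X)
  totsq <- colSums(X^2)
  m1 <- sum1 / n1
  m2 <- (tot - sum1) / n2
  ss1 <- sumsq1 - n1 * m1^2
  ss2 <- (totsq - sumsq1) - n2 * m2^2
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  sp2 <- pmax(sp2, .Machine$double.eps) # degenerate-variance guard
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

max_cluster_stat <- function(tv, thresh, adj) {
  best <- 0
  for (sgn in c(1, -1)) {
    members <- sgn * tv > thresh
    if (!any(members)) next
    for (comp in connected_components(adj, members))
      best <- max(best, abs(sum(tv[comp])))
  }
  best
}

#' Cluster-based permutation test on band-power topographies
#'
#' Compares eyes-closed against eyes-open band power per channel with
#' independent-samples t statistics on log10 power, joins supra-threshold
#' channels (|t| above the two-sided critical value at `cluster_alpha`)
#' into adjacency-connected clusters of equal sign, scores each cluster by
#' the sum of member t values, and calibrates cluster p values against the
#' permutation distribution of the maximum absolute cluster score under
#' random condition-label exchange:
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param bp A band-power tibble from [band_power()] with both conditions
#'   (epochs are treated as independent observations, a single-subject
#'   fixed-effects design).
#' @param adjacency Symmetric logical channel adjacency; defaults to
#'   [montage_adjacency()] restricted to the channels present.
#' @param n_perm Number of random label permutations.
#' @param cluster_alpha Cluster-forming (per-channel) alpha.
#' @param seed Integer seed for the permutation draws; the caller's RNG
#'   state is left untouched.
#' @param log_transform Test log10 power (variance stabilization); set
#'   `FALSE` to test raw power.
#' @return An `eeg_clusters` object; see [tidy.eeg_clusters()].
#' @export
cluster_permutation_test <- function(bp, adjacency = NULL, n_perm = 1000,
                                     cluster_alpha = 0.05, seed = NULL,
                                     log_transform = TRUE) {
  channels <- unique(bp$channel)
  if (is.null(adjacency)) {
    m <- default_montage()
    adjacency <- montage_adjacency(m[m$label %in% channels, , drop = FALSE])
  }
  if (!all(channels %in% rownames(adjacency)))
    abort("adjacency must cover all channels present")
  adjacency <- adjacency[channels, channels]

  wide <- tidyr::pivot_wider(bp, id_cols = c("condition", "epoch"),
                             names_from = "channel", values_from = "power")
  X <- as.matrix(wide[, channels, drop = FALSE])
  if (log_transform) X <- log10(pmax(X, .Machine$double.xmin))
  closed <- wide$condition == "eyes_closed"
  n1 <- sum(closed)
  n2 <- sum(!closed)
  if (n1 < 2 || n2 < 2) abort("need at least 2 epochs per condition")
  N <- n1 + n2
  thresh <- qt(1 - cluster_alpha / 2, df = N - 2)

  g_obs <- matrix(as.numeric(closed), ncol = 1)
  t_obs <- as.vector(perm_t_stats(X, g_obs, n1, n2))

  clusters <- list()
  for (sgn in c(1, -1)) {
    for (comp in connected_components(adjacency, sgn * t_obs > thresh)) {
      clusters[[length(clusters) + 1L]] <- tibble(
        direction = if (sgn > 0) "closed>open" else "open>closed",
        channels = list(channels[comp]),
        stat = sum(t_obs[comp]))
    }
  }

  null_max <- numeric(n_perm)
  if (n_perm > 0) {
    G <- with_private_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        gi <- numeric(N)
        gi[sample.int(N, n1)] <- 1
        gi
      }, numeric(N))
    })
    Tperm <- perm_t_stats(X, G, n1, n2)
    for (p in seq_len(n_perm))
      null_max[p] <- max_cluster_stat(Tperm[, p], thresh, adjacency)
  }

  cl <- if (length(clusters) > 0) bind_rows(clusters) else
    tibble(direction = character(), channels = list(), stat = numeric())
  cl$p_value <- vapply(cl$stat, function(s)
    (1 + sum(null_max >= abs(s))) / (1 + n_perm), numeric(1))
  cl <- arrange(cl, .data$p_value, dplyr::desc(abs(.data$stat)))
  cl$cluster <- seq_len(nrow(cl))
  cl <- cl[, c("cluster", "direction", "channels", "stat", "p_value")]

  structure(list(
    clusters = cl,
    t_values = tibble(channel = channels, t = t_obs,
                      supra = abs(t_obs) > thresh),
    t_threshold = thresh, cluster_alpha = cluster_alpha,
    n_perm = n_perm, n_closed = n1, n_open = n2,
    null_max = null_max, adjacency = adjacency
  ), class = "eeg_clusters")
}

#' One-call resting-state contrast analysis
#'
#' Chains [preprocess()], [epoch_recording()], [reject_bad_epochs()],
#' [compute_psd()], [band_power()] and [cluster_permutation_test()] for a
#' set of frequency bands.
#'
#' @param rec A decoded `eeg_recording` with condition triggers.
#' @param bands Band definition tibble as in [eeg_bands()].
#' @param epoch_len_s Epoch length (s).
#' @param ptp_threshold_uV Epoch rejection threshold.
#' @param n_perm,cluster_alpha,seed Passed to
#'   [cluster_permutation_test()].
#' @return A list with the preprocessed recording's `psd` and one
#'   `eeg_clusters` element per band (named by band).
#' @export
analyze_session <- function(rec, bands = eeg_bands(), epoch_len_s = 15,
                            ptp_threshold_uV = 250, n_perm = 1000,
                            cluster_alpha = 0.05, seed = NULL) {
  pre <- preprocess(rec)
  ep <- reject_bad_epochs(epoch_recording(pre, epoch_len_s), ptp_threshold_uV)
  psd <- compute_psd(ep, fmax = 45)
  tests <- purrr::pmap(bands, function(band, low, high) {
    cluster_permutation_test(band_power(psd, low, high),
                             n_perm = n_perm, cluster_alpha = cluster_alpha,
                             seed = seed)
  })
  names(tests) <- bands$band
  list(psd = psd, clusters = tests, bad_channels = attr(pre, "bad_channels"),
       n_epochs_rejected = attr(ep, "n_rejected"))
}
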