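#' Tidy a cluster permutation result
#'
#' @param x An `eeg_clusters` object.
#' @param ... Unused.
#' @return One row per cluster: `cluster`, `direction`, `n_channels`,
#'   `channels` (comma-separated), `stat`, `p_value`.
#' @export
tidy.eeg_clusters <- function(x, ...) {
  cl <- x$clusters
  tibble(cluster = cl$cluster, direction = cl$direction,
         n_channels = lengths(cl$channels),
         channels = vapply(cl$channels, paste, character(1), collapse = ","),
         stat = cl$stat, p_value = cl$p_value)
}

#' @rdname tidy.eeg_clusters
#' @export
glance.eeg_clusters <- function(x, ...) {
  tibble(n_perm = x$n_perm, cluster_alpha = x$cluster_alpha,
         t_threshold = x$t_threshold, n_closed = x$n_closed,
         n_open = x$n_open, n_clusters = nrow(x$clusters),
         min_p = if (nrow(x$clusters)) min(x$clusters$p_value) else NA_real_)
}

#' @export
print.eeg_clusters <- function(x, ...) {
  cat(sprintf(
    "Cluster permutation test: %d closed vs %d open epochs, %d permutations\n",
    x$n_closed, x$n_open, x$n_perm))
  cat(sprintf("cluster-forming |t| > %.3f (alpha = %g)\n",
              x$t_threshold, x$cluster_alpha))
  if (nrow(x$clusters) == 0) cat("no supra-threshold clusters\n")
  else print(tidy(x))
  invisible(x)
}

#' Tidy a PSD result into long form
#'
#' @param x An `eeg_psd` object.
#' @param ... Unused.
#' @return Tibble with `condition`, `epoch`, `channel`, `freq`, `power`.
#' @export
tidy.eeg_psd <- function(x, ...) {
  out <- x$info[rep(seq_len(nrow(x$info)), each = length(x$freqs)), ]
  out$freq <- rep(x$freqs, times = nrow(x$info))
  out$power <- as.vector(t(x$power))
  as_tibble(out)
}

#' @rdname tidy.eeg_psd
#' @export
glance.eeg_psd <- function(x, ...) {
  tibble(n_epochs = length(unique(x$info$epoch)),
         n_channels = length(unique(x$info$channel)),
         n_freqs = length(x$freqs),
         df_resolution = x$freqs[2] - x$freqs[1],
         taper = x$taper, fs = x$fs)
}

#' Condition-mean spectra
#'
#' @param psd An `eeg_psd`.
#' @param channels Channels to keep (default all).
#' @return Tibble `condition`, `channel`, `freq`, mean `power` across
#'   epochs.
#' @export
psd_condition_means <- function(psd, channels = NULL) {
  long <- tidy(psd)
  if (!is.null(channels)) long <- filter(long, .data$channel %in% channels)
  long |>
    group_by(.data$condition, .data$channel, .data$freq) |>
    summarise(power = mean(.data$power), .groups = "drop")
}
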