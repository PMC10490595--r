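#' Plot condition-mean spectra
#'
#' @param object An `eeg_psd` object.
#' @param channels Channels to display (default `"OZ"`).
#' @param fmax Upper frequency limit of the plot (Hz).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eeg_psd <- function(object, channels = "OZ", fmax = 45, ...) {
  dat <- psd_condition_means(object, channels)
  dat <- filter(dat, .data$freq > 0, .data$freq <= fmax)
  ggplot2::ggplot(dat, ggplot2::aes(.data$freq, .data$power,
                                    colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "frequency (Hz)",
                  y = expression(PSD ~ (mu * V^2 / Hz)),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Topographic map of channel t values and clusters
#'
#' Draws the montage on the unit head circle, colours channels by their t
#' statistic (eyes-closed minus eyes-open), and rings the members of
#' clusters at or below `p_max`.
#'
#' @param object An `eeg_clusters` object.
#' @param montage Montage tibble with positions.
#' @param p_max Highlight clusters with `p_value <= p_max`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eeg_clusters <- function(object, montage = default_montage(),
                                  p_max = 0.05, ...) {
  dat <- left_join(object$t_values, montage,
                   by = c(channel = "label"))
  sig <- unique(unlist(object$clusters$channels[
    object$clusters$p_value <= p_max]))
  dat$in_cluster <- dat$channel %in% sig
  circ <- tibble(theta = seq(0, 2 * pi, length.out = 200))
  ggplot2::ggplot(dat, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(data = tibble(x = 1.08 * cos(circ$theta),
                                     y = 1.08 * sin(circ$theta)),
                       ggplot2::aes(.data$x, .data$y), inherit.aes = FALSE) +
    ggplot2::geom_point(data = filter(dat, .data$in_cluster),
                        size = 9, shape = 21, colour = "black") +
    ggplot2::geom_point(ggplot2::aes(fill = .data$t), size = 7, shape = 21,
                        colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$channel), size = 2.2,
                       vjust = -1.8) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "t (closed - open)") +
    ggplot2::theme_void()
}

#' @rdname autoplot.eeg_clusters
#' @export
plot_topography <- function(object, montage = default_montage(),
                            p_max = 0.05, ...) {
  autoplot.eeg_clusters(object, montage = montage, p_max = p_max, ...)
}
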