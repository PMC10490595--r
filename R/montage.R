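#' The 24-channel recording montage
#'
#' The device records from 24 scalp electrodes of the international 10-20
#' system, in a fixed acquisition order (three 8-channel ADC banks). Positions
#' are the standard 2-D projection onto the unit head circle (nose along +y),
#' with the mastoids (M1/M2) placed just behind and below the ear positions.
#'
#' @return A tibble with columns `label`, `x`, `y` (unit head circle,
#'   radius <= 1), one row per channel, in acquisition order.
#' @examples
#' default_montage()
#' @export
default_montage <- function() {
  # outer 10% ring at radius 1, angles measured from the nose (+y)
  ring <- function(deg) c(sin(deg * pi / 180), cos(deg * pi / 180))
  m <- rbind(
    ring(-18),          # FP1
    ring(0),            # FPZ
    ring(18),           # FP2
    ring(-54),          # F7
    c(-0.400,  0.510),  # F3
    c( 0.000,  0.500),  # FZ
    c( 0.400,  0.510),  # F4
    ring(54),           # F8
    c(-0.920, -0.390),  # M1
    ring(-90),          # T7
    c(-0.500,  0.000),  # C3
    c( 0.000,  0.000),  # CZ
    c( 0.500,  0.000),  # C4
    ring(90),           # T8
    c( 0.920, -0.390),  # M2
    ring(-126),         # P7
    c(-0.400, -0.510),  # P3
    c( 0.000, -0.500),  # PZ
    c( 0.400, -0.510),  # P4
    ring(126),          # P8
    c( 0.000, -0.720),  # POZ
    ring(-162),         # O1
    ring(180),          # OZ
    ring(162)           # O2
  )
  tibble(label = montage_labels(), x = m[, 1], y = m[, 2])
}

#' @rdname default_montage
#' @export
montage_labels <- function() {
  c("FP1", "FPZ", "FP2", "F7", "F3", "FZ", "F4", "F8",
    "M1", "T7", "C3", "CZ", "C4", "T8", "M2",
    "P7", "P3", "PZ", "P4", "P8", "POZ", "O1", "OZ", "O2")
}

#' Channel neighbourhood graph for cluster formation
#'
#' Two channels are neighbours when their scalp distance is at most `scale`
#' times the median nearest-neighbour distance of the montage. The default
#' multiplier connects nearest 10-20 neighbours along rings and spokes
#' (including F7-T7 and P7-O1) while keeping anterior-posterior pairs such as
#' FP1-O2 unconnected; the resulting graph is a single connected component
#' with vertex degrees between 3 and 7.
#'
#' @param montage A montage tibble as returned by [default_montage()].
#' @param scale Multiplier on the median nearest-neighbour distance.
#' @return A symmetric logical matrix with empty diagonal, dimnames set to
#'   the channel labels.
#' @examples
#' adj <- montage_adjacency()
#' adj["O1", "OZ"]
#' @export
montage_adjacency <- function(montage = default_montage(), scale = 1.75) {
  stopifnot(is.data.frame(montage), all(c("label", "x", "y") %in% names(montage)))
  if (anyDuplicated(montage$label) > 0) abort("montage labels must be unique")
  d <- as.matrix(stats::dist(cbind(montage$x, montage$y)))
  dimnames(d) <- list(montage$label, montage$label)
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  adj <- d <= scale * median(nn)
  diag(adj) <- FALSE
  adj
}
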