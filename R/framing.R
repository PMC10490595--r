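#' Bit-exact telemetry message framing
#'
#' Three message kinds travel over the link. A data packet is a 1-byte
#' header (packet id in the high nibble, internally-dropped count saturated
#' at 15 in the low nibble) followed by 24 two's-complement channel values
#' of 10, 14 or 16 bits, MSB-first and bit-contiguous across byte
#' boundaries: 31, 43 or 49 bytes in total. A shift update is 14 bytes
#' (reference packet id, a reserved flags byte, then 24 4-bit shift codes
#' packed two per byte, even channel in the high nibble). A configuration /
#' battery readback message is 8 bytes.
#'
#' @param values 24 signed integers within the `bit_length` range.
#' @param bit_length 10, 14 or 16.
#' @param packet_id Integer in `[0, 15]`.
#' @param dropped Number of packets dropped since the last transmission;
#'   stored saturated at 15.
#' @return `pack_data_packet()`: a raw vector of 31/43/49 bytes.
#' @examples
#' length(pack_data_packet(integer(24), 10))
#' @export
pack_data_packet <- function(values, bit_length, packet_id = 0L, dropped = 0L) {
  n <- check_bit_length(bit_length)
  if (length(values) != 24) abort("a data packet carries exactly 24 values")
  if (any(values < -2^(n - 1) | values > 2^(n - 1) - 1))
    abort("value out of range for the configured bit length (encoder must clip)")
  if (packet_id < 0 || packet_id > 15) abort("packet_id must be in [0, 15]")
  header <- packet_id * 16L + min(as.integer(dropped), 15L)
  u <- ifelse(values < 0, values + 2^n, values)
  bits <- as.vector(vapply(u, function(x)
    (x %/% 2^((n - 1):0)) %% 2, numeric(n)))
  npad <- (-length(bits)) %% 8
  bits <- c(bits, rep(0, npad))
  bytes <- as.vector(2^(7:0) %*% matrix(bits, nrow = 8))
  as.raw(c(header, bytes))
}

#' @rdname pack_data_packet
#' @param bytes A raw vector of the exact serialized length.
#' @return `unpack_data_packet()`: a list with `packet_id`, `dropped`,
#'   `values`.
#' @export
unpack_data_packet <- function(bytes, bit_length) {
  n <- check_bit_length(bit_length)
  expected <- 1 + ceiling(24 * n / 8)
  if (length(bytes) != expected)
    abort(sprintf("malformed packet: expected %d bytes, got %d",
                  expected, length(bytes)))
  header <- as.integer(bytes[1])
  bits <- as.integer(rawToBits(bytes[-1]))
  bits <- as.vector(apply(matrix(bits, nrow = 8), 2, rev)) # MSB-first
  vals <- vapply(seq_len(24), function(j) {
    vb <- bits[((j - 1) * n + 1):(j * n)]
    u <- sum(vb * 2^((n - 1):0))
    if (u >= 2^(n - 1)) u - 2^n else u
  }, numeric(1))
  list(packet_id = header %/% 16L, dropped = header %% 16L,
       values = as.integer(vals))
}

check_bit_length <- function(bit_length) {
  if (!bit_length %in% c(10L, 14L, 16L))
    abort("bit_length must be 10, 14 or 16")
  as.integer(bit_length)
}

#' @rdname pack_data_packet
#' @param shifts 24 shift codes in `[0, 15]`.
#' @param ref_packet_id Id of the first data packet encoded with these
#'   shifts.
#' @param flags Reserved byte (0).
#' @return `pack_shift_update()`: a raw vector of 14 bytes.
#' @export
pack_shift_update <- function(shifts, ref_packet_id = 0L, flags = 0L) {
  if (length(shifts) != 24 || any(shifts < 0 | shifts > 15))
    abort("shifts must be 24 values in [0, 15]")
  hi <- shifts[seq(1, 23, by = 2)]
  lo <- shifts[seq(2, 24, by = 2)]
  as.raw(c(ref_packet_id, flags, hi * 16L + lo))
}

#' @rdname pack_data_packet
#' @return `parse_shift_update()`: a list with `ref_packet_id`, `flags`,
#'   `shifts`.
#' @export
parse_shift_update <- function(bytes) {
  if (length(bytes) != 14) abort("a shift update is exactly 14 bytes")
  b <- as.integer(bytes)
  shifts <- integer(24)
  shifts[seq(1, 23, by = 2)] <- b[3:14] %/% 16L
  shifts[seq(2, 24, by = 2)] <- b[3:14] %% 16L
  list(ref_packet_id = b[1], flags = b[2], shifts = shifts)
}

GAIN_CODES <- c(`1` = 0L, `2` = 1L, `4` = 2L, `8` = 3L)
RATE_CODES <- c(`250` = 0L, `167` = 1L)
BITLEN_CODES <- c(`10` = 0L, `14` = 1L, `16` = 2L)

#' @rdname pack_data_packet
#' @param gain Gain setting (1, 2, 4 or 8; code 0-3 on the wire).
#' @param rate Output rate (250 or 167; code 0/1).
#' @param battery_mV Battery voltage, unsigned 16-bit big-endian.
#' @param filter_mask Bitmask of enabled on-board filters.
#' @return `pack_config()`: a raw vector of 8 bytes.
#' @export
pack_config <- function(gain = 8, rate = 250, bit_length = 10,
                        filter_mask = 0L, battery_mV = 3700L) {
  gc <- GAIN_CODES[as.character(gain)]
  rc <- RATE_CODES[as.character(rate)]
  bc <- BITLEN_CODES[as.character(bit_length)]
  if (anyNA(c(gc, rc, bc))) abort("unknown gain, rate or bit-length setting")
  if (battery_mV < 0 || battery_mV > 65535) abort("battery_mV out of range")
  as.raw(c(gc, rc, bc, filter_mask,
           battery_mV %/% 256L, battery_mV %% 256L, 0L, 0L))
}

#' @rdname pack_data_packet
#' @return `parse_config()`: a list with `gain`, `rate`, `bit_length`,
#'   `filter_mask`, `battery_mV`.
#' @export
parse_config <- function(bytes) {
  if (length(bytes) != 8) abort("a configuration message is exactly 8 bytes")
  b <- as.integer(bytes)
  dec <- function(codes, code, what) {
    i <- match(code, codes)
    if (is.na(i)) abort(paste("unknown", what, "code"))
    as.integer(names(codes)[i])
  }
  list(gain = dec(GAIN_CODES, b[1], "gain"),
       rate = dec(RATE_CODES, b[2], "rate"),
       bit_length = dec(BITLEN_CODES, b[3], "bit length"),
       filter_mask = b[4],
       battery_mV = b[5] * 256L + b[6])
}

#' Simulate transport loss over a packet stream
#'
#' Removes the flagged packets and rewrites each surviving packet's
#' `dropped` field to the number of packets lost since the previous
#' delivery, saturated at 15 (the 4-bit header field).
#'
#' @param packets Tibble with one row per produced packet, containing at
#'   least `packet_id`; a `dropped` column is (re)written.
#' @param drop Logical vector, `TRUE` for packets lost in transit.
#' @return `list(delivered, log)`: the surviving packets with corrected
#'   `dropped` fields, and a per-packet delivery log with the unsaturated
#'   loss counts.
#' @export
simulate_loss <- function(packets, drop) {
  stopifnot(is.data.frame(packets), length(drop) == nrow(packets))
  lost_run <- 0L
  keep_dropped <- integer(0)
  true_dropped <- integer(0)
  for (i in seq_len(nrow(packets))) {
    if (drop[i]) {
      lost_run <- lost_run + 1L
    } else {
      keep_dropped <- c(keep_dropped, min(lost_run, 15L))
      true_dropped <- c(true_dropped, lost_run)
      lost_run <- 0L
    }
  }
  delivered <- packets[!drop, , drop = FALSE]
  delivered$dropped <- keep_dropped
  log <- tibble(produced_index = seq_len(nrow(packets)),
                delivered = !drop)
  attr(log, "true_dropped") <- true_dropped
  list(delivered = delivered, log = log)
}

#' Split / rebuild an offline telemetry stream
#'
#' An offline stream is a flat raw vector of `[type tag][message]` records;
#' tags `0x60`/`0x61`/`0x62` are data packets at 10/14/16 bits, `0xDE` a
#' shift update, `0xC0` a configuration message.
#'
#' @param stream Raw vector.
#' @return A tibble with `tag` (integer), `kind`, and `bytes` (list of raw
#'   message bodies, tag excluded).
#' @export
stream_messages <- function(stream) {
  sizes <- c(`96` = 31L, `97` = 43L, `98` = 49L, `222` = 14L, `192` = 8L)
  kinds <- c(`96` = "data", `97` = "data", `98` = "data",
             `222` = "shift_update", `192` = "config")
  pos <- 1L
  tags <- integer(0)
  bodies <- list()
  while (pos <= length(stream)) {
    tag <- as.integer(stream[pos])
    sz <- sizes[as.character(tag)]
    if (is.na(sz)) abort(sprintf("unknown message tag 0x%02X", tag))
    if (pos + sz > length(stream)) abort("truncated stream")
    tags <- c(tags, tag)
    bodies[[length(bodies) + 1L]] <- stream[(pos + 1L):(pos + sz)]
    pos <- pos + 1L + sz
  }
  tibble(tag = tags, kind = unname(kinds[as.character(tags)]), bytes = bodies)
}

#' @rdname stream_messages
#' @param messages A tibble as returned by `stream_messages()`.
#' @export
stream_from_messages <- function(messages) {
  do.call(c, purrr::map2(messages$tag, messages$bytes,
                         function(tag, body) c(as.raw(tag), body)))
}
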