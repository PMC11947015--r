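#' Transports: byte links between host and device
#'
#' The host controller speaks 16-bit command words serialized as byte pairs
#' (low byte first). Two transports share those byte semantics:
#'
#' * `loopback_transport(device)` wires the controller to an in-process
#'   [stim_device()] emulator — deterministic, used by the test harness.
#'   An optional `fault` hook rewrites (or drops, by returning `NULL`) each
#'   word before the device sees it, for fault-injection testing.
#' * `serial_transport(path)` opens a binary connection to a serial device
#'   node (e.g. `/dev/ttyUSB0`). The line is assumed configured at
#'   1 Mbaud, 8 data bits, no parity, 1 stop bit; base R cannot set port
#'   parameters, so configure them externally (e.g. with `stty`) first.
#'
#' Both transports count bytes moved; the modeled line occupancy of an
#' upload at 1 Mbaud 8N1 (10 line bits per byte) is available via
#' [modeled_line_seconds()].
#'
#' @param device A [stim_device()] the loopback transport drives.
#' @param fault Optional function `word -> word or NULL` applied to each
#'   incoming word before the device interprets it.
#' @return A transport object (classes `loopback_transport` /
#'   `serial_transport`, both `stim_transport`).
#' @name transports
NULL

#' @rdname transports
#' @export
loopback_transport <- function(device, fault = NULL) {
  stopifnot(inherits(device, "stim_device"))
  tp <- new.env(parent = emptyenv())
  tp$device <- device
  tp$fault <- fault
  tp$rx <- integer(0)          # response words queued for the host
  tp$bytes_out <- 0
  tp$bytes_in <- 0
  class(tp) <- c("loopback_transport", "stim_transport")
  tp
}

#' @rdname transports
#' @param path Serial device node path.
#' @export
serial_transport <- function(path) {
  con <- file(path, open = "w+b", raw = TRUE)
  tp <- new.env(parent = emptyenv())
  tp$con <- con
  tp$bytes_out <- 0
  tp$bytes_in <- 0
  class(tp) <- c("serial_transport", "stim_transport")
  tp
}

#' Send command words over a transport
#'
#' @param tp A transport.
#' @param words Integer vector of 16-bit command words.
#' @return The transport, invisibly.
#' @export
transport_send <- function(tp, words) UseMethod("transport_send")

#' @export
transport_send.loopback_transport <- function(tp, words) {
  tp$bytes_out <- tp$bytes_out + 2 * length(words)
  if (!is.null(tp$fault)) {
    kept <- lapply(as.integer(words), tp$fault)
    words <- unlist(kept[!vapply(kept, is.null, logical(1))],
                    use.names = FALSE)
    if (is.null(words)) words <- integer(0)
  }
  for (w in words) {
    resp <- device_apply(tp$device, w)
    if (length(resp)) tp$rx <- c(tp$rx, resp)
  }
  tp$bytes_in <- tp$bytes_in + 0  # accounted on read for loopback
  invisible(tp)
}

#' @export
transport_send.serial_transport <- function(tp, words) {
  bytes <- words_to_bytes(words)
  writeBin(as.raw(bytes), tp$con)
  flush(tp$con)
  tp$bytes_out <- tp$bytes_out + length(bytes)
  invisible(tp)
}

#' Read response words from a transport
#'
#' Blocks (serial) or drains the queue (loopback) until `n` words arrive.
#'
#' @param tp A transport.
#' @param n Number of 16-bit words to read.
#' @return Integer vector of `n` words (fewer if the link ran dry).
#' @export
transport_read <- function(tp, n) UseMethod("transport_read")

#' @export
transport_read.loopback_transport <- function(tp, n) {
  n <- min(n, length(tp$rx))
  out <- tp$rx[seq_len(n)]
  tp$rx <- tp$rx[-seq_len(n)]
  tp$bytes_in <- tp$bytes_in + 2 * length(out)
  out
}

#' @export
transport_read.serial_transport <- function(tp, n) {
  bytes <- readBin(tp$con, "raw", n = 2L * n)
  tp$bytes_in <- tp$bytes_in + length(bytes)
  bytes_to_words(as.integer(bytes))
}

#' Close a transport
#' @param tp A transport.
#' @return Invisibly, `NULL`.
#' @export
transport_close <- function(tp) {
  if (inherits(tp, "serial_transport")) close(tp$con)
  invisible(NULL)
}

#' Modeled serial line occupancy
#'
#' Time a byte count occupies a 1 Mbaud 8N1 line: 10 line bits per byte
#' (start + 8 data + stop), so 100 kB/s.
#'
#' @param n_bytes Number of bytes.
#' @param baud Line rate, bits/s.
#' @return Seconds of line time.
#' @export
modeled_line_seconds <- function(n_bytes, baud = 1e6) n_bytes * 10 / baud
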