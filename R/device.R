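#' Create a fresh stimulator device emulator
#'
#' Emulates the playback finite-state machine of the stimulator firmware:
#' two 32768-sample memories (one per output channel), a stimulus size
#' register split in two 12-bit halves, a sampling-frequency index, loop and
#' running flags, a shared read (signal) pointer driving both channels and
#' one write pointer per channel. The emulator is sample-accurate: it models
#' one DAC transaction per sample per channel, not individual clock edges.
#'
#' State is held in an environment so the device mutates in place, like a
#' connection object; [device_apply()] feeds it command words and
#' [device_advance()] runs playback time forward.
#'
#' @return An object of class `stim_device`.
#' @seealso [device_apply()], [device_advance()], [loopback_transport()]
#' @export
stim_device <- function() {
  dev <- new.env(parent = emptyenv())
  dev$capacity <- 32768L            # 2 x 2^14 16-bit words per channel
  dev$mem0 <- integer(dev$capacity) # stored 12-bit payloads, zero-extended
  dev$mem1 <- integer(dev$capacity)
  dev$size <- 0L                    # SET_SIZE_HI * 4096 + SET_SIZE_LO
  dev$freq_index <- 0L
  dev$looped <- FALSE
  dev$running <- FALSE
  dev$cycle_count <- 0L             # free-running sample tick counter (12 bit)
  dev$rd_ptr <- 0L                  # shared signal pointer, 0..size
  dev$wr_ptr0 <- 0L
  dev$wr_ptr1 <- 0L
  dev$play_count <- 0L              # samples emitted since START at rd_ptr 0
  class(dev) <- "stim_device"
  dev
}

#' @export
print.stim_device <- function(x, ...) {
  cat("<stim_device>\n")
  cat(sprintf("  size: %d samples  freq index: %d (%s)\n", x$size,
              x$freq_index,
              tryCatch(paste0(sampling_rate(x$freq_index) / 1000, " kS/s"),
                       error = function(e) "invalid")))
  cat(sprintf("  running: %s  looped: %s\n", x$running, x$looped))
  cat(sprintf("  rd_ptr: %d  wr_ptr0: %d  wr_ptr1: %d\n",
              x$rd_ptr, x$wr_ptr0, x$wr_ptr1))
  invisible(x)
}

#' Sampling rate for a frequency index
#'
#' The device supports three sampling rates selected by the `SET_FREQ`
#' payload: index 0, 1, 2 give 30, 50 and 60 kSamples/s.
#'
#' @param freq_index Integer index, one of 0, 1, 2.
#' @return Samples per second.
#' @export
sampling_rate <- function(freq_index) {
  rates <- c(30000, 50000, 60000)
  freq_index <- as.integer(freq_index)
  if (length(freq_index) != 1L || is.na(freq_index) ||
      freq_index < 0L || freq_index > 2L)
    stop("unknown frequency index (must be 0, 1 or 2): ", freq_index,
         call. = FALSE)
  rates[freq_index + 1L]
}

read_context <- function(dev, sel) {
  # DBG_READ: 12-bit context slice; undefined selectors read as 0
  switch(as.character(sel),
    "0"  = dev$size %% 4096L,
    "1"  = (dev$size %/% 4096L) %% 4096L,
    "2"  = dev$freq_index %% 4096L,
    "3"  = dev$cycle_count %% 4096L,
    "4"  = as.integer(dev$running),
    "5"  = as.integer(dev$looped),
    "6"  = dev$rd_ptr %% 4096L,
    "7"  = (dev$rd_ptr %/% 4096L) %% 4096L,
    "8"  = dev$wr_ptr0 %% 4096L,
    "9"  = (dev$wr_ptr0 %/% 4096L) %% 4096L,
    "10" = dev$wr_ptr1 %% 4096L,
    "11" = (dev$wr_ptr1 %/% 4096L) %% 4096L,
    0L)
}

#' Apply one command word to the device
#'
#' Interprets a decoded 16-bit command word and performs the corresponding
#' state transition. Commands that produce a reply (`DBG_ECHO`, `DBG_READ`,
#' `DBG_DUMP0/1`) return the reply as a vector of 16-bit words; all others
#' return `integer(0)`.
#'
#' Semantics, by code: `ISDATA0/1` store the payload at the channel's write
#' pointer and increment it (storing past the 32768-sample capacity is an
#' error); `SET_SIZE_LO/HI` overwrite one 12-bit half of the stimulus size;
#' `SET_FREQ` stores the frequency index; `SET_LOOPED` stores the loop flag;
#' `START` sets running (a no-op when size is 0); `PAUSE` clears running and
#' preserves the read pointer so a later `START` resumes; `REWIND` zeroes
#' the read pointer; `WR_REWIND` zeroes both write pointers; `DBG_ECHO`
#' returns the received word unchanged; `DBG_READ` returns the context value
#' selected by the payload (selectors in [stim_read_selectors]; anything
#' else reads 0), zero-extended to 16 bits; `DBG_DUMP0/1` stop any ongoing
#' stimulation, return all `size` stored samples of that channel and rewind
#' the read pointer and that channel's write pointer; `UNDEFINED` and `NOP`
#' change nothing.
#'
#' @param dev A [stim_device()].
#' @param word 16-bit command word (integer 0..65535).
#' @return Integer vector of response words (possibly empty). The device is
#'   modified in place.
#' @export
device_apply <- function(dev, word) {
  word <- as.integer(word)
  code <- word %/% 4096L
  data <- word %% 4096L
  if (code == 0L) {                      # ISDATA0
    if (dev$wr_ptr0 >= dev$capacity)
      stop("channel 0 memory full: capacity ", dev$capacity, " samples",
           call. = FALSE)
    dev$wr_ptr0 <- dev$wr_ptr0 + 1L
    dev$mem0[dev$wr_ptr0] <- data
    return(integer(0))
  }
  if (code == 1L) {                      # ISDATA1
    if (dev$wr_ptr1 >= dev$capacity)
      stop("channel 1 memory full: capacity ", dev$capacity, " samples",
           call. = FALSE)
    dev$wr_ptr1 <- dev$wr_ptr1 + 1L
    dev$mem1[dev$wr_ptr1] <- data
    return(integer(0))
  }
  switch(as.character(code),
    "2" = dev$size <- (dev$size %/% 4096L) * 4096L + data,   # SET_SIZE_LO
    "3" = dev$size <- data * 4096L + dev$size %% 4096L,      # SET_SIZE_HI
    "4" = dev$freq_index <- data,                            # SET_FREQ
    "5" = dev$looped <- data != 0L,                          # SET_LOOPED
    "6" = {                                                  # START
      if (dev$size > 0L) {
        if (dev$rd_ptr == 0L) dev$play_count <- 0L
        dev$running <- TRUE
      }
    },
    "7" = dev$running <- FALSE,                              # PAUSE
    "8" = dev$rd_ptr <- 0L,                                  # REWIND
    "9" = { dev$wr_ptr0 <- 0L; dev$wr_ptr1 <- 0L },          # WR_REWIND
    "10" = NULL,                                             # UNDEFINED
    "11" = return(word),                                     # DBG_ECHO
    "12" = return(as.integer(read_context(dev, data))),      # DBG_READ
    "13" = return(device_dump(dev, 0L)),                     # DBG_DUMP0
    "14" = return(device_dump(dev, 1L)),                     # DBG_DUMP1
    "15" = NULL)                                             # NOP
  integer(0)
}

device_dump <- function(dev, channel) {
  dev$running <- FALSE
  n <- dev$size
  if (n > dev$capacity) {
    warning("stimulus size ", n, " exceeds capacity ", dev$capacity,
            "; dump clamped", call. = FALSE)
    n <- dev$capacity
  }
  out <- if (channel == 0L) dev$mem0[seq_len(n)] else dev$mem1[seq_len(n)]
  dev$rd_ptr <- 0L
  if (channel == 0L) dev$wr_ptr0 <- 0L else dev$wr_ptr1 <- 0L
  out
}

#' Apply a sequence of command words
#'
#' Convenience wrapper around [device_apply()] that concatenates all reply
#' words in order.
#'
#' @param dev A [stim_device()].
#' @param words Integer vector of 16-bit command words.
#' @return Integer vector of all response words.
#' @export
device_apply_many <- function(dev, words) {
  out <- vector("list", length(words))
  for (i in seq_along(words)) out[[i]] <- device_apply(dev, words[i])
  unlist(out, use.names = FALSE)
}

#' Advance playback by up to `n_samples` sample ticks
#'
#' If the device is running, emits one DAC transaction per channel per
#' sample tick, advancing the shared read pointer. When the pointer reaches
#' the stimulus size: looped playback wraps to sample 0 and continues,
#' one-shot playback stops (`running` clears, pointer rests at `size`).
#' Advancing a paused or idle device emits nothing. A stimulus size beyond
#' the 32768-sample capacity is clamped to capacity with a warning (the
#' host-side sanitizer rejects such stimuli before upload).
#'
#' Transaction timestamps count emitted samples since the `START` that began
#' the run at sample 0; the counter does not advance while paused, so a
#' pause/resume run concatenates to the same trace as an uninterrupted one.
#'
#' @param dev A [stim_device()].
#' @param n_samples Maximum number of sample ticks to advance.
#' @return A data frame of DAC transactions with columns `channel` (0/1),
#'   `sample_index` (position in the stimulus), `word` (the 16-bit SPI-like
#'   frame carrying the stored 12-bit payload) and `time` (seconds since
#'   START). Zero rows when nothing plays.
#' @export
device_advance <- function(dev, n_samples) {
  n_samples <- as.integer(n_samples)
  empty <- data.frame(channel = integer(0), sample_index = integer(0),
                      word = integer(0), time = numeric(0))
  if (!isTRUE(dev$running) || n_samples <= 0L) return(empty)
  eff_size <- dev$size
  if (eff_size > dev$capacity) {
    warning("stimulus size ", dev$size, " exceeds capacity ", dev$capacity,
            "; playback clamped at capacity", call. = FALSE)
    eff_size <- dev$capacity
  }
  if (eff_size <= 0L) return(empty)
  fs <- sampling_rate(dev$freq_index)

  if (dev$looped) {
    steps <- n_samples
    idx <- (dev$rd_ptr + seq_len(steps) - 1L) %% eff_size
    dev$rd_ptr <- (dev$rd_ptr + steps) %% eff_size
  } else {
    steps <- min(n_samples, eff_size - dev$rd_ptr)
    if (steps <= 0L) { # already at the end (clamped size case)
      dev$running <- FALSE
      return(empty)
    }
    idx <- dev$rd_ptr + seq_len(steps) - 1L
    dev$rd_ptr <- dev$rd_ptr + steps
    if (dev$rd_ptr >= eff_size) {
      dev$running <- FALSE
      dev$rd_ptr <- dev$size   # pointer rests at size after a complete run
    }
  }
  times <- (dev$play_count + seq_len(steps) - 1L) / fs
  dev$play_count <- dev$play_count + steps
  dev$cycle_count <- (dev$cycle_count + steps) %% 4096L

  data.frame(
    channel = rep(c(0L, 1L), each = steps),
    sample_index = rep(idx, 2L),
    word = c(dev$mem0[idx + 1L], dev$mem1[idx + 1L]),
    time = rep(times, 2L)
  )
}

#' Model an external trigger-in event
#'
#' The hardware exposes a trigger input that starts stimulus delivery; it is
#' modeled as equivalent to receiving a `START` command.
#'
#' @param dev A [stim_device()].
#' @return The device, invisibly.
#' @export
device_trigger_in <- function(dev) {
  device_apply(dev, stim_commands[["START"]] * 4096L)
  invisible(dev)
}

#' Trigger-out line state
#'
#' The virtual trigger-out line is asserted while the device is running; it
#' gates the analog multiplexer that connects the current source to the
#' electrodes (see [mux_gate()]).
#'
#' @param dev A [stim_device()].
#' @return Logical scalar.
#' @export
device_trigger_out <- function(dev) isTRUE(dev$running)
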