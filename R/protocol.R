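#' Command set of the stimulator protocol
#'
#' Named integer vector mapping command mnemonics to their 4-bit command
#' codes. A command word is 16 bits: the code in bits 15..12 and a 12-bit
#' payload in bits 11..0. Code `0xA` (`UNDEFINED`) is reserved and acts as a
#' no-op on the device; `0xF` (`NOP`) does nothing by design.
#'
#' @format Named integer vector of length 16.
#' @export
stim_commands <- c(
  ISDATA0     = 0x0L, # store one channel-0 sample at the write pointer
  ISDATA1     = 0x1L, # store one channel-1 sample at the write pointer
  SET_SIZE_LO = 0x2L, # 12 LSB of the stimulus length in samples
  SET_SIZE_HI = 0x3L, # 12 MSB of the stimulus length in samples
  SET_FREQ    = 0x4L, # sampling-frequency index (0/1/2 = 30/50/60 kS/s)
  SET_LOOPED  = 0x5L, # 0 = play once, 1 = loop continuously
  START       = 0x6L,
  PAUSE       = 0x7L,
  REWIND      = 0x8L, # read (signal) pointer to sample 0
  WR_REWIND   = 0x9L, # both write pointers to sample 0
  UNDEFINED   = 0xAL,
  DBG_ECHO    = 0xBL, # echo the full 16-bit word back to the host
  DBG_READ    = 0xCL, # read one context value selected by the payload
  DBG_DUMP0   = 0xDL, # dump all stored channel-0 samples
  DBG_DUMP1   = 0xEL,
  NOP         = 0xFL
)

#' Context selectors understood by `DBG_READ`
#'
#' The payload of a `DBG_READ` command selects which 12-bit slice of the
#' device context is sent back to the host.
#'
#' @format Named integer vector of length 12.
#' @export
stim_read_selectors <- c(
  SIZE_LO = 0x0L, SIZE_HI = 0x1L, FREQ = 0x2L, CYCLE_COUNT = 0x3L,
  RUNNING = 0x4L, LOOPED = 0x5L, RD_PTR_LO = 0x6L, RD_PTR_HI = 0x7L,
  WR_PTR0_LO = 0x8L, WR_PTR0_HI = 0x9L, WR_PTR1_LO = 0xAL, WR_PTR1_HI = 0xBL
)

resolve_code <- function(code) {
  if (is.character(code)) {
    if (!code %in% names(stim_commands))
      stop("unknown command mnemonic: ", code, call. = FALSE)
    code <- stim_commands[[code]]
  }
  code <- as.integer(code)
  if (any(is.na(code)) || any(code < 0L) || any(code > 0xFL))
    stop("command code out of range 0x0..0xF", call. = FALSE)
  code
}

#' Encode a command word into its two wire bytes
#'
#' Composes the 16-bit word `code * 2^12 + data` and splits it into the two
#' bytes sent over the UART link, least significant byte first.
#'
#' @param code Command code, 0--15, or a mnemonic from [stim_commands].
#' @param data Unsigned 12-bit payload, 0--4095. Vectorized with `code`.
#' @return Integer vector of bytes, low byte first (`c(low, high)` for a
#'   single command; interleaved low/high pairs for several).
#' @examples
#' encode_command("START", 0)            # c(0x00, 0x60)
#' encode_command("DBG_ECHO", 0xABC)     # c(0xBC, 0xBA)
#' @export
encode_command <- function(code, data = 0L) {
  code <- resolve_code(code)
  data <- as.integer(data)
  if (any(is.na(data)) || any(data < 0L) || any(data > 4095L))
    stop("payload out of 12-bit range 0..4095: ",
         paste(data[is.na(data) | data < 0L | data > 4095L], collapse = ", "),
         call. = FALSE)
  words_to_bytes(code * 4096L + data)
}

#' Decode a received byte pair into a command word
#'
#' Inverse of [encode_command()]: every 16-bit word decodes (code `0xA`
#' included; the device treats it as a no-op).
#'
#' @param low,high The two received bytes, low byte first as transmitted.
#' @return A list with elements `code`, `data` and the composed 16-bit
#'   `word`; each is vectorized over the inputs.
#' @examples
#' decode_bytes(0x00, 0x60)  # START, data 0
#' @export
decode_bytes <- function(low, high) {
  low <- as.integer(low); high <- as.integer(high)
  if (any(low < 0L | low > 255L) || any(high < 0L | high > 255L))
    stop("bytes must be in 0..255", call. = FALSE)
  word <- high * 256L + low
  list(code = word %/% 4096L, data = word %% 4096L, word = word)
}

#' Serialize 16-bit words to a byte stream (low byte first)
#'
#' @param words Integer vector of 16-bit words (0..65535).
#' @return Integer vector, twice the length, low/high interleaved.
#' @export
words_to_bytes <- function(words) {
  words <- as.integer(words)
  if (any(is.na(words)) || any(words < 0L) || any(words > 65535L))
    stop("words must be in 0..65535", call. = FALSE)
  out <- integer(2L * length(words))
  out[c(TRUE, FALSE)] <- words %% 256L
  out[c(FALSE, TRUE)] <- words %/% 256L
  out
}

#' Deserialize a byte stream into 16-bit words
#'
#' @param bytes Integer vector of even length, low byte of each word first.
#' @return Integer vector of words.
#' @export
bytes_to_words <- function(bytes) {
  bytes <- as.integer(bytes)
  if (length(bytes) %% 2L != 0L)
    stop("byte stream has odd length; words are two bytes each", call. = FALSE)
  if (any(bytes < 0L | bytes > 255L))
    stop("bytes must be in 0..255", call. = FALSE)
  bytes[c(FALSE, TRUE)] * 256L + bytes[c(TRUE, FALSE)]
}

#' Signed sample codec (12-bit two's complement)
#'
#' Stimulus samples are integers in \[-2048, 2047\] and travel in the 12-bit
#' payload field as two's complement. `decode_sample()` is the exact inverse
#' of `encode_sample()`.
#'
#' @param s Integer sample(s) in \[-2048, 2047\].
#' @param field Unsigned 12-bit field value(s) in \[0, 4095\].
#' @return `encode_sample`: unsigned field 0..4095; `decode_sample`: signed
#'   sample.
#' @examples
#' encode_sample(c(0, 2047, -2048))   # 0x000, 0x7FF, 0x800
#' decode_sample(0xFFF)               # -1
#' @export
encode_sample <- function(s) {
  s <- as.integer(s)
  bad <- is.na(s) | s < -2048L | s > 2047L
  if (any(bad))
    stop("sample out of range [-2048, 2047]: ",
         paste(s[bad], collapse = ", "), call. = FALSE)
  s %% 4096L
}

#' @rdname encode_sample
#' @export
decode_sample <- function(field) {
  field <- as.integer(field)
  if (any(is.na(field) | field < 0L | field > 4095L))
    stop("field out of 12-bit range 0..4095", call. = FALSE)
  ifelse(field >= 2048L, field - 4096L, field)
}
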