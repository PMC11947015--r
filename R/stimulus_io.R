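#' Read and write stimulus CSV files
#'
#' The stimulus file dialect is one integer per line, no header, each value
#' in \[-2048, 2047\] — the native range of the 12-bit DAC. `stim_write()`
#' and `stim_read()` are exact inverses for every valid buffer.
#'
#' @param buf A [stim_buffer()] or bare integer vector of samples.
#' @param path File path.
#' @param fs Optional sampling rate to attach to the buffer on read.
#' @return `stim_read()` returns a [stim_buffer()]; `stim_write()` returns
#'   `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' stim_write(stim_buffer(c(0L, 2047L, -2048L)), f)
#' stim_read(f)$samples
#' @export
stim_write <- function(buf, path) {
  s <- if (inherits(buf, "stim_buffer")) buf$samples else
    stim_buffer(buf)$samples
  writeLines(format(s, scientific = FALSE, trim = TRUE), path)
  invisible(path)
}

#' @rdname stim_write
#' @export
stim_read <- function(path, fs = NULL) {
  if (!file.exists(path)) stop("no such stimulus file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  # a single trailing blank line is tolerated; blanks elsewhere are not
  if (length(lines) && lines[length(lines)] == "")
    lines <- lines[-length(lines)]
  if (length(lines) == 0L)
    stop("empty stimulus file: ", path, call. = FALSE)
  ok <- grepl("^[+-]?[0-9]+$", lines)
  if (any(!ok)) {
    i <- which(!ok)[1]
    stop(sprintf("%s line %d: not an integer: '%s'", path, i, lines[i]),
         call. = FALSE)
  }
  vals <- suppressWarnings(as.integer(lines))
  bad <- is.na(vals) | vals < -2048L | vals > 2047L
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("%s line %d: value %s outside [-2048, 2047]",
                 path, i, lines[i]), call. = FALSE)
  }
  stim_buffer(vals, fs)
}
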