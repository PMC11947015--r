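#' Stimulation session configuration
#'
#' Bundles the two channel stimulus files and the user-facing options of a
#' stimulation run. The frequency is given in the user-facing unit (30, 50
#' or 60, in kSamples/s) and mapped to the device index 0/1/2. Defaults are
#' 60 and not looped.
#'
#' @param path0,path1 Paths of the channel-0 and channel-1 stimulus CSVs.
#' @param freq Sampling-rate choice: 30, 50 or 60.
#' @param looped Logical; play once (`FALSE`) or loop continuously.
#' @return An object of class `stim_session`.
#' @export
stim_session <- function(path0, path1, freq = 60, looped = FALSE) {
  idx <- match(freq, c(30, 50, 60)) - 1L
  if (is.na(idx))
    stop("freq must be one of 30, 50, 60 (kSamples/s)", call. = FALSE)
  structure(list(path0 = path0, path1 = path1, freq = freq,
                 freq_index = idx, looped = isTRUE(looped)),
            class = "stim_session")
}

#' Sanitize a pair of channel stimuli
#'
#' Host-side validation before anything touches the device: every sample in
#' \[-2048, 2047\], both channels the same length (the device has a single
#' shared read pointer), and the length within the 32768-sample capacity.
#'
#' @param stim0,stim1 Per-channel stimuli: [stim_buffer()]s or bare integer
#'   vectors.
#' @return A list with validated integer vectors `stim0`, `stim1` and
#'   `size`, invisibly usable downstream.
#' @export
sanitize <- function(stim0, stim1) {
  get_samples <- function(x, ch) {
    s <- if (inherits(x, "stim_buffer")) x$samples else as.integer(x)
    bad <- is.na(s) | s < -2048L | s > 2047L
    if (any(bad))
      stop(sprintf(
        "channel %d: sample %d at position %d outside [-2048, 2047]",
        ch, s[which(bad)[1]], which(bad)[1]), call. = FALSE)
    s
  }
  s0 <- get_samples(stim0, 0L)
  s1 <- get_samples(stim1, 1L)
  if (length(s0) != length(s1))
    stop(sprintf("stimulus length mismatch: channel 0 has %d samples, channel 1 has %d",
                 length(s0), length(s1)), call. = FALSE)
  if (length(s0) > 32768L)
    stop(sprintf("stimulus length %d exceeds the 32768-sample capacity",
                 length(s0)), call. = FALSE)
  if (length(s0) == 0L)
    stop("empty stimulus", call. = FALSE)
  list(stim0 = s0, stim1 = s1, size = length(s0))
}

new_report <- function() {
  structure(list(echo_ok = NA, readback_ok = NA, dump_ok = NA,
                 mismatches = data.frame(field = character(0),
                                         sent = integer(0),
                                         received = integer(0)),
                 upload_seconds = c(NA_real_, NA_real_)),
            class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  ok <- report_pass(x)
  cat(sprintf("<verification_report> %s (echo %s, readback %s, dump %s)\n",
              if (ok) "PASS" else "FAIL", x$echo_ok, x$readback_ok, x$dump_ok))
  if (nrow(x$mismatches)) {
    cat("  mismatches:\n")
    print(x$mismatches, row.names = FALSE)
  }
  invisible(x)
}

#' Overall pass/fail of a verification report
#' @param report A `verification_report`.
#' @return Logical: all gates true and no mismatches.
#' @export
report_pass <- function(report) {
  isTRUE(report$echo_ok) && isTRUE(report$readback_ok) &&
    isTRUE(report$dump_ok) && nrow(report$mismatches) == 0L
}

send_cmd <- function(tp, code, data = 0L) {
  word <- resolve_code(code) * 4096L + as.integer(data)
  if (any(data < 0L | data > 4095L))
    stop("payload out of 12-bit range", call. = FALSE)
  transport_send(tp, word)
}

#' Configure the device and verify by readback
#'
#' Implements the initialization half of the control flow: probe the link
#' with `DBG_ECHO`, rewind the read and write pointers, set the stimulus
#' size (both 12-bit halves), the frequency index and the loop flag, then
#' read `SIZE_LO`, `SIZE_HI`, `FREQ` and `LOOPED` back and compare each
#' against the value sent. Any echo or readback mismatch is recorded and
#' fails the report.
#'
#' @param tp A transport.
#' @param size Stimulus length in samples.
#' @param freq_index Device frequency index, 0/1/2.
#' @param looped Logical loop flag.
#' @return A partial `verification_report` (`dump_ok` still `NA`).
#' @export
configure <- function(tp, size, freq_index, looped) {
  report <- new_report()
  probe <- 0x5A5L
  send_cmd(tp, "DBG_ECHO", probe)
  echo <- transport_read(tp, 1L)
  expected_echo <- stim_commands[["DBG_ECHO"]] * 4096L + probe
  report$echo_ok <- length(echo) == 1L && echo == expected_echo
  if (!report$echo_ok) {
    report$mismatches <- rbind(report$mismatches, data.frame(
      field = "DBG_ECHO", sent = expected_echo,
      received = if (length(echo)) echo[1] else NA_integer_))
    return(report)
  }
  send_cmd(tp, "REWIND")
  send_cmd(tp, "WR_REWIND")
  size_lo <- size %% 4096L
  size_hi <- size %/% 4096L
  send_cmd(tp, "SET_SIZE_LO", size_lo)
  send_cmd(tp, "SET_SIZE_HI", size_hi)
  send_cmd(tp, "SET_FREQ", freq_index)
  send_cmd(tp, "SET_LOOPED", as.integer(looped))

  expected <- c(SIZE_LO = size_lo, SIZE_HI = size_hi,
                FREQ = as.integer(freq_index), LOOPED = as.integer(looped))
  report$readback_ok <- TRUE
  for (field in names(expected)) {
    send_cmd(tp, "DBG_READ", stim_read_selectors[[field]])
    got <- transport_read(tp, 1L)
    if (length(got) != 1L || got != expected[[field]]) {
      report$readback_ok <- FALSE
      report$mismatches <- rbind(report$mismatches, data.frame(
        field = field, sent = expected[[field]],
        received = if (length(got)) got[1] else NA_integer_))
    }
  }
  report
}

#' Upload both stimuli and verify by memory dump
#'
#' Sends every sample with one `ISDATA0`/`ISDATA1` command (12-bit two's
#' complement payload), then dumps each channel memory with
#' `DBG_DUMP0`/`DBG_DUMP1` and compares against what was sent. The modeled
#' serial line occupancy of each channel's upload is recorded; at 1 Mbaud
#' it stays below one second even for a full 32768-sample stimulus.
#'
#' @param tp A transport.
#' @param stim0,stim1 Validated integer sample vectors (see [sanitize()]).
#' @param report A report from [configure()] to extend, or `NULL`.
#' @return The completed `verification_report`.
#' @export
upload_and_verify <- function(tp, stim0, stim1, report = NULL) {
  if (is.null(report)) {
    report <- new_report()
    report$echo_ok <- TRUE
    report$readback_ok <- TRUE
  }
  size <- length(stim0)
  report$dump_ok <- TRUE
  for (ch in 0:1) {
    stim <- if (ch == 0L) stim0 else stim1
    cmd <- if (ch == 0L) "ISDATA0" else "ISDATA1"
    words <- resolve_code(cmd) * 4096L + encode_sample(stim)
    transport_send(tp, words)
    report$upload_seconds[ch + 1L] <- modeled_line_seconds(2 * length(words))
    send_cmd(tp, if (ch == 0L) "DBG_DUMP0" else "DBG_DUMP1")
    dump <- transport_read(tp, size)
    got <- if (length(dump)) decode_sample(dump) else integer(0)
    if (length(got) != size || any(got != stim)) {
      report$dump_ok <- FALSE
      bad <- if (length(got) != size) length(got) + 1L else
        which(got != stim)[1]
      report$mismatches <- rbind(report$mismatches, data.frame(
        field = sprintf("DUMP%d[%d]", ch, bad),
        sent = if (bad <= size) stim[bad] else NA_integer_,
        received = if (bad <= length(got)) got[bad] else NA_integer_))
    }
  }
  report
}

#' Run a complete stimulation session
#'
#' Full control flow against a device: parse and [sanitize()] the stimulus
#' files, [configure()] with echo probe and readback verification,
#' [upload_and_verify()] by memory dump, then — only after all three gates
#' pass — prompt for `START`, play, prompt for `PAUSE` (sent only if a
#' `RUNNING` readback returns 1), and exit. Prompts are injectable so the
#' flow runs unattended in tests and scripts; the default asks on the
#' console.
#'
#' Against a loopback transport the emulator is advanced in-process after
#' `START`: one-shot sessions play to completion, looped sessions play
#' `play_samples` ticks (default 2.5 stimulus lengths) before the pause
#' prompt.
#'
#' @param session A [stim_session()].
#' @param transport A transport; when `NULL` a fresh emulator behind a
#'   loopback transport is created.
#' @param confirm Function `stage_name -> logical` standing in for the
#'   "press any key" prompts (stages `"start"`, `"pause"`, `"exit"`).
#' @param play_samples Sample ticks to advance a loopback device after
#'   START; `NULL` picks a default from the session.
#' @return A list of class `stim_session_result` with `status` (0 on
#'   success, nonzero with the failing `stage` otherwise), `report`, and
#'   for loopback transports the playback `trace` of DAC transactions.
#' @export
run_session <- function(session, transport = NULL,
                        confirm = console_confirm, play_samples = NULL) {
  stopifnot(inherits(session, "stim_session"))
  fail <- function(stage, report = NULL, message = NULL)
    structure(list(status = 1L, stage = stage, report = report,
                   message = message, trace = NULL),
              class = "stim_session_result")
  if (is.null(transport)) transport <- loopback_transport(stim_device())
  loop <- inherits(transport, "loopback_transport")

  parsed <- tryCatch(
    list(b0 = stim_read(session$path0), b1 = stim_read(session$path1)),
    error = function(e) e)
  if (inherits(parsed, "error")) return(fail("parse", message = conditionMessage(parsed)))
  clean <- tryCatch(sanitize(parsed$b0, parsed$b1), error = function(e) e)
  if (inherits(clean, "error")) return(fail("sanitize", message = conditionMessage(clean)))

  report <- configure(transport, clean$size, session$freq_index,
                      session$looped)
  if (!isTRUE(report$echo_ok)) return(fail("echo", report))
  if (!isTRUE(report$readback_ok)) return(fail("readback", report))
  report <- upload_and_verify(transport, clean$stim0, clean$stim1, report)
  if (!isTRUE(report$dump_ok)) return(fail("upload", report))

  trace <- NULL
  if (isTRUE(confirm("start"))) {
    send_cmd(transport, "START")
    if (loop) {
      n <- if (!is.null(play_samples)) play_samples
           else if (session$looped) as.integer(ceiling(2.5 * clean$size))
           else clean$size
      trace <- device_advance(transport$device, n)
    }
  }
  if (isTRUE(confirm("pause"))) {
    send_cmd(transport, "DBG_READ", stim_read_selectors[["RUNNING"]])
    running <- transport_read(transport, 1L)
    if (length(running) == 1L && running == 1L)
      send_cmd(transport, "PAUSE")
  }
  confirm("exit")
  structure(list(status = 0L, stage = "done", report = report,
                 trace = trace),
            class = "stim_session_result")
}

#' @export
print.stim_session_result <- function(x, ...) {
  cat(sprintf("<stim_session_result> status %d (%s)\n", x$status, x$stage))
  if (!is.null(x$message)) cat("  ", x$message, "\n", sep = "")
  if (!is.null(x$report)) print(x$report)
  if (!is.null(x$trace))
    cat(sprintf("  trace: %d DAC transactions\n", nrow(x$trace)))
  invisible(x)
}

#' Console prompt used by [run_session()] by default
#' @param stage Stage name being confirmed.
#' @return `TRUE` after the user presses return.
#' @export
console_confirm <- function(stage) {
  readline(sprintf("Press <return> to %s: ", stage))
  TRUE
}
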