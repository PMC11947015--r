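# Build a 16-bit command word from a mnemonic and payload.
cmd_word <- function(code, data = 0L) {
  stim_commands[[code]] * 4096L + as.integer(data)
}

# Least-squares amplitude and phase of a sinusoid at frequency f in (t, y).
fit_sinusoid <- function(t, y, f) {
  s <- sin(2 * pi * f * t)
  co <- cos(2 * pi * f * t)
  fit <- stats::lm.fit(cbind(s, co, 1), y)
  b <- unname(fit$coefficients)
  list(amplitude = sqrt(b[1]^2 + b[2]^2), phase = atan2(b[2], b[1]))
}

# Canonical ordering of a DAC transaction trace: by channel, then time.
# Playback equivalence is per channel; advance() batches group channels
# within each call, so concatenated partial runs interleave differently.
per_channel <- function(trace) {
  tr <- trace[order(trace$channel, trace$time), ]
  rownames(tr) <- NULL
  tr
}

# Upload a stimulus straight onto an emulator (no transport), set size.
load_device <- function(dev, stim0, stim1 = NULL, freq_index = 2L,
                        looped = FALSE) {
  size <- length(stim0)
  device_apply_many(dev, c(
    cmd_word("SET_SIZE_LO", size %% 4096L),
    cmd_word("SET_SIZE_HI", size %/% 4096L),
    cmd_word("SET_FREQ", freq_index),
    cmd_word("SET_LOOPED", as.integer(looped))))
  device_apply_many(dev, cmd_word("ISDATA0", 0L) + encode_sample(stim0))
  if (!is.null(stim1))
    device_apply_many(dev, cmd_word("ISDATA1", 0L) + encode_sample(stim1))
  invisible(dev)
}

# Channel-0 payload sequence from an advance() trace.
ch_words <- function(trace, channel = 0L) {
  trace$word[trace$channel == channel]
}

write_stim_files <- function(s0, s1, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  p0 <- file.path(dir, "ch0.csv"); p1 <- file.path(dir, "ch1.csv")
  stim_write(s0, p0); stim_write(s1, p1)
  c(p0, p1)
}
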