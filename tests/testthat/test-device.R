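# The first twelve tests mirror the firmware's simulation test list: each
# exercises the same command combination against the emulator.

test_that("channel-0 upload advances the write pointer and stores samples", {
  dev <- stim_device()
  stim <- c(-5L, 0L, 7L, 2047L, -2048L)
  device_apply_many(dev, c(cmd_word("SET_SIZE_LO", length(stim)),
                           cmd_word("SET_SIZE_HI", 0L)))
  for (k in seq_along(stim)) {
    device_apply(dev, cmd_word("ISDATA0", encode_sample(stim[k])))
    expect_equal(device_apply(dev, cmd_word("DBG_READ",
                                            stim_read_selectors[["WR_PTR0_LO"]])), k)
  }
  dump <- device_apply(dev, cmd_word("DBG_DUMP0"))
  expect_identical(decode_sample(dump), stim)
})

test_that("channel-1 upload advances the write pointer and stores samples", {
  dev <- stim_device()
  stim <- c(100L, -100L, 42L)
  device_apply_many(dev, c(cmd_word("SET_SIZE_LO", length(stim)),
                           cmd_word("SET_SIZE_HI", 0L)))
  device_apply_many(dev, cmd_word("ISDATA1", 0L) + encode_sample(stim))
  expect_equal(device_apply(dev, cmd_word("DBG_READ",
                                          stim_read_selectors[["WR_PTR1_LO"]])), 3L)
  dump <- device_apply(dev, cmd_word("DBG_DUMP1"))
  expect_identical(decode_sample(dump), stim)
})

test_that("the low half of the stimulus size reads back as written", {
  dev <- stim_device()
  device_apply(dev, cmd_word("SET_SIZE_LO", 5L))
  expect_equal(device_apply(dev, cmd_word("DBG_READ", 0x0)), 5L)
})

test_that("the high half of the stimulus size reads back as written", {
  dev <- stim_device()
  device_apply(dev, cmd_word("SET_SIZE_HI", 3L))
  expect_equal(device_apply(dev, cmd_word("DBG_READ", 0x1)), 3L)
  expect_equal(dev$size, 3L * 4096L)
  # the halves compose without clobbering each other
  device_apply(dev, cmd_word("SET_SIZE_LO", 7L))
  expect_equal(dev$size, 3L * 4096L + 7L)
})

test_that("the frequency index reads back as written", {
  dev <- stim_device()
  device_apply(dev, cmd_word("SET_FREQ", 2L))
  expect_equal(device_apply(dev, cmd_word("DBG_READ", 0x2)), 2L)
})

test_that("the loop flag reads back as written", {
  dev <- stim_device()
  device_apply(dev, cmd_word("SET_LOOPED", 1L))
  expect_equal(device_apply(dev, cmd_word("DBG_READ", 0x5)), 1L)
  device_apply(dev, cmd_word("SET_LOOPED", 0L))
  expect_equal(device_apply(dev, cmd_word("DBG_READ", 0x5)), 0L)
})

test_that("one-shot playback reproduces both stored stimuli exactly once", {
  dev <- stim_device()
  s0 <- c(10L, -20L, 30L, -40L)
  s1 <- c(-1L, 2L, -3L, 4L)
  load_device(dev, s0, s1)
  device_apply(dev, cmd_word("START"))
  tr <- device_advance(dev, 10L)
  expect_identical(decode_sample(ch_words(tr, 0L)), s0)
  expect_identical(decode_sample(ch_words(tr, 1L)), s1)
  expect_equal(nrow(tr), 2L * length(s0))  # conservation, per channel
  expect_false(dev$running)
  # no further output after completion
  expect_equal(nrow(device_advance(dev, 5L)), 0L)
})

test_that("looped playback repeats the stimulus continuously", {
  dev <- stim_device()
  s0 <- c(1L, 2L, 3L, 4L)
  load_device(dev, s0, looped = TRUE)
  device_apply(dev, cmd_word("START"))
  tr <- device_advance(dev, 10L)
  expect_equal(ch_words(tr, 0L)[1:10], rep(s0, 3)[1:10])
  expect_equal(tr$sample_index[tr$channel == 0L],
               c(0L, 1L, 2L, 3L, 0L, 1L, 2L, 3L, 0L, 1L))
  expect_true(dev$running)
})

test_that("pause preserves the read pointer and resume completes the run", {
  set.seed(7)
  s0 <- decode_sample(sample.int(4096L, 6L) - 1L)
  # reference: uninterrupted run
  ref_dev <- stim_device(); load_device(ref_dev, s0)
  device_apply(ref_dev, cmd_word("START"))
  ref <- device_advance(ref_dev, 6L)
  # paused run
  dev <- stim_device(); load_device(dev, s0)
  device_apply(dev, cmd_word("START"))
  part1 <- device_advance(dev, 2L)
  device_apply(dev, cmd_word("PAUSE"))
  expect_false(dev$running)
  expect_equal(device_apply(dev, cmd_word("DBG_READ", 0x6)), 2L)
  expect_equal(nrow(device_advance(dev, 10L)), 0L)  # paused: silent
  device_apply(dev, cmd_word("START"))
  part2 <- device_advance(dev, 10L)
  expect_equal(per_channel(rbind(part1, part2)), per_channel(ref))
})

test_that("rewinding the read pointer lets a finished run replay identically", {
  dev <- stim_device()
  s0 <- c(5L, 6L, 7L)
  load_device(dev, s0)
  device_apply(dev, cmd_word("START"))
  first <- device_advance(dev, 3L)
  expect_equal(device_apply(dev, cmd_word("DBG_READ", 0x6)), 3L)
  device_apply(dev, cmd_word("PAUSE"))
  device_apply(dev, cmd_word("REWIND"))
  expect_equal(device_apply(dev, cmd_word("DBG_READ", 0x6)), 0L)
  device_apply(dev, cmd_word("START"))
  again <- device_advance(dev, 3L)
  expect_equal(again, first)
})

test_that("rewinding the write pointers enables bit-identical rewrite", {
  dev <- stim_device()
  s_old <- c(1L, 2L, 3L)
  load_device(dev, s_old)
  expect_equal(device_apply(dev, cmd_word("DBG_READ", 0x8)), 3L)
  device_apply(dev, cmd_word("WR_REWIND"))
  expect_equal(device_apply(dev, cmd_word("DBG_READ", 0x8)), 0L)
  s_new <- c(-7L, 8L, -9L)
  device_apply_many(dev, cmd_word("ISDATA0", 0L) + encode_sample(s_new))
  dump <- device_apply(dev, cmd_word("DBG_DUMP0"))
  expect_identical(decode_sample(dump), s_new)
})

test_that("the echo command returns the received word unchanged", {
  dev <- stim_device()
  for (payload in c(0x000L, 0xABCL, 0xFFFL)) {
    word <- cmd_word("DBG_ECHO", payload)
    expect_equal(device_apply(dev, word), word)
  }
})

# --- emulator behavior beyond the firmware test list ---

test_that("sampling rates map indices 0/1/2 to 30/50/60 kS/s", {
  expect_equal(sampling_rate(0), 30000)
  expect_equal(sampling_rate(1), 50000)
  expect_equal(sampling_rate(2), 60000)
  expect_error(sampling_rate(3), "frequency index")
})

test_that("undefined context selectors and commands are benign", {
  dev <- stim_device()
  device_apply(dev, cmd_word("SET_SIZE_LO", 9L))
  for (sel in 0xC:0xF)
    expect_equal(device_apply(dev, cmd_word("DBG_READ", sel)), 0L)
  before <- mget(ls(dev), envir = dev)
  device_apply(dev, cmd_word("UNDEFINED", 0x123))
  device_apply(dev, cmd_word("NOP", 0xFFF))
  expect_equal(mget(ls(dev), envir = dev), before)
})

test_that("START with size 0 is a no-op and capacity overruns error", {
  dev <- stim_device()
  device_apply(dev, cmd_word("START"))
  expect_false(dev$running)
  dev$wr_ptr0 <- dev$capacity
  expect_error(device_apply(dev, cmd_word("ISDATA0", 1L)), "capacity")
})

test_that("memory round-trips for random stimuli up to capacity limits", {
  set.seed(42)
  dev <- stim_device()
  for (len in c(1L, 17L, 1000L)) {
    stim <- sample(-2048:2047, len, replace = TRUE)
    device_apply(dev, cmd_word("WR_REWIND"))
    device_apply_many(dev, c(cmd_word("SET_SIZE_LO", len %% 4096L),
                             cmd_word("SET_SIZE_HI", len %/% 4096L)))
    device_apply_many(dev, cmd_word("ISDATA0", 0L) + encode_sample(stim))
    dump <- device_apply(dev, cmd_word("DBG_DUMP0"))
    expect_identical(decode_sample(dump), stim)
  }
})

test_that("transaction timestamps are spaced by exactly one sampling period", {
  for (idx in 0:2) {
    dev <- stim_device()
    load_device(dev, rep(1L, 8L), freq_index = idx)
    device_apply(dev, cmd_word("START"))
    tr <- device_advance(dev, 8L)
    t0 <- tr$time[tr$channel == 0L]
    expect_equal(diff(t0), rep(1 / sampling_rate(idx), 7L))
  }
})

test_that("a stimulus size beyond capacity clamps playback with a warning", {
  dev <- stim_device()
  load_device(dev, c(1L, 2L))
  dev$size <- dev$capacity + 10L   # device accepts it; the host would not
  device_apply(dev, cmd_word("START"))
  expect_warning(tr <- device_advance(dev, 5L), "capacity")
  expect_equal(max(tr$sample_index), 4L)
})

test_that("an external trigger event starts playback like START", {
  dev <- stim_device()
  load_device(dev, c(1L, 2L, 3L))
  expect_false(device_trigger_out(dev))
  device_trigger_in(dev)
  expect_true(dev$running)
  expect_true(device_trigger_out(dev))
})
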