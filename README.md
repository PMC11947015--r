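# stimtwin

A software twin of a two-channel arbitrary-waveform neurostimulator, for
researchers who design stimuli for — or develop host software against —
FPGA-based current stimulators without needing the bench hardware in the
loop.

Preclinical work on retinal prostheses, kilohertz-frequency and
interference-based neuromodulation needs stimulators that deliver
*arbitrary* current waveforms, not just trains of biphasic
constant-current pulses. A practical architecture is: a host PC uploads a
sampled stimulus over a 1 Mbaud serial link; an FPGA stores up to 32 k
12-bit samples per channel and plays them into a DAC at 30/50/60 kS/s; an
analog chain reconstructs, recenters and isolates the voltage and converts
it to current through the electrodes. `stimtwin` implements that whole
stack in software:

* **Protocol codec** — 16-bit command words `code·2¹² + data` (4-bit code,
  12-bit payload), serialized low byte first; 12-bit two's-complement
  sample codec. Exhaustively round-trip tested.
* **Device emulator** — the playback state machine behind the 16-command
  set (`ISDATA0/1`, `SET_SIZE_LO/HI`, `SET_FREQ`, `SET_LOOPED`, `START`,
  `PAUSE`, `REWIND`, `WR_REWIND`, `DBG_ECHO`, `DBG_READ`, `DBG_DUMP0/1`,
  `NOP`), sample-accurate, with shared read pointer, per-channel write
  pointers and debug readback.
* **Analog chain model** — zero-order-hold DAC (`V = V_ref·c/4096`,
  V_ref = 3.3 V), first-order RC reconstruction filter
  (R = 2.2 kΩ, C = 2.2 nF, f_c = 1/(2πRC) ≈ 33 kHz), recentering map
  `V → 2V − V_ref` onto ±3.3 V, unity-gain isolation, modified-Howland
  transconductor `I = g_m·V_in` with g_m = 1/R₂ = 1 mA/V and hard
  compliance clipping at ±15 V, and trigger-controlled electrode
  shorting, into resistive or series-RC loads.
* **Waveform toolkit** — charge-balanced biphasic pulses, linear chirps,
  amplitude-modulated sinusoids, plain sinusoids; symmetric 12-bit
  quantization (`round(v·2047)`); net-charge balance checking; the
  one-integer-per-line stimulus CSV dialect.
* **Host controller** — the full verified session flow (sanitize →
  echo probe → configure → readback verify → upload → dump verify →
  START/PAUSE), with injectable prompts, a deterministic in-process
  loopback transport onto the emulator (plus a fault-injection hook), and
  a serial transport for real hardware.

See `vignettes/stimulator-twin.Rmd` for the model details and the design
decisions.

## Worked example

Generate an 80 ms chirp sweeping 100 Hz → 10 kHz, upload it through the
fully verified session flow, and drive a 10 kΩ electrode model:

```r
library(stimtwin)

w   <- gen_chirp(100, 10000, 0.08, 60000)
buf <- quantize(w)
buf
#> <stim_buffer> 4800 samples, range [-2047, 2047]

stim_write(buf, "ch0.csv"); stim_write(buf, "ch1.csv")
res <- run_session(stim_session("ch0.csv", "ch1.csv", freq = 60),
                   confirm = function(stage) TRUE)
res
#> <stim_session_result> status 0 (done)
#> <verification_report> PASS (echo TRUE, readback TRUE, dump TRUE)
#>   trace: 9600 DAC transactions
```

Status 0 with all three gates (echo, configuration readback, memory-dump
comparison) green; the 4800-sample stimulus produced exactly 4800 DAC
transactions on each of the two channels. Now the analog side:

```r
out <- simulate_chain(buf$samples, 60000, load = resistive_load(10000))
max(abs(out$voltage$value))
#> [1] 15
```

A full-scale chirp demands up to 3.3 V × 1 mA/V × 10 kΩ = 33 V from the
current source, so into this high-impedance load the output saturates at
the 15 V compliance limit — the regime small high-impedance electrodes
operate in. A chirp is also not charge balanced, which the net-charge
check flags, while a symmetric biphasic pulse balances exactly:

```r
check_charge_balance(buf)
#> <charge_report> FAIL: |net|/total = 0.0166 (tolerance 0.001)
bi <- quantize(gen_biphasic(1, 500e-6, 10e-6, 60000))
#> Warning message:
#> interphase gap of 1e-05 s is 0.600 samples at 60000 S/s; rounded to 1
check_charge_balance(bi)
#> <charge_report> PASS: |net|/total = 0 (tolerance 0.001)
```

A command-line front end with `stimulate`, `generate` and `simulate`
subcommands is installed at `inst/scripts/stimtwin.R`:

```sh
Rscript inst/scripts/stimtwin.R stimulate input0.csv input1.csv --freq 60 --looped
```

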