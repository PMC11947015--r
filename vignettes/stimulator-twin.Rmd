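---
title: "A software twin of a two-channel arbitrary-waveform neurostimulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A software twin of a two-channel arbitrary-waveform neurostimulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimtwin)
```

## What the package models

Preclinical neurostimulation experiments increasingly need *arbitrary*
current waveforms — chirps, amplitude-modulated carriers, interference
patterns — rather than the classical trains of biphasic constant-current
pulses. A practical instrument for this is an FPGA-backed two-channel
stimulator: the host uploads a sampled stimulus over a serial link, the
FPGA plays it into a DAC per channel, and an analog chain turns the DAC
voltage into an isolated, compliance-limited current through the
electrodes.

`stimtwin` is a software twin of such an instrument, in four layers:

1. **Protocol codec** — bit-exact encoding of 16-bit command words (4-bit
   command code, 12-bit payload) and their byte serialization, low byte
   first.
2. **Device emulator** — the firmware's playback finite-state machine:
   per-channel 32768-sample memories, a stimulus-size register written in
   two 12-bit halves, a frequency index, loop/run flags, a shared read
   pointer and per-channel write pointers, plus the debug commands (echo,
   context readback, memory dump).
3. **Analog chain model** — zero-order-hold DAC, first-order RC
   reconstruction filter, recentering subtractor, unity-gain isolation, a
   modified-Howland voltage-to-current converter with compliance clipping,
   and trigger-controlled output shorting into a load model.
4. **Waveform toolkit and host controller** — stimulus generators,
   12-bit quantization, charge-balance checking, the one-integer-per-line
   stimulus CSV dialect, and the full verified upload/playback session
   flow.

The emulator is *sample-accurate*, not clock-edge-accurate: it models one
DAC transaction per sample per channel and does not simulate FPGA clock
cycles, SPI bit timing or UART line states. That is the right granularity
for verifying command semantics, playback order and stimulus content.

## The command protocol

A command word is `code * 2^12 + data`. The sixteen codes cover stimulus
upload (`ISDATA0/1`), configuration (`SET_SIZE_LO/HI`, `SET_FREQ`,
`SET_LOOPED`), playback control (`START`, `PAUSE`, `REWIND`,
`WR_REWIND`), and debugging (`DBG_ECHO`, `DBG_READ`, `DBG_DUMP0/1`),
with `UNDEFINED` (0xA) reserved and `NOP` (0xF) inert. Words travel as
two bytes, least significant first; the codec round-trips the full
16-bit space exactly (the test suite checks all 65536 words).

Three choices here were genuinely open and are package decisions, not
documented firmware facts:

* **Sample wire format.** Samples are integers in [−2048, 2047]; the
  12-bit payload encoding is not fixed by the interface description. We
  use two's complement on the wire and convert to an offset-binary DAC
  code (`sample + 2048`) at the DAC, so sample 0 lands on the DAC
  midpoint — consistent with the downstream subtractor recentering
  mid-scale to 0 V.
* **`DBG_READ` reply format.** The context value is returned in the 12
  LSBs with the four MSBs zero (unlike `DBG_ECHO`, which returns the
  whole word). Selectors above 0xB read as 0.
* **`DBG_DUMP` semantics.** The dump returns `size` words, each a stored
  12-bit payload zero-extended to 16 bits; "rewinding the vectors after
  finishing" is implemented as read pointer ← 0 and the dumped channel's
  write pointer ← 0.

Other degenerate-input rules: `START` with size 0 is a no-op; `ISDATA`
past the 32768-sample capacity is an error; a configured size larger than
capacity is accepted by the device (the host rejects it before upload)
and playback clamps at capacity with a warning. `CYCLE_COUNT`, which in
hardware implements the inter-sample spacing, is modeled as a
free-running 12-bit counter ticking once per emitted sample — the only
meaningful reading at sample granularity.

Pause/resume equivalence is a core FSM property: `PAUSE` preserves the
read pointer, so any interleaving of `PAUSE`/`START` that plays out
yields the same per-channel transaction sequence as an uninterrupted run.
Transaction timestamps therefore count emitted samples since the `START`
that began the run at sample 0 and do not advance while paused.

## The analog chain

Per channel, a 12-bit code `c` becomes a held voltage
`V = V_ref · c / 4096` (`V_ref` = 3.3 V), smoothed by a first-order RC
low-pass (R = 2.2 kΩ, C = 2.2 nF, cutoff `1/(2πRC)` ≈ 33 kHz — half the
top 60 kS/s sampling rate, per Nyquist), recentered by the affine map
`V → 2V − V_ref` onto ±3.3 V, isolated (modeled as unity gain, zero
delay), and converted to current by a modified Howland stage modeled as
an ideal transconductor `I = g_m · V_in` with `g_m = 1/R2 = 1 mA/V`,
hard-clipped when the load voltage would exceed the ±15 V compliance.
A trigger-driven multiplexer shorts both the source and the electrode
when deasserted, so delivered current is exactly zero outside the
stimulus window.

Numerical choices:

* **Oversampling.** Traces live on a grid of `oversample` points per
  sampling period (default 32, i.e. 1.92 MHz at 60 kS/s): dense enough
  that the discrete filter's −3 dB magnitude sits within ~0.1 % of the
  analytic value.
* **Filter discretization.** The RC stage uses the exact zero-order-hold
  discretization `y[n] = a·y[n−1] + (1−a)·x[n]`, `a = exp(−Δt/τ)`, which
  is exact for the piecewise-constant DAC output and has exactly unit DC
  gain. The closed-form `1/(1 + j2πfRC)` is kept as an independent oracle;
  the discrete response trails it in phase by about half a grid sample.
  The filter state is initialized at the first input value, so a constant
  input produces no startup transient.
* **The recenter gain.** The subtractor's schematic gain is not pinned
  down by the interface description; the map `2V − V_ref` is chosen as
  the unique affine map sending [0, V_ref] onto the stated symmetric
  ±V_ref range.
* **Clipping.** Where the ideal load voltage exceeds ±15 V, the delivered
  voltage saturates and the current scales by `V_s/|V_ideal|` at that
  instant — for a resistive load exactly `±V_s/R`. Clipping is pointwise,
  idempotent, and never engages while peak `|I·Z|` ≤ V_s. Whether a real
  stage clips at exactly the supply or slightly inside it is
  hardware-specific; exact ±15 V is used.
* **Loads.** Resistive and series-RC only; the series capacitor is
  integrated by forward Euler on the dense grid. Constant-phase-element
  electrode models are out of scope.

What the model deliberately does *not* reproduce: the bench-measured
transconductance roll-off to ~0.75 mA/V at 30 kHz (an op-amp/layout
artifact of the physical build — the ideal model is flat across the
design band, which the test suite asserts), op-amp slewing and output
impedance, the 3 pF compensation capacitor's dynamics (retained in the
parameter block for documentation), DC-DC converter ripple, and
isolation-amplifier distortion. Conclusions drawn from the twin about
these hardware effects would be vacuous, and no test pretends otherwise.

## Waveforms and quantization

The generators cover the stimuli such an instrument is demonstrated
with: charge-balanced biphasic pulses (cathodic-first; sub-sample
durations round to whole samples with a warning, and a phase under two
samples is rejected as unreconstructable), linear chirps (zero initial
phase), amplitude-modulated sinusoids (rectified-triangle envelope
starting at its trough), and plain sinusoids specified by peak-to-peak
fraction of full scale.

Quantization is symmetric: `s = round(v · 2047)`, so +1 → 2047 and
−1 → −2047 and a negated waveform quantizes to the negated buffer —
which keeps sign-symmetric stimuli *exactly* charge balanced after
quantization. The code −2048 is never produced but remains legal in
stimulus files. Rounding (not truncation) is the documented choice.

One quirk worth knowing: for the demonstration AM stimulus (2 kHz
carrier, 100 Hz envelope, peak 0.5 + offset 0.5) the envelope attains
1.0 at its peaks, but each envelope peak falls 10 carrier cycles after
t = 0 — exactly on a zero of the zero-phase sine carrier — so the
attained maximum of the product is ≈ 0.9875, not 1.0.

The charge-balance check compares `|Σs|/fs` against a tolerance fraction
of the total absolute charge `Σ|s|/fs`, optionally converted to coulombs
via the volts-per-LSB at the converter input (`V_ref/2048`) and `g_m`.
It is a net-charge check only; electrochemical safety windows per
electrode material are out of scope.

## Host controller

`run_session()` reproduces the control script flow: parse and sanitize
both channel CSVs (every sample in range, equal lengths — the device has
a single shared read pointer — and length within capacity), probe the
link with `DBG_ECHO`, rewind both pointer sets, configure size,
frequency and looping, read all four settings back and compare, upload
with one `ISDATA` command per sample, verify by full memory dump, and
only after all three gates (echo, readback, dump) pass, prompt for
`START`. `PAUSE` is sent only if a `RUNNING` readback returns 1.
Prompts are injectable callbacks so sessions run unattended in tests
and scripts. Defaults are 60 kS/s, not looped.

The transport abstraction has two implementations with identical byte
semantics: an in-process loopback onto the emulator (deterministic; it
also accepts a fault-injection hook used to test that dropped or
corrupted commands are caught by the verification gates) and a serial
connection for real hardware. Byte accounting models the 1 Mbaud 8N1
link at 10 line bits per byte (100 kB/s), under which even a
full-capacity 32768-sample stimulus uploads in 0.66 s of line time.

## What the tests do and do not show

The protocol and FSM tests mirror the firmware's own simulation test
list one-for-one (upload round-trips, readbacks, one-shot and looped
playback, pause/resume equivalence, rewinds, echo) and add exhaustive
codec round-trips and property-style checks over seeded random stimuli.
The analog tests check the model against closed-form oracles (DC gain,
−3 dB point, Ohm's-law clipping thresholds, linearity/superposition).
All inputs are generated by the waveform toolkit; there are no recorded
hardware traces in the loop. Passing tests therefore demonstrate
fidelity to the *specified* behavior and to first-order circuit theory —
not to any particular physical unit, whose measured frequency response,
offsets and noise the model idealizes away by design.

Problem sizes used in the checks (a few thousand samples per simulated
trace, 20 ms of 60 kS/s playback, 32× oversampling) were chosen as the
smallest at which steady-state measurements are clean; all quantities
they estimate are scale-free.
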