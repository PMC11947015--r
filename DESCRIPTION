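Package: stimtwin
Title: Software Twin of a Two-Channel Arbitrary-Waveform Neurostimulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bit-exact emulation of the command protocol and playback state
    machine of an FPGA-based two-channel arbitrary current neurostimulator,
    together with a behavioral model of its analog drive chain (zero-order
    hold DAC, RC reconstruction filter, recentering subtractor, modified
    Howland voltage-to-current converter with compliance clipping, and
    trigger-controlled electrode shorting), a stimulus design toolkit
    (biphasic pulses, chirps, amplitude-modulated sinusoids, quantization,
    charge-balance checking, CSV stimulus I/O), and a host controller that
    drives the emulator or real hardware over a serial line with full
    configuration readback and upload verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
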