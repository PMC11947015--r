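#' Analytic design requirements of the stimulator
#'
#' First-principles computations behind the instrument's headline numbers.
#' Each helper takes the governing physical quantities as arguments with
#' the hardware values as defaults, so the figures are recomputed, not
#' stored.
#'
#' @name design_requirements
NULL

#' @describeIn design_requirements -3 dB cutoff of the first-order RC
#'   reconstruction filter, `1 / (2 pi R C)`; ~33 kHz with the built
#'   component values.
#' @param r Resistance, ohms.
#' @param c Capacitance, farads.
#' @export
rc_cutoff_hz <- function(r = 2200, c = 2.2e-9) 1 / (2 * pi * r * c)

#' @describeIn design_requirements minimum per-channel sample memory, in
#'   bytes, to hold a stimulus of `duration_s` seconds at `fs` with
#'   `bits`-bit samples.
#' @param duration_s Longest stimulus to store, seconds.
#' @param fs Sampling rate, samples/s.
#' @param bits Bits per sample.
#' @export
min_memory_bytes <- function(duration_s = 0.5, fs = 60000, bits = 12)
  duration_s * fs * bits / 8

#' @describeIn design_requirements minimum sampling rate to reconstruct a
#'   rectangular phase of `phase_s` seconds (two samples per phase).
#' @param phase_s Phase duration, seconds.
#' @export
min_sampling_rate_hz <- function(phase_s = 50e-6) 2 / phase_s

#' @describeIn design_requirements Nyquist bandwidth available at sampling
#'   rate `fs`.
#' @export
max_bandwidth_hz <- function(fs = 60000) fs / 2

#' @describeIn design_requirements host-link throughput in bytes/s of an
#'   8N1 UART at `baud` (10 line bits per byte).
#' @param baud Line rate, bits/s.
#' @export
uart_throughput_bytes_s <- function(baud = 1e6) baud / 10

#' @describeIn design_requirements per-channel sample capacity: two
#'   2^14-word single-port RAM blocks per channel.
#' @export
channel_capacity_samples <- function() 2L * 2L^14L

#' @describeIn design_requirements compliance voltage needed to drive
#'   current `i_amps` into impedance `z_ohms`.
#' @param i_amps Peak stimulation current, amps.
#' @param z_ohms Load impedance magnitude, ohms.
#' @export
compliance_voltage_v <- function(i_amps = 1e-3, z_ohms = 15000)
  i_amps * z_ohms

#' All design requirements at the built hardware's operating point
#'
#' @return Named list of the recomputed figures.
#' @export
design_requirements <- function() {
  list(
    rc_cutoff_hz = rc_cutoff_hz(),
    min_memory_bytes = min_memory_bytes(),
    min_sampling_rate_hz = min_sampling_rate_hz(),
    max_bandwidth_hz = max_bandwidth_hz(),
    uart_throughput_bytes_s = uart_throughput_bytes_s(),
    channel_capacity_samples = channel_capacity_samples(),
    compliance_voltage_v = compliance_voltage_v()
  )
}
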