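#' Analog chain parameters
#'
#' Component values of the analog drive chain: the DAC reference, the RC
#' reconstruction filter, the recentering subtractor, and the modified
#' Howland voltage-to-current converter with its compliance (supply)
#' voltage. Defaults are the built hardware's values.
#'
#' @param v_ref DAC full-scale voltage, volts.
#' @param r1_f Reconstruction-filter resistance, ohms.
#' @param c_f Reconstruction-filter capacitance, farads. With the default
#'   2.2 kOhm / 2.2 nF the -3 dB cutoff is ~33 kHz ([rc_cutoff_hz()]).
#' @param r2_f Subtractor resistance, ohms (documentation; the recenter
#'   stage is modeled as the exact affine map `2 V - v_ref`).
#' @param r1_h Howland resistance R1, ohms.
#' @param r2_h Howland resistance R2, ohms; sets the transconductance
#'   `g_m = 1 / r2_h` (1 mA/V by default).
#' @param c_h Howland compensation capacitance, farads (documentation only;
#'   the converter is modeled as an ideal transconductor in the design
#'   band).
#' @param v_s Compliance/supply voltage magnitude, volts. The delivered
#'   load voltage hard-clips at +/- `v_s`.
#' @return A list of class `chain_params`.
#' @export
chain_params <- function(v_ref = 3.3, r1_f = 2200, c_f = 2.2e-9,
                         r2_f = 1000, r1_h = 3e5, r2_h = 1000,
                         c_h = 3e-12, v_s = 15) {
  vals <- c(v_ref = v_ref, r1_f = r1_f, c_f = c_f, r2_f = r2_f,
            r1_h = r1_h, r2_h = r2_h, c_h = c_h, v_s = v_s)
  if (any(vals <= 0)) stop("all chain components must be positive",
                           call. = FALSE)
  if (v_s < 15) stop("compliance voltage must be at least 15 V", call. = FALSE)
  p <- as.list(vals)
  p$g_m <- 1 / r2_h
  class(p) <- "chain_params"
  p
}

#' Read chain parameters from a YAML config file
#'
#' The file holds any subset of the [chain_params()] arguments; missing
#' entries take the hardware defaults.
#'
#' @param path Path to a YAML file.
#' @return A `chain_params` object.
#' @export
read_chain_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(chain_params))
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown chain parameter(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  do.call(chain_params, cfg)
}

#' Load models for the electrode-tissue interface
#'
#' `resistive_load()` is a pure resistance; `series_rc_load()` is a
#' resistance in series with a capacitance, a first-order stand-in for the
#' electrode double layer.
#'
#' @param r_load Resistance, ohms.
#' @param c_load Capacitance, farads (series-RC only).
#' @return A list of class `stim_load`.
#' @export
resistive_load <- function(r_load) {
  if (r_load <= 0) stop("load resistance must be positive", call. = FALSE)
  structure(list(kind = "resistive", r_load = r_load), class = "stim_load")
}

#' @rdname resistive_load
#' @export
series_rc_load <- function(r_load, c_load) {
  if (r_load <= 0 || c_load <= 0)
    stop("load components must be positive", call. = FALSE)
  structure(list(kind = "series-RC", r_load = r_load, c_load = c_load),
            class = "stim_load")
}

new_trace <- function(time, value, rate) {
  structure(data.frame(time = time, value = value), rate = rate)
}

trace_rate <- function(trace) {
  r <- attr(trace, "rate")
  if (is.null(r)) {
    if (nrow(trace) < 2L) stop("cannot infer grid rate from a short trace",
                               call. = FALSE)
    r <- 1 / mean(diff(trace$time))
  }
  r
}

#' Zero-order-hold DAC output
#'
#' Each 12-bit code is held for one sampling period, producing the
#' staircase `V = v_ref * code / 4096` on a dense uniform grid.
#'
#' @param codes Unsigned DAC codes, 0..4095.
#' @param fs Sampling rate, samples/s.
#' @param oversample Grid points per sampling period (>= 8).
#' @param params A [chain_params()].
#' @return A voltage trace: data frame with `time` and `value`, grid rate
#'   `fs * oversample`.
#' @export
dac_output <- function(codes, fs, oversample = 32L, params = chain_params()) {
  codes <- as.integer(codes)
  if (any(is.na(codes) | codes < 0L | codes > 4095L))
    stop("DAC codes must be in 0..4095", call. = FALSE)
  oversample <- as.integer(oversample)
  if (oversample < 8L) stop("oversample must be at least 8", call. = FALSE)
  rate <- fs * oversample
  if (length(codes) == 0L) return(new_trace(numeric(0), numeric(0), rate))
  v <- params$v_ref * codes / 4096
  value <- rep(v, each = oversample)
  new_trace((seq_along(value) - 1) / rate, value, rate)
}

#' Analytic frequency response of the reconstruction filter
#'
#' Closed-form complex gain `1 / (1 + j 2 pi f R C)` of the first-order RC
#' stage; serves as the oracle for the time-domain filter.
#'
#' @param f Frequency, Hz (vectorized).
#' @param params A [chain_params()].
#' @return Complex gain.
#' @export
frequency_response <- function(f, params = chain_params()) {
  if (any(f < 0)) stop("frequency must be nonnegative", call. = FALSE)
  1 / (1 + 1i * 2 * pi * f * params$r1_f * params$c_f)
}

#' First-order RC reconstruction filter
#'
#' Applies the low-pass `tau = r1_f * c_f` stage by exact zero-order-hold
#' discretization on the trace grid: `y[n] = a y[n-1] + (1 - a) x[n]` with
#' `a = exp(-dt / tau)`, which is exact for piecewise-constant input and
#' keeps the -3 dB point tight against [frequency_response()] on a dense
#' grid. DC gain is exactly 1. The filter state starts at the first input
#' value.
#'
#' @param trace Voltage trace on a uniform grid.
#' @param params A [chain_params()].
#' @return Filtered voltage trace on the same grid.
#' @export
reconstruction_filter <- function(trace, params = chain_params()) {
  if (nrow(trace) == 0L) return(trace)
  dt <- 1 / trace_rate(trace)
  a <- exp(-dt / (params$r1_f * params$c_f))
  x <- trace$value
  y <- stats::filter((1 - a) * x, a, method = "recursive",
                     init = x[1])
  new_trace(trace$time, as.numeric(y), trace_rate(trace))
}

#' Recentering subtractor
#'
#' Affine map `V -> 2 V - v_ref` sending the unipolar DAC range
#' \[0, v_ref\] onto the symmetric range \[-v_ref, +v_ref\], so the DAC
#' midpoint (sample 0 in offset binary) lands at exactly 0 V.
#'
#' @param trace Voltage trace.
#' @param params A [chain_params()].
#' @return Recentered voltage trace.
#' @export
recenter <- function(trace, params = chain_params()) {
  new_trace(trace$time, 2 * trace$value - params$v_ref, trace_rate(trace))
}

load_ideal_voltage <- function(current, load, rate) {
  if (load$kind == "resistive") return(current * load$r_load)
  # series-RC: v = i R + v_C, capacitor integrated on the dense grid
  v_c <- cumsum(current) / (rate * load$c_load)
  current * load$r_load + v_c
}

#' Howland voltage-to-current converter with compliance clipping
#'
#' Behavioral model of the modified Howland stage: an ideal transconductor
#' `I = g_m V_in` (g_m = 1/r2_h, nominally 1 mA/V) driving the load, with
#' hard clipping when the ideal load voltage exceeds the compliance
#' magnitude `v_s`. At a clipped instant the delivered load voltage
#' saturates at +/- `v_s` and the current scales down proportionally (for a
#' resistive load this is exactly `sign(I) v_s / R`).
#'
#' @param v_in Input voltage trace (output of the isolation stage, modeled
#'   as unity gain).
#' @param load A [resistive_load()] or [series_rc_load()].
#' @param params A [chain_params()].
#' @return A list with `current` (delivered current trace, amps) and
#'   `voltage` (delivered load voltage trace, volts).
#' @export
howland_drive <- function(v_in, load, params = chain_params()) {
  rate <- trace_rate(v_in)
  i_ideal <- params$g_m * v_in$value
  v_ideal <- load_ideal_voltage(i_ideal, load, rate)
  scale <- rep(1, length(v_ideal))
  over <- abs(v_ideal) > params$v_s
  scale[over] <- params$v_s / abs(v_ideal[over])
  list(current = new_trace(v_in$time, i_ideal * scale, rate),
       voltage = new_trace(v_in$time, v_ideal * scale, rate))
}

#' Trigger-controlled output shorting
#'
#' While the trigger line is deasserted the analog multiplexer shorts both
#' the current source and the electrode, so the delivered current is
#' exactly zero there; where asserted the current passes unchanged.
#'
#' @param current Current trace.
#' @param trigger Logical vector aligned with the trace.
#' @return Gated current trace.
#' @export
mux_gate <- function(current, trigger) {
  if (length(trigger) != nrow(current))
    stop("trigger trace must align with the current trace", call. = FALSE)
  new_trace(current$time, current$value * as.numeric(trigger),
            trace_rate(current))
}

#' Simulate the full analog drive chain for one channel
#'
#' Composition of the whole drive path: signed samples are converted to
#' offset-binary DAC codes (`sample + 2048`), reconstructed by the
#' zero-order-hold DAC, low-pass filtered, recentered to the symmetric
#' range, passed through the (unity-gain) isolation stage, converted to
#' current by the Howland stage into the load, and finally gated by the
#' trigger-driven multiplexer.
#'
#' @param samples Signed samples in \[-2048, 2047\].
#' @param fs Sampling rate, samples/s.
#' @param load A load model; default 1 kOhm resistive.
#' @param params A [chain_params()].
#' @param oversample Grid points per sampling period.
#' @param trigger Logical vector, one entry per sample, marking where the
#'   trigger is asserted; default asserted for the whole stimulus.
#' @return A list with delivered `current` and load `voltage` traces.
#' @examples
#' sine <- gen_sine(1000, 2.2 / 3.3, 0.005, 60000)
#' out <- simulate_chain(quantize(sine)$samples, 60000)
#' max(out$current$value) * 1e3  # ~1.1 mA peak
#' @export
simulate_chain <- function(samples, fs, load = resistive_load(1000),
                           params = chain_params(), oversample = 32L,
                           trigger = NULL) {
  samples <- as.integer(samples)
  if (any(samples < -2048L | samples > 2047L))
    stop("samples must be in [-2048, 2047]", call. = FALSE)
  if (is.null(trigger)) trigger <- rep(TRUE, length(samples))
  if (length(trigger) != length(samples))
    stop("trigger must have one entry per sample", call. = FALSE)
  codes <- samples + 2048L
  v <- dac_output(codes, fs, oversample, params)
  v <- reconstruction_filter(v, params)
  v <- recenter(v, params)
  # isolation amplifier: unity gain, zero delay
  out <- howland_drive(v, load, params)
  gate <- rep(trigger, each = oversample)
  out$current <- mux_gate(out$current, gate)
  out$voltage <- new_trace(out$voltage$time,
                           out$voltage$value * as.numeric(gate),
                           trace_rate(out$voltage))
  out
}

#' Write a trace as two-column CSV
#'
#' @param trace A voltage or current trace.
#' @param path Output file path.
#' @param value_name Header for the value column.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, value_name = "value") {
  df <- data.frame(time = trace$time, value = trace$value)
  names(df)[2] <- value_name
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
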