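#' Continuous-valued stimulus waveform
#'
#' A waveform is a normalized amplitude sequence in \[-1, 1\] at a given
#' sampling rate; [quantize()] turns it into a 12-bit stimulus buffer ready
#' for upload. Device-bound waveforms use one of the supported rates
#' (30/50/60 kSamples/s), but the constructor accepts any positive rate so
#' waveforms can be designed off-device.
#'
#' @param values Numeric amplitudes, all within \[-1, 1\].
#' @param fs Sampling rate, samples/s.
#' @return An object of class `stim_waveform`.
#' @export
stim_waveform <- function(values, fs) {
  if (fs <= 0) stop("sampling rate must be positive", call. = FALSE)
  if (length(values) && max(abs(values)) > 1 + 1e-12)
    stop("waveform values must lie in [-1, 1]", call. = FALSE)
  structure(list(values = pmin(1, pmax(-1, values)), fs = fs),
            class = "stim_waveform")
}

#' @export
print.stim_waveform <- function(x, ...) {
  cat(sprintf("<stim_waveform> %d samples @ %g kS/s (%.3f ms), peak %.3f\n",
              length(x$values), x$fs / 1000, 1000 * length(x$values) / x$fs,
              if (length(x$values)) max(abs(x$values)) else 0))
  invisible(x)
}

#' Quantized 12-bit stimulus buffer
#'
#' @param samples Integer samples in \[-2048, 2047\], at most 32768 of them.
#' @param fs Sampling rate the buffer is intended for (optional, samples/s).
#' @return An object of class `stim_buffer`.
#' @export
stim_buffer <- function(samples, fs = NULL) {
  samples <- as.integer(samples)
  if (any(is.na(samples) | samples < -2048L | samples > 2047L))
    stop("stimulus samples must be integers in [-2048, 2047]", call. = FALSE)
  if (length(samples) > 32768L)
    stop("stimulus exceeds the 32768-sample channel capacity", call. = FALSE)
  structure(list(samples = samples, fs = fs), class = "stim_buffer")
}

#' @export
print.stim_buffer <- function(x, ...) {
  cat(sprintf("<stim_buffer> %d samples, range [%d, %d]\n",
              length(x$samples),
              if (length(x$samples)) min(x$samples) else NA_integer_,
              if (length(x$samples)) max(x$samples) else NA_integer_))
  invisible(x)
}

round_samples <- function(duration_s, fs, what) {
  n_exact <- duration_s * fs
  n <- as.integer(round(n_exact))
  if (abs(n - n_exact) > 1e-9)
    warning(sprintf("%s of %g s is %.3f samples at %g S/s; rounded to %d",
                    what, duration_s, n_exact, fs, n), call. = FALSE)
  n
}

#' Charge-balanced biphasic pulse
#'
#' Cathodic-first rectangular pulse: a negative phase, an interphase gap at
#' zero, then an anodic phase of equal magnitude and duration, so the net
#' sum of samples is exactly zero. Durations round to whole samples (with a
#' warning when they are not exact multiples of the sampling period); a
#' phase shorter than two samples cannot be reconstructed and is rejected.
#'
#' @param amplitude Normalized amplitude in (0, 1].
#' @param phase_s Duration of each phase, seconds.
#' @param interphase_s Gap between phases, seconds.
#' @param fs Sampling rate, samples/s.
#' @return A [stim_waveform()].
#' @examples
#' w <- gen_biphasic(1, 500e-6, 10e-6, 60000)
#' sum(w$values)  # 0
#' @export
gen_biphasic <- function(amplitude, phase_s, interphase_s = 0, fs) {
  if (amplitude <= 0 || amplitude > 1)
    stop("amplitude must be in (0, 1]", call. = FALSE)
  if (phase_s * fs < 2)
    stop(sprintf(
      "phase of %g s spans %.2f samples at %g S/s; at least 2 are needed",
      phase_s, phase_s * fs, fs), call. = FALSE)
  n_phase <- round_samples(phase_s, fs, "phase")
  n_gap <- max(0L, round_samples(interphase_s, fs, "interphase gap"))
  stim_waveform(c(rep(-amplitude, n_phase), rep(0, n_gap),
                  rep(amplitude, n_phase)), fs)
}

#' Linear chirp
#'
#' Unit-amplitude sweep whose instantaneous frequency moves linearly from
#' `f0` at t = 0 to `f1` at t = `duration_s`, starting at zero phase.
#'
#' @param f0,f1 Start and end frequency, Hz. `f1` must respect Nyquist.
#' @param duration_s Duration, seconds.
#' @param fs Sampling rate, samples/s.
#' @return A [stim_waveform()].
#' @export
gen_chirp <- function(f0, f1, duration_s, fs) {
  if (f1 > fs / 2)
    stop(sprintf("end frequency %g Hz exceeds Nyquist (%g Hz)", f1, fs / 2),
         call. = FALSE)
  n <- round_samples(duration_s, fs, "chirp")
  t <- (seq_len(n) - 1) / fs
  phase <- 2 * pi * (f0 * t + (f1 - f0) / (2 * duration_s) * t^2)
  stim_waveform(sin(phase), fs)
}

#' Amplitude-modulated sinusoid
#'
#' Sinusoidal carrier multiplied by a rectified-triangle envelope
#' `env_offset + env_peak * tri(t)`, where `tri` is a unit-peak triangle at
#' `env_hz` starting at its trough. With peak 0.5 and offset 0.5 the
#' envelope spans \[0.5, 1\].
#'
#' @param carrier_hz Carrier frequency, Hz (must respect Nyquist).
#' @param env_hz Envelope frequency, Hz.
#' @param env_peak Envelope modulation depth.
#' @param env_offset Envelope offset.
#' @param duration_s Duration, seconds.
#' @param fs Sampling rate, samples/s.
#' @return A [stim_waveform()].
#' @export
gen_am_sine <- function(carrier_hz, env_hz, env_peak, env_offset,
                        duration_s, fs) {
  if (carrier_hz > fs / 2)
    stop(sprintf("carrier %g Hz exceeds Nyquist (%g Hz)", carrier_hz, fs / 2),
         call. = FALSE)
  if (env_offset + env_peak > 1 + 1e-12)
    stop("envelope exceeds 1: offset + peak must not pass full scale",
         call. = FALSE)
  n <- round_samples(duration_s, fs, "waveform")
  t <- (seq_len(n) - 1) / fs
  frac <- (t * env_hz) %% 1
  tri <- 1 - abs(2 * frac - 1)        # trough at t = 0, unit peak
  env <- env_offset + env_peak * tri
  stim_waveform(env * sin(2 * pi * carrier_hz * t), fs)
}

#' Sinusoid
#'
#' @param f_hz Frequency, Hz. Exactly Nyquist is accepted with a warning.
#' @param vpp_fraction Peak-to-peak amplitude as a fraction of full scale;
#'   peak amplitude is `vpp_fraction / 2`.
#' @param duration_s Duration, seconds.
#' @param fs Sampling rate, samples/s.
#' @return A [stim_waveform()].
#' @export
gen_sine <- function(f_hz, vpp_fraction, duration_s, fs) {
  if (f_hz > fs / 2)
    stop(sprintf("frequency %g Hz exceeds Nyquist (%g Hz)", f_hz, fs / 2),
         call. = FALSE)
  if (f_hz == fs / 2)
    warning("frequency is exactly Nyquist; reconstruction is marginal",
            call. = FALSE)
  if (vpp_fraction < 0 || vpp_fraction > 2)
    stop("vpp_fraction must be in [0, 2]", call. = FALSE)
  n <- round_samples(duration_s, fs, "waveform")
  t <- (seq_len(n) - 1) / fs
  stim_waveform((vpp_fraction / 2) * sin(2 * pi * f_hz * t), fs)
}

#' Quantize a waveform to a 12-bit stimulus buffer
#'
#' Symmetric quantization `s = round(value * 2047)`, clamped to
#' \[-2048, 2047\]: full scale +1 maps to 2047 and -1 to -2047, so a
#' negated waveform quantizes to the negated buffer and sign-symmetric
#' stimuli stay exactly charge balanced. The code -2048 is never produced
#' (though it remains legal in stimulus files).
#'
#' @param w A [stim_waveform()].
#' @return A [stim_buffer()].
#' @export
quantize <- function(w) {
  stopifnot(inherits(w, "stim_waveform"))
  if (length(w$values) > 32768L)
    stop("waveform exceeds the 32768-sample channel capacity", call. = FALSE)
  s <- pmin(2047L, pmax(-2048L, as.integer(round(w$values * 2047))))
  stim_buffer(s, w$fs)
}

#' Reverse of quantization (for error analysis)
#'
#' @param buf A [stim_buffer()].
#' @return A [stim_waveform()] with values `samples / 2047`.
#' @export
dequantize <- function(buf) {
  stopifnot(inherits(buf, "stim_buffer"))
  stim_waveform(pmin(1, pmax(-1, buf$samples / 2047)),
                if (is.null(buf$fs)) 60000 else buf$fs)
}

#' Check the charge balance of a stimulus buffer
#'
#' Sums the samples as a proxy for delivered charge: `net = sum(s) / fs`
#' in sample-seconds, against `total = sum(|s|) / fs`. The check passes
#' when `|net| <= tolerance_fraction * total`. When chain parameters are
#' supplied the net charge is also converted to coulombs via the volts per
#' LSB at the converter input (`v_ref / 2048`) and the transconductance.
#'
#' @param buf A [stim_buffer()] (or bare integer vector).
#' @param tolerance_fraction Allowed `|net| / total` ratio.
#' @param fs Sampling rate, samples/s (taken from the buffer if present).
#' @param params Optional [chain_params()] for the coulomb conversion.
#' @return A list of class `charge_report` with `net`, `total`, `ratio`,
#'   `pass` and (when `params` is given) `net_coulombs`.
#' @export
check_charge_balance <- function(buf, tolerance_fraction = 1e-3, fs = NULL,
                                 params = NULL) {
  if (inherits(buf, "stim_buffer")) {
    if (is.null(fs)) fs <- buf$fs
    s <- buf$samples
  } else s <- as.integer(buf)
  if (length(s) == 0L) stop("empty stimulus buffer", call. = FALSE)
  if (is.null(fs)) fs <- 60000
  net <- sum(s) / fs
  total <- sum(abs(s)) / fs
  ratio <- if (total == 0) 0 else abs(net) / total
  rep <- list(net = net, total = total, ratio = ratio,
              pass = ratio <= tolerance_fraction,
              tolerance = tolerance_fraction)
  if (!is.null(params))
    rep$net_coulombs <- net * params$g_m * params$v_ref / 2048
  class(rep) <- "charge_report"
  rep
}

#' @export
print.charge_report <- function(x, ...) {
  cat(sprintf("<charge_report> %s: |net|/total = %.3g (tolerance %.3g)\n",
              if (x$pass) "PASS" else "FAIL", x$ratio, x$tolerance))
  if (!is.null(x$net_coulombs))
    cat(sprintf("  net charge: %.3g C\n", x$net_coulombs))
  invisible(x)
}

#' Compensate a measured DC offset
#'
#' Subtracts a measured normalized DC level from the waveform and re-clamps
#' to \[-1, 1\]; used to cancel offsets introduced downstream in the analog
#' chain at waveform-generation time.
#'
#' @param w A [stim_waveform()].
#' @param measured_dc Normalized DC level, |dc| < 1.
#' @return A compensated [stim_waveform()].
#' @export
offset_compensate <- function(w, measured_dc) {
  stopifnot(inherits(w, "stim_waveform"))
  if (abs(measured_dc) >= 1)
    stop("measured DC must satisfy |dc| < 1", call. = FALSE)
  stim_waveform(pmin(1, pmax(-1, w$values - measured_dc)), w$fs)
}
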