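#' Design the Butterworth bandpass filter used before energy estimation
#'
#' Designs a digital Butterworth bandpass via the bilinear transform
#' ([signal::butter()]). `order` is the Butterworth design order (the order
#' of the lowpass prototype); the resulting bandpass transfer function has
#' `2 * order` poles. The magnitude response is -3.01 dB at both band edges
#' by construction and rolls off monotonically outside the band.
#'
#' The default 200-800 Hz band is the nasalance analysis band: it contains
#' the first formant region where oral/nasal energy differences are most
#' informative, while excluding low-frequency rumble and high-frequency
#' channel differences.
#'
#' @param low_hz,high_hz Band edges in Hz; `0 < low_hz < high_hz < sample_rate/2`.
#' @param order Butterworth design order (positive integer, default 2).
#'   `order = 1` gives the single-biquad variant.
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `filter_spec`: transfer-function coefficients
#'   `b`, `a` plus the design parameters.
#' @export
design_bandpass <- function(low_hz, high_hz, order = 2, sample_rate = 44100) {
  if (!is.numeric(low_hz) || low_hz <= 0) stop("low_hz must be > 0")
  if (high_hz <= low_hz) stop("band edges must satisfy low_hz < high_hz")
  if (high_hz >= sample_rate / 2) {
    stop("high_hz (", high_hz, ") must be below the Nyquist frequency (",
         sample_rate / 2, ")")
  }
  if (order < 1 || order != round(order)) stop("order must be a positive integer")
  flt <- signal::butter(order, c(low_hz, high_hz) * 2 / sample_rate,
                        type = "pass")
  spec <- structure(
    list(b = as.numeric(flt$b), a = as.numeric(flt$a),
         low_hz = low_hz, high_hz = high_hz, order = order,
         sample_rate = sample_rate, type = "bandpass"),
    class = "filter_spec")
  if (!filter_is_stable(spec)) stop("designed filter is unstable")
  spec
}

#' Pass-through (identity) filter
#'
#' Used when a recording should be analyzed as provided, e.g. output of a
#' commercial nasometer whose hardware already band-limits the signal.
#'
#' @param sample_rate Sampling rate the spec is nominally attached to
#'   (`NA` matches any rate).
#' @return A `filter_spec` whose application is the identity.
#' @export
passthrough_filter <- function(sample_rate = NA) {
  structure(list(b = 1, a = 1, low_hz = NA, high_hz = NA, order = 0,
                 sample_rate = sample_rate, type = "passthrough"),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  if (x$type == "passthrough") {
    cat("<filter_spec> passthrough\n")
  } else {
    cat(sprintf("<filter_spec> Butterworth bandpass %g-%g Hz, order %d @ %g Hz\n",
                x$low_hz, x$high_hz, x$order, x$sample_rate))
  }
  invisible(x)
}

#' Filter stability check
#'
#' @param spec A `filter_spec`.
#' @return `TRUE` when all poles lie strictly inside the unit circle.
#' @export
filter_is_stable <- function(spec) {
  if (length(spec$a) == 1) return(TRUE)
  all(Mod(polyroot(rev(spec$a))) < 1)
}

#' Evaluate a filter's frequency response
#'
#' Evaluates the transfer function on the unit circle at the requested
#' frequencies.
#'
#' @param spec A `filter_spec`.
#' @param freq_hz Frequencies in Hz.
#' @param db If `TRUE` (default) return magnitude in dB, else the complex
#'   response.
#' @return Numeric (dB) or complex vector, one value per frequency.
#' @export
filter_response <- function(spec, freq_hz, db = TRUE) {
  fs <- spec$sample_rate
  if (is.na(fs)) fs <- 2  # passthrough: response is 1 everywhere
  h <- vapply(freq_hz, function(f) {
    zi <- exp(-1i * 2 * pi * f / fs)
    sum(spec$b * zi^(seq_along(spec$b) - 1)) /
      sum(spec$a * zi^(seq_along(spec$a) - 1))
  }, complex(1))
  if (db) 20 * log10(Mod(h)) else h
}

#' Apply an IIR filter to a signal
#'
#' `causal` mode is a single forward pass, matching a real-time streaming
#' implementation; `zero_phase` runs forward-backward
#' ([signal::filtfilt()]) and introduces no group delay, which is preferable
#' for offline spectral analysis. Output length equals input length in both
#' modes.
#'
#' @param x Numeric signal sampled at `spec$sample_rate`.
#' @param spec A `filter_spec` from [design_bandpass()] or
#'   [passthrough_filter()].
#' @param mode `"causal"` (default) or `"zero_phase"`.
#' @return Filtered numeric vector, same length as `x`.
#' @export
apply_filter <- function(x, spec, mode = c("causal", "zero_phase")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$type == "passthrough") return(as.numeric(x))
  if (mode == "causal") {
    as.numeric(signal::filter(spec$b, spec$a, x))
  } else {
    as.numeric(signal::filtfilt(spec$b, spec$a, x))
  }
}

#' Filter both channels of a dual recording
#'
#' Applies the same filter to the nasal and oral channels, checking that the
#' recording's rate matches the filter design rate.
#'
#' @param rec A [dual_recording()].
#' @inheritParams apply_filter
#' @return A filtered [dual_recording()].
#' @export
filter_recording <- function(rec, spec, mode = c("causal", "zero_phase")) {
  stopifnot(inherits(rec, "dual_recording"), inherits(spec, "filter_spec"))
  mode <- match.arg(mode)
  if (spec$type != "passthrough" && !is.na(spec$sample_rate) &&
      spec$sample_rate != rec$sample_rate) {
    stop("filter designed for ", spec$sample_rate,
         " Hz applied to recording at ", rec$sample_rate, " Hz")
  }
  dual_recording(nasal = apply_filter(rec$nasal, spec, mode),
                 oral = apply_filter(rec$oral, spec, mode),
                 sample_rate = rec$sample_rate)
}
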