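#' Long-term average spectrum aggregated into fixed-width bands
#'
#' Estimates the power spectral density by overlapped averaged periodograms
#' (Welch's method: Hann-windowed segments, 50% overlap), then sums power
#' within contiguous frequency bands and converts to dB. The banding (one
#' representative level per `band_width_hz` interval) matches how nasometer
#' frequency responses are conventionally compared. Band membership is
#' half-open: `[low, low + band_width_hz)`, centers reported at
#' `low + band_width_hz / 2`.
#'
#' @param x Numeric signal.
#' @param sample_rate Sampling rate in Hz.
#' @param band_width_hz Band width in Hz (default 50); must divide the range.
#' @param range_hz Two-element display/analysis range (default 100-1000 Hz),
#'   upper edge below Nyquist.
#' @param segment_s Welch segment length in seconds (default 1).
#' @param overlap Segment overlap fraction (default 0.5).
#' @return An object of class `ltas_curve`: data.frame with
#'   `band_center_hz`, `level_db`, and attributes `mode` (`"absolute"`),
#'   `range_hz`, `band_width_hz`.
#' @export
compute_ltas <- function(x, sample_rate, band_width_hz = 50,
                         range_hz = c(100, 1000), segment_s = 1,
                         overlap = 0.5) {
  if (range_hz[2] > sample_rate / 2) stop("range_hz exceeds Nyquist")
  if (range_hz[2] <= range_hz[1]) stop("invalid range_hz")
  if ((range_hz[2] - range_hz[1]) %% band_width_hz != 0) {
    stop("band_width_hz must divide the analysis range")
  }
  seg_n <- round(segment_s * sample_rate)
  if (length(x) < seg_n) {
    stop("signal shorter than one ", segment_s, " s analysis segment")
  }
  hop_n <- max(1L, round(seg_n * (1 - overlap)))
  starts <- seq(1L, length(x) - seg_n + 1L, by = hop_n)
  w <- .window_samples(seg_n, "hann")
  scale <- sample_rate * sum(w^2)
  psd <- 0
  for (s in starts) {
    X <- stats::fft(x[s:(s + seg_n - 1L)] * w)
    psd <- psd + Mod(X)^2 / scale
  }
  psd <- psd / length(starts)
  # one-sided PSD over [0, Nyquist]
  half <- seq_len(seg_n %/% 2 + 1)
  psd_1 <- psd[half]
  psd_1[-c(1, length(half))] <- 2 * psd_1[-c(1, length(half))]
  freqs <- (half - 1) * sample_rate / seg_n
  df <- sample_rate / seg_n

  lows <- seq(range_hz[1], range_hz[2] - band_width_hz, by = band_width_hz)
  power <- vapply(lows, function(lo) {
    sel <- freqs >= lo & freqs < lo + band_width_hz
    sum(psd_1[sel]) * df
  }, numeric(1))
  structure(data.frame(band_center_hz = lows + band_width_hz / 2,
                       level_db = 10 * log10(power)),
            class = c("ltas_curve", "data.frame"),
            mode = "absolute", range_hz = range_hz,
            band_width_hz = band_width_hz)
}

#' @export
print.ltas_curve <- function(x, ...) {
  cat(sprintf("<ltas_curve> %d bands of %g Hz over %g-%g Hz (%s dB)\n",
              nrow(x), attr(x, "band_width_hz"), attr(x, "range_hz")[1],
              attr(x, "range_hz")[2], attr(x, "mode")))
  invisible(x)
}

#' Normalize an LTAS curve to its own maximum
#'
#' Emphasizes spectral shape over absolute gain: every level is reduced by
#' the curve maximum so the peak band sits at 0 dB. Two curves differing only
#' by a constant gain become identical.
#'
#' @param curve An absolute-mode `ltas_curve`.
#' @return A relative-mode `ltas_curve`.
#' @export
normalize_relative <- function(curve) {
  stopifnot(inherits(curve, "ltas_curve"))
  if (attr(curve, "mode") != "absolute") {
    stop("curve is already in relative mode")
  }
  if (all(!is.finite(curve$level_db))) stop("all-silent curve cannot be normalized")
  curve$level_db <- curve$level_db - max(curve$level_db)
  attr(curve, "mode") <- "relative"
  curve
}

#' Mean absolute difference between two LTAS curves
#'
#' Averages `|a - b|` over the bands whose centers fall inside `band_hz`
#' (inclusive). The curves must share band grid and mode.
#'
#' @param a,b `ltas_curve` objects on identical band grids, same mode.
#' @param band_hz Comparison band (default 200-800 Hz, the nasalance band).
#' @return The MAD in dB.
#' @export
ltas_mad <- function(a, b, band_hz = c(200, 800)) {
  stopifnot(inherits(a, "ltas_curve"), inherits(b, "ltas_curve"))
  if (!isTRUE(all.equal(a$band_center_hz, b$band_center_hz))) {
    stop("mismatched band grids")
  }
  if (!identical(attr(a, "mode"), attr(b, "mode"))) {
    stop("curves must share the same mode (absolute/relative)")
  }
  sel <- a$band_center_hz >= band_hz[1] & a$band_center_hz <= band_hz[2]
  if (!any(sel)) stop("no bands inside the comparison range")
  mean(abs(a$level_db[sel] - b$level_db[sel]))
}

#' Oral-nasal intensity gap (channel isolation)
#'
#' With a single active source (e.g. an oral loudspeaker) the level
#' difference between the oral and nasal channels measures the acoustic
#' isolation provided by the separator plate: higher gap = less
#' cross-channel leakage. Levels are whole-recording RMS in dB re full
#' scale; only the difference is comparable across systems.
#'
#' @param rec A [dual_recording()].
#' @param filt Optional `filter_spec` applied to both channels first
#'   (`NULL` = analyze as provided).
#' @return An object of class `isolation_result`: list with
#'   `oral_level_db`, `nasal_level_db`, `gap_db = oral - nasal`.
#' @export
intensity_gap <- function(rec, filt = NULL) {
  stopifnot(inherits(rec, "dual_recording"))
  if (!is.null(filt)) rec <- filter_recording(rec, filt)
  rms_n <- sqrt(mean(rec$nasal^2))
  rms_o <- sqrt(mean(rec$oral^2))
  if (rms_n == 0 || rms_o == 0) {
    stop("silent channel: intensity gap is undefined")
  }
  structure(list(oral_level_db = 20 * log10(rms_o),
                 nasal_level_db = 20 * log10(rms_n),
                 gap_db = 20 * log10(rms_o) - 20 * log10(rms_n)),
            class = "isolation_result")
}

#' @export
print.isolation_result <- function(x, ...) {
  cat(sprintf("<isolation_result> oral %.2f dBFS, nasal %.2f dBFS, gap %.2f dB\n",
              x$oral_level_db, x$nasal_level_db, x$gap_db))
  invisible(x)
}

#' Total harmonic distortion of a recorded tone
#'
#' Estimates harmonic amplitudes from the Hann-windowed spectrum: each
#' harmonic's amplitude is taken as the root of the spectral power within
#' +/- 2 bins of its peak (capturing the window main lobe, which makes the
#' estimate robust to non-integer cycle counts). THD% is
#' `100 * sqrt(sum of harmonic powers 2..n) / fundamental amplitude`.
#'
#' @param x Numeric signal containing a steady tone.
#' @param sample_rate Sampling rate in Hz.
#' @param fundamental_hz Nominal tone frequency (default 1000 Hz, the
#'   standard distortion test tone).
#' @param n_harmonics Highest harmonic included (default 5); harmonics at or
#'   above Nyquist are skipped.
#' @return THD in percent.
#' @export
compute_thd <- function(x, sample_rate, fundamental_hz = 1000,
                        n_harmonics = 5) {
  n <- length(x)
  if (n < sample_rate / fundamental_hz * 10) {
    stop("signal too short to resolve the fundamental")
  }
  w <- .window_samples(n, "hann")
  X <- Mod(stats::fft(x * w))[seq_len(n %/% 2 + 1)]
  bin_of <- function(f) round(f * n / sample_rate) + 1

  band_amp <- function(f) {
    b0 <- bin_of(f)
    search <- max(2, b0 - 2):min(length(X), b0 + 2)
    pk <- search[which.max(X[search])]
    lo <- max(2, pk - 2)
    hi <- min(length(X), pk + 2)
    sqrt(sum(X[lo:hi]^2))
  }

  a1 <- band_amp(fundamental_hz)
  if (a1 <= 20 * stats::median(X)) {
    stop("no detectable fundamental near ", fundamental_hz, " Hz")
  }
  # refine the fundamental estimate from the observed peak bin
  b0 <- bin_of(fundamental_hz)
  search <- max(2, b0 - 2):min(length(X), b0 + 2)
  f1 <- (search[which.max(X[search])] - 1) * sample_rate / n

  harm <- 2:n_harmonics
  harm <- harm[harm * f1 < sample_rate / 2]
  hpow <- sum(vapply(harm, function(k) band_amp(k * f1)^2, numeric(1)))
  100 * sqrt(hpow) / a1
}
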