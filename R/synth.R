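#' Configuration for the synthetic dual-channel generator
#'
#' Describes a simulated nasometer recording with known ground truth: a
#' single source signal split between the nasal and oral channels so that
#' the frame RMS ratio follows a prescribed nasalance profile, with
#' symmetric cross-channel leakage (finite isolation) and an additive noise
#' floor.
#'
#' @param duration_s Recording length in seconds (> 0).
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @param nasalance_profile Target nasalance in percent: a scalar, a numeric
#'   vector (piecewise constant over equal time segments), or a function of
#'   time in seconds returning percentages.
#' @param source_kind `"speech_like"` (default; 200-800 Hz band-limited
#'   noise with 4 Hz syllabic amplitude modulation), `"noise"` (white), or
#'   `"sine"`.
#' @param isolation_db Cross-channel isolation in dB (>= 0); `Inf` means no
#'   leakage. Leakage is modeled as a frequency-independent symmetric gain
#'   `alpha = 10^(-isolation_db / 20)`.
#' @param noise_floor_dbfs Per-channel independent white noise RMS in dBFS;
#'   `-Inf` disables it.
#' @param source_freq_hz Tone frequency for `source_kind = "sine"`.
#' @param source_level_dbfs RMS level of the source signal (default -20).
#' @param seed Integer seed; identical configs give bit-identical recordings.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(duration_s = 10, sample_rate = 44100,
                         nasalance_profile = 50,
                         source_kind = c("speech_like", "noise", "sine"),
                         isolation_db = Inf, noise_floor_dbfs = -Inf,
                         source_freq_hz = 1000, source_level_dbfs = -20,
                         seed = 1) {
  source_kind <- match.arg(source_kind)
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (isolation_db < 0) stop("isolation_db must be >= 0")
  if (is.numeric(nasalance_profile) &&
      any(nasalance_profile < 0 | nasalance_profile > 100)) {
    stop("nasalance_profile values must lie in [0, 100]")
  }
  structure(list(duration_s = duration_s, sample_rate = sample_rate,
                 nasalance_profile = nasalance_profile,
                 source_kind = source_kind, isolation_db = isolation_db,
                 noise_floor_dbfs = noise_floor_dbfs,
                 source_freq_hz = source_freq_hz,
                 source_level_dbfs = source_level_dbfs,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# evaluate the profile (percent) at arbitrary times
.profile_fun <- function(profile, duration_s) {
  if (is.function(profile)) return(profile)
  values <- as.numeric(profile)
  function(t) {
    idx <- pmin(length(values), pmax(1L, floor(t / duration_s * length(values)) + 1L))
    values[idx]
  }
}

# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic dual-channel recording with known ground truth
#'
#' A common source signal is split with time-varying weights
#' `w_nasal = p(t)/100`, `w_oral = 1 - p(t)/100`, so the ideal frame RMS
#' ratio equals the profile exactly. Leakage then mixes `alpha * oral` into
#' the nasal channel and vice versa, and independent white noise at the
#' configured floor is added per channel. Because both channels carry the
#' same source, the leakage effect on measured nasalance has the closed
#' form given by [expected_leakage_bias()].
#'
#' @param cfg A [synth_config()].
#' @return List with `recording` (a [dual_recording()]) and `truth` (class
#'   `ground_truth`: the profile function, `leakage_coefficient`,
#'   `expected_nasalance(t)` including the leakage bias, and `warp_map`,
#'   `NULL` until [apply_time_warp()] is used).
#' @export
generate_dual_recording <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  fs <- cfg$sample_rate
  n <- round(cfg$duration_s * fs)
  t <- (seq_len(n) - 1) / fs

  src <- .with_seed(cfg$seed, {
    s <- switch(cfg$source_kind,
      noise = stats::rnorm(n),
      sine = sin(2 * pi * cfg$source_freq_hz * t),
      speech_like = {
        raw <- stats::rnorm(n)
        bl <- apply_filter(raw, design_bandpass(200, 800, 2, fs))
        bl * (0.55 + 0.45 * sin(2 * pi * 4 * t))
      })
    s / sqrt(mean(s^2)) * 10^(cfg$source_level_dbfs / 20)
  })

  pf <- .profile_fun(cfg$nasalance_profile, cfg$duration_s)
  p <- pf(t) / 100
  if (any(p < 0 | p > 1)) stop("nasalance_profile values must lie in [0, 100]")
  nasal0 <- p * src
  oral0 <- (1 - p) * src

  alpha <- if (is.infinite(cfg$isolation_db)) 0 else 10^(-cfg$isolation_db / 20)
  nasal <- nasal0 + alpha * oral0
  oral <- oral0 + alpha * nasal0

  if (is.finite(cfg$noise_floor_dbfs)) {
    amp <- 10^(cfg$noise_floor_dbfs / 20)
    noise <- .with_seed(cfg$seed + 1L, list(stats::rnorm(n), stats::rnorm(n)))
    nasal <- nasal + amp * noise[[1]]
    oral <- oral + amp * noise[[2]]
  }

  truth <- structure(
    list(profile = pf,
         leakage_coefficient = alpha,
         expected_nasalance = function(t) {
           expected_leakage_bias(pf(t), cfg$isolation_db)
         },
         warp_map = NULL,
         config = cfg),
    class = "ground_truth")
  list(recording = dual_recording(nasal, oral, fs), truth = truth)
}

#' Closed-form nasalance under cross-channel leakage
#'
#' When channels with true RMS weights `n = p/100`, `o = 1 - p/100` of a
#' shared source are mixed with leakage coefficient
#' `alpha = 10^(-isolation_db/20)`, the RMS-ratio nasalance becomes
#' `100 * (n + alpha * o) / ((n + alpha * o) + (o + alpha * n))`. This is the
#' analytic oracle for recordings made by [generate_dual_recording()]:
#' leakage compresses nasalance monotonically toward 50%, the mechanism by
#' which a device with poorer isolation reads high on oral material and low
#' on nasal material.
#'
#' @param profile_pct True nasalance percentage(s) in \[0, 100\].
#' @param isolation_db Isolation in dB (>= 0, `Inf` = no leakage).
#' @return Expected measured nasalance percentage(s).
#' @export
expected_leakage_bias <- function(profile_pct, isolation_db) {
  if (any(profile_pct < 0 | profile_pct > 100)) stop("profile_pct out of range")
  alpha <- ifelse(is.infinite(isolation_db), 0, 10^(-isolation_db / 20))
  n <- profile_pct / 100
  o <- 1 - n
  100 * (n + alpha * o) / ((n + alpha * o) + (o + alpha * n))
}

#' Monotone time warp objects
#'
#' A time warp maps output time `u` in `[0, duration_out]` to input time
#' `w(u)` in the original recording, strictly increasing. `time_warp_linear`
#' is a uniform rate change (`rate` > 1 slows down: output duration =
#' `rate * duration_in`). `time_warp_sine` adds a smooth sinusoidal
#' modulation emulating non-linear speaking-rate variation; `depth_s` is the
#' maximum local time displacement in seconds and must keep the map
#' monotone (`2 * pi * depth_s / duration < 1` per modulation cycle).
#'
#' @param duration_in Input duration in seconds.
#' @param rate Uniform slowdown factor (> 0).
#' @param depth_s Peak displacement of the sinusoidal modulation in seconds.
#' @param cycles Number of modulation cycles over the recording (default 1).
#' @return An object of class `time_warp`: list with `fun` (output time to
#'   input time), `duration_out`, `duration_in`.
#' @export
time_warp_linear <- function(duration_in, rate = 1) {
  if (rate <= 0) stop("rate must be > 0")
  structure(list(fun = function(u) u / rate,
                 duration_out = duration_in * rate,
                 duration_in = duration_in),
            class = "time_warp")
}

#' @rdname time_warp_linear
#' @export
time_warp_sine <- function(duration_in, depth_s = 0, cycles = 1) {
  dur <- duration_in
  if (abs(depth_s) * 2 * pi * cycles / dur >= 1) {
    stop("depth_s too large: warp would not be monotone")
  }
  f <- function(u) u + depth_s * sin(2 * pi * cycles * u / dur)
  structure(list(fun = f, duration_out = dur, duration_in = dur),
            class = "time_warp")
}

.check_monotone_warp <- function(warp) {
  u <- seq(0, warp$duration_out, length.out = 512)
  tin <- warp$fun(u)
  if (any(diff(tin) <= 0)) stop("warp map is not strictly increasing")
  if (min(tin) < -1e-9 || max(tin) > warp$duration_in + 1e-9) {
    stop("warp map must cover the input time span")
  }
  invisible(TRUE)
}

#' Apply a monotone time warp
#'
#' Resamples the input at the warped times by linear interpolation,
#' emulating speaking-rate variability between two non-synchronous
#' recordings of the same material. Works on a [dual_recording()] (sample
#' level) or a `nasalance_trajectory` (frame level, preserving the hop grid;
#' a warped frame is valid when its two interpolation neighbors are valid).
#'
#' @param x A `dual_recording` or `nasalance_trajectory`.
#' @param warp A `time_warp` from [time_warp_linear()] / [time_warp_sine()].
#' @return A warped object of the same class, with the warp recorded in the
#'   `warp` attribute.
#' @export
apply_time_warp <- function(x, warp) UseMethod("apply_time_warp")

#' @export
apply_time_warp.dual_recording <- function(x, warp) {
  stopifnot(inherits(warp, "time_warp"))
  .check_monotone_warp(warp)
  fs <- x$sample_rate
  t_in <- (seq_along(x$nasal) - 1) / fs
  u <- seq(0, warp$duration_out, by = 1 / fs)
  tq <- pmin(pmax(warp$fun(u), 0), max(t_in))
  out <- dual_recording(
    nasal = stats::approx(t_in, x$nasal, xout = tq, rule = 2)$y,
    oral = stats::approx(t_in, x$oral, xout = tq, rule = 2)$y,
    sample_rate = fs)
  attr(out, "warp") <- warp
  out
}

#' @export
apply_time_warp.nasalance_trajectory <- function(x, warp) {
  stopifnot(inherits(warp, "time_warp"))
  .check_monotone_warp(warp)
  hop <- attr(x, "hop_s")
  u <- seq(min(x$time_s), by = hop,
           length.out = max(2, floor((warp$duration_out - 2 * min(x$time_s)) / hop) + 1))
  tq <- pmin(pmax(warp$fun(u), min(x$time_s)), max(x$time_s))
  if (sum(x$valid) < 2) stop("need at least 2 valid frames to warp")
  vals <- stats::approx(x$time_s[x$valid], x$nasalance_pct[x$valid],
                        xout = tq, rule = 2)$y
  # a warped frame is valid only when both interpolation neighbors are
  validity <- stats::approx(x$time_s, as.numeric(x$valid), xout = tq,
                            rule = 2)$y >= 1 - 1e-9
  vals[!validity] <- NA_real_
  out <- nasalance_trajectory(u, vals, valid = validity & !is.na(vals),
                              hop_s = hop)
  attr(out, "warp") <- warp
  out
}
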