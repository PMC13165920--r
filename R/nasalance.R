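#' Framing configuration
#'
#' @param window_s Analysis window length in seconds (> 0). Default 50 ms,
#'   the standard nasometric analysis window.
#' @param overlap_fraction Fraction of the window shared by consecutive
#'   frames, in \[0, 1). Default 0.5.
#' @param window_function `"hann"` (default) or `"rectangular"`.
#' @return An object of class `frame_config`.
#' @export
frame_config <- function(window_s = 0.05, overlap_fraction = 0.5,
                         window_function = c("hann", "rectangular")) {
  window_function <- match.arg(window_function)
  if (window_s <= 0) stop("window_s must be > 0")
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must be in [0, 1)")
  }
  structure(list(window_s = window_s, overlap_fraction = overlap_fraction,
                 window_function = window_function),
            class = "frame_config")
}

#' Energy gate configuration
#'
#' Frames whose combined two-channel RMS falls below `floor_dbfs` are marked
#' invalid so that near-silence and noise-dominated frames do not contribute
#' unstable nasalance estimates. The threshold is compared against the RMS
#' of the windowed frame samples of both channels jointly.
#'
#' @param floor_dbfs Gate threshold in dB re digital full scale (must be
#'   <= 0). Default -50 dBFS, well below conversational speech recorded at
#'   typical calibration levels but above electronic noise floors.
#' @param enabled Logical; gate on/off.
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(floor_dbfs = -50, enabled = TRUE) {
  if (floor_dbfs > 0) stop("floor_dbfs must be <= 0 (dB re full scale)")
  structure(list(floor_dbfs = floor_dbfs, enabled = isTRUE(enabled)),
            class = "gate_config")
}

.window_samples <- function(n, kind) {
  if (n == 1) return(1)
  switch(kind,
         rectangular = rep(1, n),
         hann = 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)))
}

#' Slice a signal into overlapping windowed frames
#'
#' Frames start at integer multiples of the hop
#' (`window_s * (1 - overlap_fraction)`); a trailing partial window is
#' discarded. The window function is applied multiplicatively. Frame
#' timestamps are window centers.
#'
#' @param x Numeric signal.
#' @param sample_rate Sampling rate in Hz.
#' @param cfg A [frame_config()].
#' @return A list with `times_s` (frame-center seconds), `frames` (matrix,
#'   one column per frame, window applied) and `hop_s`.
#' @export
frame_signal <- function(x, sample_rate, cfg = frame_config()) {
  stopifnot(inherits(cfg, "frame_config"))
  win_n <- round(cfg$window_s * sample_rate)
  hop_n <- round(win_n * (1 - cfg$overlap_fraction))
  if (hop_n < 1) stop("hop is below one sample; reduce overlap_fraction")
  if (length(x) < win_n) {
    stop("signal (", length(x), " samples) shorter than one analysis window (",
         win_n, " samples)")
  }
  starts <- seq(1L, length(x) - win_n + 1L, by = hop_n)
  w <- .window_samples(win_n, cfg$window_function)
  frames <- vapply(starts, function(s) x[s:(s + win_n - 1L)] * w,
                   numeric(win_n))
  frames <- matrix(frames, nrow = win_n)
  list(times_s = (starts - 1 + (win_n - 1) / 2) / sample_rate,
       frames = frames,
       hop_s = hop_n / sample_rate)
}

#' Root-mean-square amplitude of a frame
#'
#' @param frame Non-empty numeric vector (windowed samples).
#' @return `sqrt(mean(frame^2))`.
#' @export
frame_rms <- function(frame) {
  if (length(frame) == 0) stop("empty frame")
  sqrt(mean(frame^2))
}

#' Compute a nasalance trajectory
#'
#' The core nasometric computation: both channels are bandpass filtered with
#' the same filter, sliced into identical overlapping windowed frames, and
#' per frame the nasalance is the RMS amplitude ratio
#' `100 * N / (N + O)` where `N` and `O` are the nasal and oral frame RMS.
#' Frames are marked invalid when the energy gate is enabled and the
#' combined two-channel frame RMS falls below the gate floor, or when
#' `N + O` is exactly zero (the ratio is undefined there).
#'
#' @param rec A [dual_recording()].
#' @param filt A `filter_spec`; use [passthrough_filter()] to analyze a
#'   recording as provided.
#' @param fcfg A [frame_config()].
#' @param gate A [gate_config()].
#' @param mode Filtering mode passed to [apply_filter()]; `"causal"`
#'   (default) matches a streaming implementation.
#' @param energy `"rms"` (default) uses the RMS amplitude ratio;
#'   `"squared"` uses the mean-square (energy) ratio instead.
#' @return An object of class `nasalance_trajectory`: a data.frame with
#'   columns `time_s`, `nasalance_pct` (`NA` where invalid), `valid`,
#'   `nasal_rms`, `oral_rms`, plus a `config` attribute recording the full
#'   provenance.
#' @export
compute_trajectory <- function(rec, filt = design_bandpass(200, 800, 2, rec$sample_rate),
                               fcfg = frame_config(), gate = gate_config(),
                               mode = c("causal", "zero_phase"),
                               energy = c("rms", "squared")) {
  stopifnot(inherits(rec, "dual_recording"))
  mode <- match.arg(mode)
  energy <- match.arg(energy)
  if (length(rec$nasal) == 0) stop("empty recording")
  frec <- filter_recording(rec, filt, mode)
  fn <- frame_signal(frec$nasal, rec$sample_rate, fcfg)
  fo <- frame_signal(frec$oral, rec$sample_rate, fcfg)

  n_rms <- apply(fn$frames, 2, frame_rms)
  o_rms <- apply(fo$frames, 2, frame_rms)
  if (energy == "squared") {
    num <- n_rms^2
    den <- n_rms^2 + o_rms^2
  } else {
    num <- n_rms
    den <- n_rms + o_rms
  }

  # combined RMS over both channels' windowed samples jointly
  combined_rms <- sqrt((colSums(fn$frames^2) + colSums(fo$frames^2)) /
                         (2 * nrow(fn$frames)))
  valid <- den > 0
  if (gate$enabled) {
    valid <- valid & combined_rms >= 10^(gate$floor_dbfs / 20)
  }
  pct <- ifelse(valid, 100 * num / den, NA_real_)

  traj <- data.frame(time_s = fn$times_s, nasalance_pct = pct, valid = valid,
                     nasal_rms = n_rms, oral_rms = o_rms)
  structure(traj,
            class = c("nasalance_trajectory", "data.frame"),
            hop_s = fn$hop_s,
            config = list(filter = filt, frame = fcfg, gate = gate,
                          mode = mode, energy = energy,
                          sample_rate = rec$sample_rate))
}

#' Construct a nasalance trajectory from bare values
#'
#' Convenience constructor used for precomputed or simulated trajectories
#' (e.g. ground-truth profiles, CSV round trips).
#'
#' @param time_s Increasing frame-center times.
#' @param nasalance_pct Values in \[0, 100\] (`NA` where invalid).
#' @param valid Logical mask; defaults to `!is.na(nasalance_pct)`.
#' @param hop_s Frame hop in seconds; inferred from `time_s` when omitted.
#' @return A `nasalance_trajectory`.
#' @export
nasalance_trajectory <- function(time_s, nasalance_pct,
                                 valid = !is.na(nasalance_pct),
                                 hop_s = NULL) {
  if (length(time_s) != length(nasalance_pct)) stop("length mismatch")
  if (is.unsorted(time_s, strictly = TRUE)) {
    stop("time_s must be strictly increasing")
  }
  if (any(nasalance_pct < 0 | nasalance_pct > 100, na.rm = TRUE)) {
    stop("nasalance_pct must lie in [0, 100]")
  }
  if (is.null(hop_s)) {
    hop_s <- if (length(time_s) > 1) stats::median(diff(time_s)) else NA_real_
  }
  structure(data.frame(time_s = time_s,
                       nasalance_pct = ifelse(valid, nasalance_pct, NA_real_),
                       valid = valid,
                       nasal_rms = NA_real_, oral_rms = NA_real_),
            class = c("nasalance_trajectory", "data.frame"),
            hop_s = hop_s, config = list())
}

#' @export
print.nasalance_trajectory <- function(x, ...) {
  cat(sprintf("<nasalance_trajectory> %d frames (%d valid), hop %.4g s\n",
              nrow(x), sum(x$valid), attr(x, "hop_s")))
  invisible(x)
}

#' Session-level nasalance summary
#'
#' Mean, minimum, maximum and sample standard deviation (n - 1 denominator)
#' of the nasalance over valid frames only.
#'
#' @param object A `nasalance_trajectory`.
#' @param ... Unused.
#' @return An object of class `nasalance_summary`: list with `mean_pct`,
#'   `min_pct`, `max_pct`, `sd_pct`, `n_valid_frames`, `n_total_frames`.
#' @export
summary.nasalance_trajectory <- function(object, ...) {
  v <- object$nasalance_pct[object$valid]
  if (length(v) == 0) {
    stop("no valid frames: the recording is fully gated or silent")
  }
  structure(list(mean_pct = mean(v),
                 min_pct = min(v),
                 max_pct = max(v),
                 sd_pct = if (length(v) > 1) stats::sd(v) else 0,
                 n_valid_frames = length(v),
                 n_total_frames = nrow(object)),
            class = "nasalance_summary")
}

#' @export
print.nasalance_summary <- function(x, ...) {
  cat(sprintf(paste0("<nasalance_summary> mean %.2f%%, sd %.2f, range ",
                     "[%.2f, %.2f]%% over %d/%d valid frames\n"),
              x$mean_pct, x$sd_pct, x$min_pct, x$max_pct,
              x$n_valid_frames, x$n_total_frames))
  invisible(x)
}

#' Write / read a trajectory as CSV
#'
#' Columns: `time_s, nasalance_pct, valid, nasal_rms, oral_rms`.
#'
#' @param traj A `nasalance_trajectory`.
#' @param path Output path.
#' @return `path` invisibly (write) or a `nasalance_trajectory` (read).
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path)
  traj <- nasalance_trajectory(d$time_s, d$nasalance_pct,
                               valid = as.logical(d$valid))
  if (!is.null(d$nasal_rms)) traj$nasal_rms <- d$nasal_rms
  if (!is.null(d$oral_rms)) traj$oral_rms <- d$oral_rms
  traj
}
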