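# Shared fixture builders. Everything is generated in code; no binary data.

# deterministic sine, amplitude a
tone <- function(freq, dur, fs, a = 1) a * sin(2 * pi * freq * (0:(dur * fs - 1)) / fs)

rms_of <- function(x) sqrt(mean(x^2))

# a slowly varying nasalance profile spanning a wide dynamic range,
# used wherever a non-degenerate trajectory is needed
wavy_profile <- function(t) 50 + 35 * sin(2 * pi * 0.4 * t)

# a speech-like synthetic recording with that profile
wavy_recording <- function(duration_s = 5, fs = 22050, isolation_db = Inf,
                           noise_floor_dbfs = -Inf, seed = 11) {
  generate_dual_recording(synth_config(
    duration_s = duration_s, sample_rate = fs,
    nasalance_profile = wavy_profile, source_kind = "speech_like",
    isolation_db = isolation_db, noise_floor_dbfs = noise_floor_dbfs,
    seed = seed))
}

wavy_trajectory <- function(...) {
  sim <- wavy_recording(...)
  fs <- sim$recording$sample_rate
  compute_trajectory(sim$recording, design_bandpass(200, 800, 2, fs))
}

# independent brute-force DTW oracle: plain O(n*m) DP over the full cost
# matrix, no path reuse with the implementation
dtw_cost_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  D <- matrix(Inf, n, m)
  D[1, 1] <- abs(x[1] - y[1])
  for (j in 2:m) D[1, j] <- D[1, j - 1] + abs(x[1] - y[j])
  for (i in 2:n) {
    D[i, 1] <- D[i - 1, 1] + abs(x[i] - y[1])
    for (j in 2:m) {
      D[i, j] <- abs(x[i] - y[j]) + min(D[i - 1, j - 1], D[i - 1, j], D[i, j - 1])
    }
  }
  D[n, m]
}
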