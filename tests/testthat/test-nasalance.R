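test_that("framing produces the expected frame grid", {
  fs <- 1000
  x <- rnorm(fs)  # 1.0 s
  fr <- frame_signal(x, fs, frame_config(0.05, 0.5))
  expect_identical(ncol(fr$frames), 39L)  # floor((1000-50)/25)+1
  expect_equal(fr$hop_s, 0.025)
  expect_equal(diff(fr$times_s), rep(0.025, 38))

  # zero overlap tiles the signal
  fr0 <- frame_signal(x, fs, frame_config(0.05, 0))
  expect_identical(ncol(fr0$frames), 20L)

  # rectangular window of a constant signal: every frame identical
  frc <- frame_signal(rep(0.5, fs), fs, frame_config(0.05, 0.5, "rectangular"))
  expect_true(all(frc$frames == 0.5))

  expect_error(frame_signal(rnorm(10), fs, frame_config(0.05, 0.5)), "shorter")
})

test_that("frame_rms matches closed forms", {
  expect_equal(frame_rms(rep(0.5, 100)), 0.5)
  expect_equal(frame_rms(tone(100, 0.1, 8000)), 1 / sqrt(2), tolerance = 0.01)
  expect_identical(frame_rms(numeric(10)), 0)
  expect_error(frame_rms(numeric(0)), "empty")
})

test_that("nasalance identities: N=O gives 50, N=0 gives 0, 3:1 gives 75", {
  fs <- 8000
  src <- tone(400, 2, fs, a = 0.4)
  flt <- passthrough_filter()
  traj_mean <- function(nasal, oral) {
    tr <- compute_trajectory(dual_recording(nasal, oral, fs), flt,
                             gate = gate_config(enabled = FALSE))
    unique(round(tr$nasalance_pct[tr$valid], 10))
  }
  expect_equal(traj_mean(src, src), 50)
  expect_equal(traj_mean(0 * src, src), 0)
  expect_equal(traj_mean(3 * src, src), 75)
})

test_that("energy gate invalidates exactly the frames a brute-force recount flags", {
  fs <- 8000
  set.seed(21)
  dur <- 4
  nasal <- rnorm(dur * fs, sd = 0.05)
  oral <- rnorm(dur * fs, sd = 0.05)
  # inject quiet stretches (well below the -50 dBFS floor)
  quiet <- c(seq(fs, 1.5 * fs), seq(2.7 * fs, 3.2 * fs))
  nasal[quiet] <- nasal[quiet] * 1e-4
  oral[quiet] <- oral[quiet] * 1e-4
  rec <- dual_recording(nasal, oral, fs)
  fcfg <- frame_config(0.05, 0.5)
  gate <- gate_config(-50)
  tr <- compute_trajectory(rec, passthrough_filter(), fcfg, gate)

  # independent recount: re-frame both channels and threshold combined RMS
  win <- round(0.05 * fs); hop <- round(win * 0.5)
  starts <- seq(1, length(nasal) - win + 1, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, win - 1) / (win - 1))
  below <- vapply(starts, function(s) {
    seg <- c(nasal[s:(s + win - 1)] * w, oral[s:(s + win - 1)] * w)
    sqrt(mean(seg^2)) < 10^(-50 / 20)
  }, logical(1))
  expect_identical(sum(!tr$valid), sum(below))
  expect_identical(which(!tr$valid), which(below))
})

test_that("summary statistics match an independent recount over valid frames", {
  tr <- wavy_trajectory()
  s <- summary(tr)
  v <- tr$nasalance_pct[tr$valid]
  expect_equal(s$mean_pct, mean(v))
  expect_equal(s$min_pct, min(v))
  expect_equal(s$max_pct, max(v))
  expect_equal(s$sd_pct, sd(v))
  expect_identical(s$n_valid_frames, length(v))
  expect_identical(s$n_total_frames, nrow(tr))
  expect_true(s$min_pct <= s$mean_pct && s$mean_pct <= s$max_pct)

  # degenerate cases
  const <- nasalance_trajectory(c(0, 0.025), c(50, 50))
  expect_equal(summary(const)$sd_pct, 0)
  both <- nasalance_trajectory(c(0, 0.025), c(0, 100))
  expect_equal(summary(both)$mean_pct, 50)
  silent <- compute_trajectory(dual_recording(numeric(4000), numeric(4000), 8000),
                               passthrough_filter())
  expect_error(summary(silent), "no valid frames")
})

test_that("nasalance is scale-invariant and antisymmetric under channel swap", {
  sim <- wavy_recording(duration_s = 3)
  fs <- sim$recording$sample_rate
  flt <- design_bandpass(200, 800, 2, fs)
  tr <- compute_trajectory(sim$recording, flt, gate = gate_config(enabled = FALSE))

  scaled <- dual_recording(2.5 * sim$recording$nasal, 2.5 * sim$recording$oral, fs)
  tr_s <- compute_trajectory(scaled, flt, gate = gate_config(enabled = FALSE))
  expect_equal(tr_s$nasalance_pct, tr$nasalance_pct, tolerance = 1e-10)

  tr_sw <- compute_trajectory(swap_channels(sim$recording), flt,
                              gate = gate_config(enabled = FALSE))
  expect_equal(tr_sw$nasalance_pct[tr$valid], 100 - tr$nasalance_pct[tr$valid],
               tolerance = 1e-10)

  expect_true(all(tr$nasalance_pct[tr$valid] >= 0 &
                    tr$nasalance_pct[tr$valid] <= 100))
})

test_that("constant-ratio recordings recover the target nasalance within 0.5 pp", {
  for (p in c(10, 50, 90)) {
    sim <- generate_dual_recording(synth_config(
      duration_s = 2, sample_rate = 22050, nasalance_profile = p,
      source_kind = "speech_like", isolation_db = Inf,
      noise_floor_dbfs = -Inf, seed = p))
    tr <- compute_trajectory(sim$recording, design_bandpass(200, 800, 2, 22050))
    expect_lt(abs(summary(tr)$mean_pct - p), 0.5)
  }
})

test_that("unfiltered per-frame trajectory mean equals the summary mean", {
  sim <- wavy_recording(duration_s = 3)
  tr <- compute_trajectory(sim$recording, passthrough_filter(),
                           gate = gate_config(enabled = FALSE))
  expect_equal(summary(tr)$mean_pct, mean(tr$nasalance_pct[tr$valid]))
})

test_that("trajectory CSV round trip preserves values and validity", {
  tr <- wavy_trajectory(duration_s = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  back <- read_trajectory_csv(f)
  expect_equal(back$nasalance_pct, tr$nasalance_pct)
  expect_identical(back$valid, tr$valid)
  expect_equal(attr(back, "hop_s"), attr(tr, "hop_s"))
})
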