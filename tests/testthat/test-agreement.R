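# shift a trajectory by k whole hops (positive k = delayed start)
shift_trajectory <- function(tr, k) {
  hop <- attr(tr, "hop_s")
  nasalance_trajectory(tr$time_s, c(rep(NA, k), utils::head(tr$nasalance_pct, -k)),
                       hop_s = hop)
}

test_that("self-comparison gives r_raw = r_dtw = 1 at lag 0", {
  tr <- wavy_trajectory()
  res <- compare_trajectories(tr, tr)
  expect_equal(res$r_raw, 1)
  expect_equal(res$best_lag_s, 0)
  expect_equal(res$r_dtw, 1)
  # DTW path of identical sequences is the diagonal
  expect_true(all(res$warp_path[, 1] == res$warp_path[, 2]))
})

test_that("a pure delay inside the lag window is recovered exactly", {
  tr <- wavy_trajectory()
  hop <- attr(tr, "hop_s")
  delayed <- shift_trajectory(tr, 8)  # 8 hops = 200 ms at 25 ms hop
  res <- raw_cross_correlation(trajectory_pair(tr, delayed), max_lag_s = 0.5)
  expect_equal(res$r_raw, 1, tolerance = 1e-6)
  expect_equal(res$best_lag_s, -8 * hop)
})

test_that("raw cross-correlation equals an exhaustive lag-enumeration oracle", {
  tr <- wavy_trajectory()
  anti <- nasalance_trajectory(tr$time_s, 100 - tr$nasalance_pct,
                               hop_s = attr(tr, "hop_s"))
  pair <- trajectory_pair(tr, anti)
  res <- raw_cross_correlation(pair, max_lag_s = 0.5)

  # brute force: every integer-hop lag, Pearson over the overlap
  hop <- attr(tr, "hop_s")
  x <- tr$nasalance_pct
  y <- anti$nasalance_pct
  max_k <- floor(0.5 / hop)
  brute <- vapply(-max_k:max_k, function(k) {
    t <- max(1, 1 - k):min(length(x), length(y) - k)
    if (length(t) < 10) return(NA_real_)
    cor(x[t], y[t + k])
  }, numeric(1))
  expect_equal(res$r_raw, max(brute, na.rm = TRUE))
  # at lag 0 the centered correlation of p vs 100-p is exactly -1
  expect_equal(brute[max_k + 1], -1)
  expect_true(res$r_raw >= -1 && res$r_raw <= 1)
})

test_that("r_raw is non-decreasing in the lag window half-width", {
  tr <- wavy_trajectory()
  warped <- apply_time_warp(tr, time_warp_sine(5, depth_s = 0.3, cycles = 1))
  pair <- trajectory_pair(tr, warped)
  rs <- vapply(c(0.1, 0.25, 0.5, 1), function(L) {
    raw_cross_correlation(pair, max_lag_s = L)$r_raw
  }, numeric(1))
  expect_true(all(diff(rs) >= -1e-12))
})

test_that("DTW path cost equals an exhaustive DP oracle on short random pairs", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    m <- sample(4:12, 1)
    x <- runif(n, 0, 100)
    y <- runif(m, 0, 100)
    hop <- 0.025
    tx <- nasalance_trajectory(seq(0, by = hop, length.out = n), x)
    ty <- nasalance_trajectory(seq(0, by = hop, length.out = m), y)
    al <- dtw_align(trajectory_pair(tx, ty))
    expect_equal(al$distance, dtw_cost_oracle(x, y))
    # path is monotone with full boundary conditions
    expect_identical(al$warp_path[1, ], c(reference = 1L, candidate = 1L))
    expect_identical(al$warp_path[nrow(al$warp_path), ],
                     c(reference = as.integer(n), candidate = as.integer(m)))
    expect_true(all(diff(al$warp_path[, 1]) >= 0))
    expect_true(all(diff(al$warp_path[, 2]) >= 0))
  }
})

test_that("DTW absorbs a local slowdown at zero cost", {
  vals <- c(10, 20, 35, 35, 60, 40, 25)
  hop <- 0.025
  tx <- nasalance_trajectory(seq(0, by = hop, length.out = length(vals)), vals)
  dup <- append(vals, vals[4], after = 4)  # duplicate one frame
  ty <- nasalance_trajectory(seq(0, by = hop, length.out = length(dup)), dup)
  al <- dtw_align(trajectory_pair(tx, ty))
  expect_equal(al$distance, 0)
})

test_that("r_dtw is affine-invariant and recovers smooth monotone warps", {
  tr <- wavy_trajectory()
  hop <- attr(tr, "hop_s")

  # affine invariance of the Pearson step under an identity warp
  x <- tr$nasalance_pct[tr$valid]
  identity_alignment <- list(reference_values = x,
                             aligned_candidate = 0.5 * x + 20)
  affine <- nasalance_trajectory(tr$time_s, 0.5 * tr$nasalance_pct + 20,
                                 hop_s = hop)
  expect_equal(dtw_correlation(trajectory_pair(tr, affine),
                               alignment = identity_alignment), 1,
               tolerance = 1e-9)

  warped <- apply_time_warp(tr, time_warp_sine(5, depth_s = 0.25, cycles = 1))
  expect_gte(dtw_correlation(trajectory_pair(tr, warped)), 0.99)
})

test_that("DTW alignment beats raw correlation on nonlinearly warped pairs", {
  for (seed in c(11, 12, 13)) {
    tr <- wavy_trajectory(seed = seed)
    warped <- apply_time_warp(tr, time_warp_sine(5, depth_s = 0.3, cycles = 2))
    res <- compare_trajectories(tr, warped)
    expect_gte(res$r_dtw, res$r_raw)
    expect_true(abs(res$r_raw) <= 1 && abs(res$r_dtw) <= 1)
  }
})

test_that("longer, wider-range trajectories yield higher r_dtw than short flat ones", {
  # long, high dynamic range
  long_tr <- wavy_trajectory(duration_s = 6, seed = 61)
  long_w <- apply_time_warp(long_tr, time_warp_sine(6, depth_s = 0.3, cycles = 2))
  r_long <- dtw_correlation(trajectory_pair(long_tr, long_w))

  # short, low variance (narrow profile) plus the same relative perturbation
  flat_sim <- generate_dual_recording(synth_config(
    duration_s = 2, sample_rate = 22050,
    nasalance_profile = function(t) 20 + 3 * sin(2 * pi * 0.4 * t),
    source_kind = "speech_like", noise_floor_dbfs = -35, seed = 62))
  flat_tr <- compute_trajectory(flat_sim$recording,
                                design_bandpass(200, 800, 2, 22050))
  flat_w <- apply_time_warp(flat_tr, time_warp_sine(2, depth_s = 0.1, cycles = 2))
  r_flat <- dtw_correlation(trajectory_pair(flat_tr, flat_w))
  expect_gt(r_long, r_flat)
})

test_that("degenerate agreement inputs are rejected", {
  tr <- wavy_trajectory(duration_s = 2)
  hop <- attr(tr, "hop_s")
  short <- nasalance_trajectory(c(0, hop), c(40, 60), hop_s = hop)
  expect_error(raw_cross_correlation(trajectory_pair(tr, short)),
               "overlapping valid frames")
  const <- nasalance_trajectory(tr$time_s, rep(50, nrow(tr)), hop_s = hop)
  expect_error(raw_cross_correlation(trajectory_pair(const, const)),
               "overlapping valid frames|variance")
  other_hop <- nasalance_trajectory(seq(0, 1, by = 0.05), rep(50, 21))
  expect_error(trajectory_pair(tr, other_hop), "hop")
})
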