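#' Pair two nasalance trajectories for agreement analysis
#'
#' Both trajectories must be computed on the same frame hop; only mutually
#' valid frames enter the correlations downstream. The reference plays the
#' role of the fixed time axis (e.g. the commercial device), the candidate
#' is aligned onto it.
#'
#' @param reference,candidate `nasalance_trajectory` objects with matching
#'   hop.
#' @return An object of class `trajectory_pair`.
#' @export
trajectory_pair <- function(reference, candidate) {
  stopifnot(inherits(reference, "nasalance_trajectory"),
            inherits(candidate, "nasalance_trajectory"))
  h1 <- attr(reference, "hop_s")
  h2 <- attr(candidate, "hop_s")
  if (is.na(h1) || is.na(h2) || abs(h1 - h2) > 1e-9 * max(h1, h2)) {
    stop("trajectories must share the same frame hop (",
         format(h1), " vs ", format(h2), " s)")
  }
  structure(list(reference = reference, candidate = candidate,
                 common_hop_s = h1),
            class = "trajectory_pair")
}

#' Maximum lagged cross-correlation between two trajectories
#'
#' For each integer-hop lag within `max_lag_s`, the candidate is shifted and
#' the Pearson correlation (means recomputed over the overlapping mutually
#' valid frames at that lag) is evaluated; the maximum over lags and the lag
#' achieving it are returned. Ties are broken toward the smaller absolute
#' lag. The reported `best_lag_s` is the time shift of the candidate
#' relative to the reference: a candidate that lags (starts later than) the
#' reference yields a negative `best_lag_s`.
#'
#' @param pair A [trajectory_pair()].
#' @param max_lag_s Half-width of the lag search window in seconds
#'   (default 0.5).
#' @param min_overlap Minimum overlapping valid frame count for a lag to be
#'   considered (default 10).
#' @return List with `r_raw` and `best_lag_s`.
#' @export
raw_cross_correlation <- function(pair, max_lag_s = 0.5, min_overlap = 10) {
  stopifnot(inherits(pair, "trajectory_pair"))
  hop <- pair$common_hop_s
  x <- pair$reference$nasalance_pct
  y <- pair$candidate$nasalance_pct
  vx <- pair$reference$valid
  vy <- pair$candidate$valid
  max_k <- floor(max_lag_s / hop + 1e-9)

  best_r <- -Inf
  best_k <- NA_integer_
  any_lag <- FALSE
  for (k in -max_k:max_k) {
    # compare x[t] with y[t + k]
    t_lo <- max(1L, 1L - k)
    t_hi <- min(length(x), length(y) - k)
    if (t_hi - t_lo + 1L < min_overlap) next
    t <- t_lo:t_hi
    keep <- vx[t] & vy[t + k]
    if (sum(keep) < min_overlap) next
    xs <- x[t][keep]
    ys <- y[t + k][keep]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) next
    any_lag <- TRUE
    r <- stats::cor(xs, ys)
    if (r > best_r + 1e-12 ||
        (abs(r - best_r) <= 1e-12 && abs(k) < abs(best_k))) {
      best_r <- r
      best_k <- k
    }
  }
  if (!any_lag) {
    stop("no lag with at least ", min_overlap,
         " overlapping valid frames and nonzero variance")
  }
  list(r_raw = best_r, best_lag_s = -best_k * hop)
}

# Classic DTW on the mutually compacted valid values: absolute-difference
# local cost, symmetric steps {(1,1),(1,0),(0,1)}, full boundary conditions.
# Diagonal preferred on ties so identical sequences align on the diagonal.
.dtw_path <- function(x, y) {
  n <- length(x)
  m <- length(y)
  if (n < 2 || m < 2) stop("degenerate trajectory: need at least 2 frames")
  cost <- abs(outer(x, y, "-"))
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    # the (0,1) step depends on the row being filled, so fill sequentially
    row_prev <- D[i, ]
    row_cur <- rep(Inf, m + 1)
    for (j in seq_len(m)) {
      row_cur[j + 1] <- cost[i, j] +
        min(row_prev[j], row_prev[j + 1], row_cur[j])
    }
    D[i + 1, ] <- row_cur
    D[i + 1, 1] <- Inf
  }
  # backtrack, preferring the diagonal on ties
  i <- n; j <- m
  path <- list(c(n, m))
  while (i > 1 || j > 1) {
    choices <- c(diag = if (i > 1 && j > 1) D[i, j] else Inf,
                 up   = if (i > 1) D[i, j + 1] else Inf,
                 left = if (j > 1) D[i + 1, j] else Inf)
    step <- names(choices)[which.min(choices)]
    if (step == "diag") { i <- i - 1; j <- j - 1 }
    else if (step == "up") i <- i - 1
    else j <- j - 1
    path[[length(path) + 1]] <- c(i, j)
  }
  path <- do.call(rbind, rev(path))
  storage.mode(path) <- "integer"
  colnames(path) <- c("reference", "candidate")
  list(path = path, distance = D[n + 1, m + 1])
}

#' Dynamic time warping alignment of a trajectory pair
#'
#' Classic DTW with absolute-difference local cost on the nasalance values,
#' symmetric step pattern `{(1,1),(1,0),(0,1)}` and full boundary
#' conditions. Invalid frames are dropped (compacted) before warping rather
#' than interpolated. The candidate is mapped onto the reference time axis:
#' each reference frame receives the mean of all candidate values matched to
#' it by the warping path.
#'
#' @param pair A [trajectory_pair()].
#' @return List with `warp_path` (two-column index matrix into the valid
#'   frames of each trajectory), `aligned_candidate` (candidate values on
#'   the reference's valid-frame axis), `reference_values`,
#'   `reference_times` and `distance` (total path cost).
#' @export
dtw_align <- function(pair) {
  stopifnot(inherits(pair, "trajectory_pair"))
  x <- pair$reference$nasalance_pct[pair$reference$valid]
  y <- pair$candidate$nasalance_pct[pair$candidate$valid]
  tx <- pair$reference$time_s[pair$reference$valid]
  if (length(x) == 0 || length(y) == 0) stop("empty trajectory after validity masking")
  res <- .dtw_path(x, y)
  aligned <- vapply(seq_along(x), function(i) {
    mean(y[res$path[res$path[, 1] == i, 2]])
  }, numeric(1))
  list(warp_path = res$path, aligned_candidate = aligned,
       reference_values = x, reference_times = tx,
       distance = res$distance)
}

#' Pearson correlation after DTW alignment
#'
#' @param pair A [trajectory_pair()].
#' @param alignment Optional precomputed result of [dtw_align()].
#' @return `r_dtw`, the Pearson correlation between the reference values and
#'   the aligned candidate.
#' @export
dtw_correlation <- function(pair, alignment = dtw_align(pair)) {
  x <- alignment$reference_values
  y <- alignment$aligned_candidate
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance after alignment: correlation undefined")
  }
  stats::cor(x, y)
}

#' Full agreement analysis between two trajectories
#'
#' Computes both the raw lagged cross-correlation (no warping; quantifies
#' agreement under a rigid time shift) and the DTW-aligned Pearson
#' correlation (agreement after compensating speaking-rate variability and
#' non-linear temporal misalignment).
#'
#' @param reference,candidate `nasalance_trajectory` objects on the same hop.
#' @param max_lag_s Lag window for the raw correlation (default 0.5 s).
#' @return An object of class `agreement_result`: list with `r_raw`,
#'   `best_lag_s`, `r_dtw`, `warp_path`, `aligned_candidate`,
#'   `n_reference_valid`, `n_candidate_valid`.
#' @export
compare_trajectories <- function(reference, candidate, max_lag_s = 0.5) {
  pair <- trajectory_pair(reference, candidate)
  raw <- raw_cross_correlation(pair, max_lag_s)
  al <- dtw_align(pair)
  structure(list(r_raw = raw$r_raw, best_lag_s = raw$best_lag_s,
                 r_dtw = dtw_correlation(pair, al),
                 warp_path = al$warp_path,
                 aligned_candidate = al$aligned_candidate,
                 n_reference_valid = sum(reference$valid),
                 n_candidate_valid = sum(candidate$valid)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> r_raw %.3f at lag %+.3f s; r_dtw %.3f\n",
              x$r_raw, x$best_lag_s, x$r_dtw))
  invisible(x)
}
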