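# Independent brute-force oracles and small fixture builders. These
# re-derive expected values from first principles, by enumeration or by
# directly solving the defining equations, and stay independent of the
# package's implementation paths.

make_series <- function(glucose, meal_idx = integer(), start_clock = 0L,
                        series_id = "S1", patient_id = "P1") {
  cgm_series(series_id = series_id, patient_id = patient_id,
             glucose = glucose, start_clock = start_clock,
             raw_meal_times = meal_idx)
}

# --- natural cubic spline, solved directly from the tridiagonal system -----
# x must be strictly increasing. Natural boundary: second derivative zero at
# both ends. Returns interpolated values at xout.
oracle_natural_spline <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  # solve for second derivatives m[1..n], m[1] = m[n] = 0
  m <- numeric(n)
  if (n > 2) {
    k <- n - 2L                      # interior unknowns m[2..n-1]
    A <- matrix(0, k, k)
    b <- numeric(k)
    for (i in seq_len(k)) {
      j <- i + 1L                    # index into x
      if (i > 1) A[i, i - 1L] <- h[j - 1L]
      A[i, i] <- 2 * (h[j - 1L] + h[j])
      if (i < k) A[i, i + 1L] <- h[j]
      b[i] <- 6 * ((y[j + 1L] - y[j]) / h[j] - (y[j] - y[j - 1L]) / h[j - 1L])
    }
    m[2:(n - 1L)] <- solve(A, b)
  }
  vapply(xout, function(xi) {
    if (xi <= x[1]) {                # linear extrapolation (natural spline)
      slope <- (y[2] - y[1]) / h[1] - h[1] * m[2] / 6
      return(y[1] + slope * (xi - x[1]))
    }
    if (xi >= x[n]) {
      slope <- (y[n] - y[n - 1L]) / h[n - 1L] + h[n - 1L] * m[n - 1L] / 6
      return(y[n] + slope * (xi - x[n]))
    }
    i <- findInterval(xi, x)
    dx1 <- xi - x[i]; dx2 <- x[i + 1L] - xi; hi <- h[i]
    m[i] * dx2^3 / (6 * hi) + m[i + 1L] * dx1^3 / (6 * hi) +
      (y[i] / hi - m[i] * hi / 6) * dx2 +
      (y[i + 1L] / hi - m[i + 1L] * hi / 6) * dx1
  }, 0)
}

# --- feature oracles: literal transcription of the definitions -------------
oracle_rig <- function(window, t) {
  w <- window[1:(t + 1)]
  if (anyNA(w)) return(NA_real_)
  peak <- 0L
  for (s in 0:t) if (w[s + 1] > w[peak + 1]) peak <- s   # smallest argmax
  if (peak == 0L) 0 else (w[peak + 1] - w[1]) / (5 * peak)
}

oracle_grc <- function(window, t) {
  (window[t + 1] - window[t]) / 5
}

oracle_label <- function(window, t, horizon = 6L, threshold = 70) {
  v <- window[t + horizon + 1]
  if (is.na(v)) NA_integer_ else as.integer(v < threshold)
}

# which prediction steps t in 1..W are emitted for a window (presence check
# by exhaustive scan)
oracle_emitted <- function(window, W = 42L, horizon = 6L) {
  L <- length(window)
  Filter(function(t) {
    t + horizon + 1 <= L &&
      !anyNA(window[1:(t + 1)]) &&
      !is.na(window[t + horizon + 1])
  }, seq_len(W))
}

# --- event/alarm oracles: exhaustive run/merge scans ------------------------
# maximal runs of >= min_len consecutive TRUE, as a two-column matrix of
# (start, end) indices
oracle_runs <- function(flag, min_len = 2L) {
  out <- NULL
  i <- 1L
  n <- length(flag)
  while (i <= n) {
    if (isTRUE(flag[i])) {
      j <- i
      while (j < n && isTRUE(flag[j + 1L])) j <- j + 1L
      if (j - i + 1L >= min_len) out <- rbind(out, c(i, j))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# merge runs whose intervening gap is <= merge_gap minutes (5 min per point)
oracle_merge <- function(runs, merge_gap = 10) {
  if (is.null(runs)) return(NULL)
  out <- runs[1, , drop = FALSE]
  for (r in seq_len(nrow(runs))[-1]) {
    gap_min <- (runs[r, 1] - out[nrow(out), 2] - 1) * 5
    if (gap_min <= merge_gap) {
      out[nrow(out), 2] <- runs[r, 2]
    } else {
      out <- rbind(out, runs[r, , drop = FALSE])
    }
  }
  out
}

# AUC as the rank statistic: P(score_pos > score_neg) + P(tie)/2 over all
# positive-negative pairs
oracle_rank_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# a small deterministic cohort for pipeline-level tests
small_cohort_config <- function(n_series = 20L, seed = 11L) {
  cohort_config(n_series = n_series, seed = seed)
}

single_point_grids <- function() {
  list(
    rf = data.frame(num_trees = 150L, max_depth = 0L),
    svm_ln = data.frame(C = 1),
    svm_rbf = data.frame(C = 1, gamma = 1),
    knn = data.frame(k = 15L),
    lr = data.frame(C = 1)
  )
}
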