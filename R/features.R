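#' Rate of increase in glucose (RIG) after a meal
#'
#' RIG at prediction step t is the rise from the meal-time glucose to the
#' running post-meal peak, divided by the time from meal to peak:
#' `(peak - window[0]) / (5 * peak_step)` in mg/dL per minute. The peak is the
#' smallest-index maximum of the window over steps 0..t, so RIG freezes once
#' the true peak has passed. When the running maximum is still the meal-time
#' point itself (no post-meal rise), RIG is 0 by convention, which also avoids
#' a zero time difference.
#'
#' @param window Numeric postprandial window as returned by
#'   [postprandial_window()] (element t + 1 is step t).
#' @param t Prediction step (>= 1).
#' @return A list with `rig` (mg/dL per minute), `peak_index` (step of the
#'   running maximum, 0-based), `peak_value` (mg/dL) and `td_meal_to_peak`
#'   (minutes). `rig` is `NA` when any of steps 0..t is missing.
#' @export
compute_rig <- function(window, t) {
  t <- as.integer(t)
  if (t < 1L || t + 1L > length(window)) {
    stop("prediction step t = ", t, " outside the window", call. = FALSE)
  }
  w <- window[seq_len(t + 1L)]
  if (anyNA(w)) {
    return(list(rig = NA_real_, peak_index = NA_integer_,
                peak_value = NA_real_, td_meal_to_peak = NA_real_))
  }
  peak_pos <- which.max(w)            # smallest index of the maximum
  peak_index <- peak_pos - 1L         # 0-based postprandial step
  peak_value <- w[peak_pos]
  rig <- if (peak_index == 0L) 0 else (peak_value - w[1L]) / (5 * peak_index)
  list(rig = rig, peak_index = peak_index, peak_value = peak_value,
       td_meal_to_peak = 5 * peak_index)
}

#' Glucose rate of change (GRC) at a prediction step
#'
#' First difference of the window at step t divided by the 5-minute sampling
#' interval: `(window[t] - window[t - 1]) / 5` in mg/dL per minute. At t = 1
#' the left operand is the meal-time point.
#'
#' @inheritParams compute_rig
#' @return GRC in mg/dL per minute, or `NA` when either operand is missing.
#' @export
compute_grc <- function(window, t) {
  t <- as.integer(t)
  if (t < 1L || t + 1L > length(window)) {
    stop("prediction step t = ", t, " outside the window", call. = FALSE)
  }
  (window[t + 1L] - window[t]) / 5
}

#' Hypoglycemia label at the prediction horizon
#'
#' The label at step t is 1 iff the glucose at step `t + horizon` is strictly
#' below the alert threshold (70 mg/dL, i.e. 3.9 mmol/L, by default); the
#' default horizon of 6 steps is a 30-minute prediction horizon.
#'
#' @inheritParams compute_rig
#' @param horizon Prediction horizon in grid steps (default 6 = 30 min).
#' @param threshold Hypoglycemia alert threshold in mg/dL (default 70).
#' @return 0/1, or `NA` when the horizon point is missing or beyond the
#'   window.
#' @export
compute_label <- function(window, t, horizon = 6L, threshold = 70) {
  t <- as.integer(t)
  target <- t + as.integer(horizon) + 1L
  if (t < 1L || target > length(window)) {
    return(NA_integer_)
  }
  v <- window[target]
  if (is.na(v)) return(NA_integer_)
  as.integer(v < threshold)
}

#' Build the (CGM, RIG, GRC, label) sample set from preprocessed series
#'
#' For every series, filtered meal announcement and prediction step
#' t = 1..W, a sample is emitted iff all points it needs are present: steps
#' 0..t (for the running-peak RIG, which also covers the GRC operands) and
#' step `t + horizon` (for the label). Samples whose required points are
#' missing or beyond the series end are skipped silently and counted in the
#' attached skip log.
#'
#' @param series_list List of preprocessed (gap-filled) [cgm_series()].
#' @param meals Data.frame of filtered meal announcements
#'   (`series_id`, `meal_index`, `grid_index`) as returned by
#'   [filter_meal_announcements()]; computed from each series when `NULL`.
#' @param W Number of prediction steps per meal (default 42).
#' @param horizon Prediction horizon in steps (default 6).
#' @param threshold Alert threshold in mg/dL (default 70).
#' @return A data.frame with columns `series_id`, `meal_index`, `t`, `cgm`,
#'   `rig`, `grc`, `label`, ordered by (series, meal, t), with attribute
#'   `skip_log` = c(n_emitted, n_skipped_missing, n_skipped_short).
#' @export
build_dataset <- function(series_list, meals = NULL, W = 42L, horizon = 6L,
                          threshold = 70) {
  if (is.null(meals)) {
    meals <- do.call(rbind, lapply(series_list, filter_meal_announcements))
  }
  names(series_list) <- vapply(series_list, function(s) s$series_id, "")
  out <- vector("list", nrow(meals))
  n_missing <- 0L
  n_short <- 0L
  for (r in seq_len(nrow(meals))) {
    s <- series_list[[meals$series_id[r]]]
    gi <- meals$grid_index[r]
    if (gi >= length(s$glucose)) {
      n_short <- n_short + W
      next
    }
    w <- postprandial_window(s, gi, W = W + horizon)
    L <- length(w)
    tmax <- min(W, L - 1L - horizon)
    n_short <- n_short + (W - max(tmax, 0L))
    if (tmax < 1L) next
    na_before <- cumsum(is.na(w))   # number of missing points in steps 0..k-1
    rows <- vector("list", tmax)
    run_peak_idx <- 0L
    run_peak_val <- w[1L]
    for (t in seq_len(tmax)) {
      if (!is.na(w[t + 1L]) &&
          (is.na(run_peak_val) || w[t + 1L] > run_peak_val)) {
        run_peak_val <- w[t + 1L]
        run_peak_idx <- t
      }
      if (na_before[t + 1L] > 0L || is.na(w[t + 1L]) ||
          is.na(w[t + horizon + 1L])) {
        n_missing <- n_missing + 1L
        next
      }
      rig <- if (run_peak_idx == 0L) 0 else
        (run_peak_val - w[1L]) / (5 * run_peak_idx)
      rows[[t]] <- data.frame(
        series_id = meals$series_id[r],
        meal_index = meals$meal_index[r],
        t = t,
        cgm = w[t + 1L],
        rig = rig,
        grc = (w[t + 1L] - w[t]) / 5,
        label = as.integer(w[t + horizon + 1L] < threshold),
        stringsAsFactors = FALSE
      )
    }
    out[[r]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(series_id = character(), meal_index = integer(),
                      t = integer(), cgm = numeric(), rig = numeric(),
                      grc = numeric(), label = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  attr(res, "skip_log") <- c(n_emitted = nrow(res),
                             n_skipped_missing = n_missing,
                             n_skipped_short = n_short)
  res
}

#' Min-max feature scaler
#'
#' `fit_scaler()` learns per-feature minima and maxima from a training set;
#' `apply_scaler()` maps each feature by `(x - min) / (max - min)`. Values of
#' a test set outside the training range map outside \[0, 1\] (no clipping);
#' a degenerate feature (max equal to min in training) maps to 0.
#'
#' @param samples Data.frame of feature samples.
#' @param features Character vector of feature column names.
#' @return `fit_scaler()`: an object of class `scaler_params` with fields
#'   `min`, `max` and `features`. `apply_scaler()`: `samples` with the feature
#'   columns rescaled.
#' @export
fit_scaler <- function(samples, features = c("cgm", "rig", "grc")) {
  if (nrow(samples) == 0L) stop("cannot fit a scaler on an empty set", call. = FALSE)
  stopifnot(all(features %in% names(samples)))
  structure(
    list(
      min = vapply(features, function(f) min(samples[[f]]), 0),
      max = vapply(features, function(f) max(samples[[f]]), 0),
      features = features
    ),
    class = "scaler_params"
  )
}

#' @rdname fit_scaler
#' @param params A `scaler_params` object from [fit_scaler()].
#' @export
apply_scaler <- function(params, samples) {
  stopifnot(inherits(params, "scaler_params"))
  for (f in params$features) {
    rng <- params$max[[f]] - params$min[[f]]
    samples[[f]] <- if (rng == 0) {
      rep(0, nrow(samples))
    } else {
      (samples[[f]] - params$min[[f]]) / rng
    }
  }
  samples
}
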