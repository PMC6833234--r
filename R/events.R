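#' Extract postprandial hypoglycemic events from a CGM trace
#'
#' An event is a maximal run of at least two consecutive readings below the
#' alert threshold (70 mg/dL); runs separated by at most `merge_gap` minutes
#' are merged into one event. Events are kept when their start lies in the
#' postprandial interval `(meal + 5, meal + 240]` minutes of some filtered
#' meal announcement, and are assigned to the latest such meal. An event is
#' flagged `severe` when any constituent reading is below 54 mg/dL
#' (3.0 mmol/L), and `excluded_immediate` when it starts within 10 minutes of
#' its meal — too early for two prior prediction steps, so such events are
#' counted but not scored as alarmed or missed.
#'
#' @param series A preprocessed [cgm_series()].
#' @param meals Data.frame of filtered meal announcements for the series
#'   ([filter_meal_announcements()] output).
#' @param alert,severe Alert and severity thresholds in mg/dL.
#' @param merge_gap Maximal gap (minutes) between runs merged into one event.
#' @param pp_start,pp_end Postprandial interval bounds in minutes after the
#'   meal (start exclusive, end inclusive).
#' @param immediate_cutoff Events starting at most this many minutes after
#'   their meal are flagged `excluded_immediate`.
#' @return A data.frame with columns `series_id`, `meal_index`,
#'   `start_minute`, `end_minute`, `min_glucose`, `severe`,
#'   `excluded_immediate` (minutes are series time, `5 * (grid_index - 1)`).
#' @export
extract_hypo_events <- function(series, meals, alert = 70, severe = 54,
                                merge_gap = 10, pp_start = 5, pp_end = 240,
                                immediate_cutoff = 10) {
  g <- series$glucose
  hypo <- !is.na(g) & g < alert
  runs <- hypo_runs(hypo, min_len = 2L)
  merged <- merge_runs(runs, merge_gap = merge_gap)

  empty <- data.frame(series_id = character(), meal_index = integer(),
                      start_minute = numeric(), end_minute = numeric(),
                      min_glucose = numeric(), severe = logical(),
                      excluded_immediate = logical(), stringsAsFactors = FALSE)
  if (!length(merged) || nrow(meals) == 0L) return(empty)

  meal_min <- 5 * (meals$grid_index - 1)
  rows <- lapply(merged, function(r) {
    start_min <- 5 * (r[1] - 1)
    end_min <- 5 * (r[2] - 1)
    containing <- which(start_min > meal_min + pp_start &
                        start_min <= meal_min + pp_end)
    if (!length(containing)) return(NULL)
    m <- containing[which.max(meal_min[containing])]  # latest containing meal
    data.frame(
      series_id = series$series_id,
      meal_index = meals$meal_index[m],
      start_minute = start_min,
      end_minute = end_min,
      min_glucose = min(g[r[1]:r[2]], na.rm = TRUE),
      severe = min(g[r[1]:r[2]], na.rm = TRUE) < severe,
      excluded_immediate = start_min <= meal_min[m] + immediate_cutoff,
      stringsAsFactors = FALSE
    )
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Maximal runs of TRUE of length >= min_len, as a list of c(start, end)
# (1-based grid indices).
hypo_runs <- function(flag, min_len = 2L) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  Map(c, starts[keep], ends[keep])
}

# Merge runs whose gap (minutes between the end of one and the start of the
# next, i.e. 5 * number of intervening points) is <= merge_gap.
merge_runs <- function(runs, merge_gap = 10) {
  merged <- list()
  for (r in runs) {
    last <- if (length(merged)) merged[[length(merged)]] else NULL
    if (!is.null(last) && (r[1] - last[2] - 1L) * 5 <= merge_gap) {
      merged[[length(merged)]] <- c(last[1], r[2])
    } else {
      merged[[length(merged) + 1L]] <- r
    }
  }
  merged
}

#' Detect alarms in a per-meal prediction sequence
#'
#' An alarm is a maximal run of at least two consecutive positive hard
#' predictions at adjacent prediction steps; it is stamped at the run's first
#' step (minute `5 * t_first` post-meal, converted to series time). Runs lying
#' wholly inside an ongoing hypoglycemic event are discarded — alarms within
#' events are not counted.
#'
#' @param predictions 0/1 vector of hard predictions at steps t = 1, 2, ...;
#'   `NA` (no emitted sample at that step) is treated as 0.
#' @param meal_grid_index 1-based grid index of the meal in its series.
#' @param series_id Series identifier stamped on the alarms.
#' @param meal_index Meal index stamped on the alarms.
#' @param events Optional event data.frame for the same series
#'   ([extract_hypo_events()] output) used to discard in-event runs.
#' @param min_run Minimal run length that raises an alarm (default 2).
#' @return A data.frame with columns `series_id`, `meal_index`,
#'   `alarm_minute` (series time), `t_first`, `run_length`.
#' @export
detect_alarms <- function(predictions, meal_grid_index, series_id = "S1",
                          meal_index = 1L, events = NULL, min_run = 2L) {
  pred <- !is.na(predictions) & predictions == 1
  runs <- hypo_runs(pred, min_len = min_run)   # indices here are steps t
  meal_minute <- 5 * (meal_grid_index - 1)
  rows <- lapply(runs, function(r) {
    t_first <- r[1]
    minutes <- meal_minute + 5 * (r[1]:r[2])
    if (!is.null(events) && nrow(events) > 0L) {
      inside <- any(minutes[1] >= events$start_minute &
                    minutes[length(minutes)] <= events$end_minute)
      if (inside) return(NULL)
    }
    data.frame(series_id = series_id, meal_index = meal_index,
               alarm_minute = minutes[1], t_first = t_first,
               run_length = r[2] - r[1] + 1L, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(series_id = character(), meal_index = integer(),
                      alarm_minute = numeric(), t_first = integer(),
                      run_length = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Match alarms to hypoglycemic events
#'
#' A (non-excluded) event is true-alarmed iff at least one alarm of the same
#' series fires in the 60 minutes before its start, `[start - 60, start)`;
#' the earliest such alarm defines the detection time
#' `DT = start - alarm_minute` (minutes, in (0, 60] by construction). An alarm
#' that precedes no event start within the following 60 minutes,
#' `(alarm, alarm + 60]`, counts as a false alarm (FP_e); events flagged
#' `excluded_immediate` still shield their alarms from being false but are not
#' scored as alarmed or missed. The false alarm rate is
#' `FAR = FP_e / (TP_e + FP_e)`, `NA` when no alarm fired.
#'
#' @param alarms Alarm data.frame ([detect_alarms()] output, possibly
#'   row-bound over meals/series).
#' @param events Event data.frame ([extract_hypo_events()] output, same
#'   series frame).
#' @param horizon_min Matching window in minutes (default 60).
#' @return A list with `metrics` (named `NH`, `TP_e`, `FP_e`, `FAR`, `DT`,
#'   `severe_alarmed`, `severe_missed`), `events` (input plus `alarmed` and
#'   `dt` columns) and `alarms` (input plus `false_alarm` column).
#' @export
match_alarms_events <- function(alarms, events, horizon_min = 60) {
  ev <- events
  ev$alarmed <- logical(nrow(ev))
  ev$dt <- rep(NA_real_, nrow(ev))
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      cand <- alarms$series_id == ev$series_id[i] &
        alarms$alarm_minute >= ev$start_minute[i] - horizon_min &
        alarms$alarm_minute < ev$start_minute[i]
      if (any(cand)) {
        ev$alarmed[i] <- TRUE
        ev$dt[i] <- ev$start_minute[i] - min(alarms$alarm_minute[cand])
      }
    }
  }
  al <- alarms
  al$false_alarm <- logical(nrow(al))
  if (nrow(al)) {
    for (a in seq_len(nrow(al))) {
      matched <- nrow(ev) > 0L && any(
        ev$series_id == al$series_id[a] &
          ev$start_minute > al$alarm_minute[a] &
          ev$start_minute <= al$alarm_minute[a] + horizon_min
      )
      al$false_alarm[a] <- !matched
    }
  }
  eligible <- ev[!ev$excluded_immediate, , drop = FALSE]
  tp_e <- sum(eligible$alarmed)
  fp_e <- sum(al$false_alarm)
  far <- if (tp_e + fp_e > 0) fp_e / (tp_e + fp_e) else NA_real_
  dts <- eligible$dt[eligible$alarmed]
  list(
    metrics = c(
      NH = nrow(ev), TP_e = tp_e, FP_e = fp_e, FAR = far,
      DT = if (length(dts)) mean(dts) else NA_real_,
      severe_alarmed = sum(eligible$severe & eligible$alarmed),
      severe_missed = sum(eligible$severe & !eligible$alarmed)
    ),
    events = ev,
    alarms = al
  )
}

#' Severe-event alarm accounting
#'
#' Partitions the clinically significant events (at least one reading below
#' 54 mg/dL, excluding immediate-post-meal events) of a matched result into
#' alarmed and missed.
#'
#' @param matched Result of [match_alarms_events()].
#' @return Named vector `c(alarmed, missed)`.
#' @export
severe_event_stats <- function(matched) {
  ev <- matched$events
  eligible <- ev[!ev$excluded_immediate & ev$severe, , drop = FALSE]
  c(alarmed = sum(eligible$alarmed), missed = sum(!eligible$alarmed))
}

#' Fraction of false alarms followed by a near-hypoglycemic excursion
#'
#' A false alarm is counted as near-hypo-related when its series contains a
#' run of at least two consecutive readings at or below 80 mg/dL
#' (4.4 mmol/L) starting within the 60 minutes after the alarm,
#' `(alarm, alarm + 60]`.
#'
#' @param matched Result of [match_alarms_events()].
#' @param series_list List of the evaluated [cgm_series()].
#' @param near Near-hypoglycemia threshold in mg/dL (default 80, inclusive).
#' @param horizon_min Look-ahead window in minutes (default 60).
#' @return Fraction in \[0, 1\], or `NA` when there are no false alarms.
#' @export
near_hypo_false_alarm_fraction <- function(matched, series_list, near = 80,
                                           horizon_min = 60) {
  fa <- matched$alarms[matched$alarms$false_alarm, , drop = FALSE]
  if (nrow(fa) == 0L) return(NA_real_)
  names(series_list) <- vapply(series_list, function(s) s$series_id, "")
  near_starts <- lapply(series_list, function(s) {
    flag <- !is.na(s$glucose) & s$glucose <= near
    runs <- hypo_runs(flag, min_len = 2L)
    vapply(runs, function(r) 5 * (r[1] - 1), 0)
  })
  hits <- vapply(seq_len(nrow(fa)), function(a) {
    starts <- near_starts[[fa$series_id[a]]]
    any(starts > fa$alarm_minute[a] &
          starts <= fa$alarm_minute[a] + horizon_min)
  }, TRUE)
  mean(hits)
}
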