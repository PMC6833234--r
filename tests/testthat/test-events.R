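# build a daytime series with one meal at grid index `meal` and the given
# glucose values pasted in starting at `at`
series_with <- function(values, at, n = 288, meal = 97L, base = 120) {
  g <- rep(base, n)
  g[at:(at + length(values) - 1L)] <- values
  make_series(g, meal_idx = meal)
}

meals_of <- function(s) filter_meal_announcements(s)

test_that("events need two consecutive alert values and merge across <=10 min", {
  meal <- 97L  # 08:00 for a midnight start

  # a lone sub-70 point is not an event
  s <- series_with(65, at = meal + 12)
  expect_equal(nrow(extract_hypo_events(s, meals_of(s))), 0L)

  # two runs separated by one in-range point (5-min gap) merge
  s <- series_with(c(65, 66, 75, 64, 63), at = meal + 12)
  ev <- extract_hypo_events(s, meals_of(s))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_minute, 5 * (meal + 12 - 1))
  expect_equal(ev$end_minute, 5 * (meal + 16 - 1))

  # gap of exactly 10 min (two intervening points) still merges
  s <- series_with(c(65, 66, 75, 76, 64, 63), at = meal + 12)
  expect_equal(nrow(extract_hypo_events(s, meals_of(s))), 1L)

  # 15-min separation yields two events
  s <- series_with(c(65, 66, 75, 76, 77, 64, 63), at = meal + 12)
  expect_equal(nrow(extract_hypo_events(s, meals_of(s))), 2L)
})

test_that("events are confined to the postprandial interval and flagged", {
  meal <- 97L
  # starts 5 min after the meal: outside the (meal+5, meal+240] interval? The
  # interval is open at meal+5, so a start at exactly +5 min is dropped
  s <- series_with(c(65, 65), at = meal + 1)
  expect_equal(nrow(extract_hypo_events(s, meals_of(s))), 0L)

  # start at +10 min is inside but excluded as immediately postprandial
  s <- series_with(c(65, 65), at = meal + 2)
  ev <- extract_hypo_events(s, meals_of(s))
  expect_equal(nrow(ev), 1L)
  expect_true(ev$excluded_immediate)

  # start at +15 min is scored normally
  s <- series_with(c(65, 65), at = meal + 3)
  ev <- extract_hypo_events(s, meals_of(s))
  expect_false(ev$excluded_immediate)
  expect_false(ev$severe)

  # severe flag when any constituent point < 54
  s <- series_with(c(65, 53, 65), at = meal + 12)
  expect_true(extract_hypo_events(s, meals_of(s))$severe)

  # start beyond meal + 240 min (48 steps) is not postprandial
  s <- series_with(c(65, 65), at = meal + 50)
  expect_equal(nrow(extract_hypo_events(s, meals_of(s))), 0L)

  # nocturnal dip with no meal context is ignored
  s <- series_with(c(65, 65), at = 10L)
  expect_equal(nrow(extract_hypo_events(s, meals_of(s))), 0L)
})

test_that("events spanning two meals' windows attach to the latest meal", {
  g <- rep(120, 288)
  m1 <- 97L            # 08:00
  m2 <- 123L           # 10:10, 130 min later so both survive merging
  g[(m2 + 12):(m2 + 14)] <- 60     # 60 min after m2, 190 min after m1
  s <- make_series(g, meal_idx = c(m1, m2))
  ev <- extract_hypo_events(s, meals_of(s))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$meal_index, 2L)
})

test_that("alarm detection applies the two-consecutive rule per maximal run", {
  a <- detect_alarms(c(0, 1, 1, 0), meal_grid_index = 97L)
  expect_equal(nrow(a), 1L)
  expect_equal(a$t_first, 2L)
  expect_equal(a$alarm_minute, 5 * (97 - 1) + 10)

  expect_equal(nrow(detect_alarms(c(0, 1, 0, 1, 0), 97L)), 0L)
  a <- detect_alarms(c(1, 1, 1, 1), 97L)
  expect_equal(nrow(a), 1L)
  expect_equal(a$run_length, 4L)
  expect_equal(nrow(detect_alarms(c(NA, 1, NA, 1, 1), 97L)), 1L)

  # runs wholly inside an ongoing event are not alarms
  ev <- data.frame(series_id = "S1", meal_index = 1L,
                   start_minute = 5 * 96 + 10, end_minute = 5 * 96 + 40,
                   min_glucose = 60, severe = FALSE,
                   excluded_immediate = FALSE)
  a <- detect_alarms(c(0, 1, 1, 0, 0, 0, 0, 0, 0, 1, 1), 97L, events = ev)
  expect_equal(nrow(a), 1L)                     # the in-event run is dropped
  expect_equal(a$t_first, 10L)
})

test_that("alarm/event matching implements the 60-min window calculus", {
  ev <- function(start, excluded = FALSE, severe = FALSE) {
    data.frame(series_id = "S1", meal_index = 1L, start_minute = start,
               end_minute = start + 20, min_glucose = if (severe) 50 else 60,
               severe = severe, excluded_immediate = excluded)
  }
  al <- function(minute) {
    data.frame(series_id = "S1", meal_index = 1L, alarm_minute = minute,
               t_first = 1L, run_length = 2L)
  }

  # alarm 30 min ahead: one true alarm, DT = 30
  m <- match_alarms_events(al(570), ev(600))
  expect_equal(unname(m$metrics[c("TP_e", "FP_e", "FAR", "DT")]),
               c(1, 0, 0, 30))

  # alarm 70 min ahead: event missed AND alarm false
  m <- match_alarms_events(al(530), ev(600))
  expect_equal(unname(m$metrics[["TP_e"]]), 0)
  expect_equal(unname(m$metrics[["FP_e"]]), 1)
  expect_equal(unname(m$metrics[["FAR"]]), 1)

  # 3 matched + 1 unmatched alarm: FAR = 0.25
  alarms <- do.call(rbind, lapply(c(570, 1000, 1430, 2000), al))
  events <- do.call(rbind, lapply(c(600, 1030, 1460), ev))
  m <- match_alarms_events(alarms, events)
  expect_equal(unname(m$metrics[["TP_e"]]), 3)
  expect_equal(unname(m$metrics[["FP_e"]]), 1)
  expect_equal(unname(m$metrics[["FAR"]]), 0.25)

  # earliest alarm in the window defines DT
  m <- match_alarms_events(rbind(al(550), al(580)), ev(600))
  expect_equal(unname(m$metrics[["DT"]]), 50)
  expect_equal(unname(m$metrics[["TP_e"]]), 1)

  # immediate-post-meal events count in NH but not in TP_e / severe strata,
  # yet still shield their alarm from being false
  m <- match_alarms_events(al(570), ev(600, excluded = TRUE))
  expect_equal(unname(m$metrics[["NH"]]), 1)
  expect_equal(unname(m$metrics[["TP_e"]]), 0)
  expect_equal(unname(m$metrics[["FP_e"]]), 0)

  # no alarms at all: FAR and DT undefined
  m <- match_alarms_events(alarms[0, ], ev(600))
  expect_true(is.na(m$metrics[["FAR"]]))
  expect_true(is.na(m$metrics[["DT"]]))

  # severe partition
  m <- match_alarms_events(al(570), rbind(ev(600, severe = TRUE),
                                          ev(2000, severe = TRUE)))
  expect_equal(unname(severe_event_stats(m)), c(1, 1))
  m <- match_alarms_events(al(570), ev(600))
  expect_equal(unname(severe_event_stats(m)), c(0, 0))
})

test_that("near-hypo accounting considers only false alarms and <=80 runs", {
  meal <- 97L
  base_minute <- 5 * (meal - 1)

  # false alarm followed 20 min later by two consecutive 78s: counted
  s <- series_with(c(78, 78), at = meal + 10)
  alarms <- data.frame(series_id = "S1", meal_index = 1L,
                       alarm_minute = base_minute + 30, t_first = 6L,
                       run_length = 2L)
  m <- match_alarms_events(alarms, extract_hypo_events(s, meals_of(s)))
  expect_equal(unname(m$metrics[["FP_e"]]), 1)
  expect_equal(near_hypo_false_alarm_fraction(m, list(s)), 1)

  # a single 78 does not qualify
  s1 <- series_with(78, at = meal + 10)
  m1 <- match_alarms_events(alarms, extract_hypo_events(s1, meals_of(s1)))
  expect_equal(near_hypo_false_alarm_fraction(m1, list(s1)), 0)

  # no false alarms -> undefined
  m0 <- match_alarms_events(alarms[0, ], extract_hypo_events(s, meals_of(s)))
  expect_true(is.na(near_hypo_false_alarm_fraction(m0, list(s))))
})

test_that("run extraction and alarms match exhaustive oracles on random traces", {
  set.seed(801)
  for (i in 1:200) {
    n <- sample(10:40, 1)
    flag <- runif(n) < 0.35

    runs <- oracle_runs(flag, min_len = 2L)
    merged <- oracle_merge(runs, merge_gap = 10)

    # alarms: same run rule on a prediction vector with no event masking
    a <- detect_alarms(as.integer(flag), meal_grid_index = 1L)
    if (is.null(runs)) {
      expect_equal(nrow(a), 0L)
    } else {
      expect_equal(a$t_first, unname(runs[, 1]))
      expect_equal(a$run_length, unname(runs[, 2] - runs[, 1] + 1L))
    }

    # events: embed the flags as glucose (65 = alert, 120 = normal) shortly
    # after a daytime meal so every run start is postprandial
    g <- c(rep(120, 100), ifelse(flag, 65, 120), rep(120, 4))
    s <- make_series(g, meal_idx = 98L)       # 08:05, flags start +15 min
    ev <- extract_hypo_events(s, meals_of(s))
    if (is.null(merged)) {
      expect_equal(nrow(ev), 0L)
    } else {
      expect_equal(ev$start_minute, 5 * (merged[, 1] + 100 - 1))
      expect_equal(ev$end_minute, 5 * (merged[, 2] + 100 - 1))
    }
  }
})
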