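#' Meal-response scenario
#'
#' A `meal_scenario` parameterizes the noiseless glucose response to one meal
#' as one of four postprandial archetypes observed in CGM traces around
#' mealtimes: `NO_PEAK` (little or no post-meal rise), `LOW_PEAK_FALL` (small
#' peak then fall), `STEEP_PEAK_FALL` (large fast peak then rapid fall, as
#' after a high-glycemic-index meal or late rapid-acting insulin) and
#' `IOB_FALL` (a fall with no peak, driven by insulin on board).
#'
#' The response is `baseline + amplitude * (tau/tp) * exp(1 - tau/tp) -
#' insulin_drop * (1 - 2^(-tau/decay_halflife))` at `tau` minutes post-meal
#' (`tp` = `time_to_peak`), floored at 40 mg/dL. The gamma-shaped rise has its
#' maximum `amplitude` exactly at `tau = tp`; the insulin term saturates at
#' `insulin_drop` with the stated half-life.
#'
#' @param pattern One of `"NO_PEAK"`, `"LOW_PEAK_FALL"`, `"STEEP_PEAK_FALL"`,
#'   `"IOB_FALL"`.
#' @param baseline Pre-meal glucose in mg/dL.
#' @param amplitude Height of the meal rise in mg/dL (about 0 for `NO_PEAK`).
#' @param time_to_peak Minutes from meal to the rise maximum.
#' @param decay_halflife Half-life of the insulin-action build-up in minutes.
#' @param insulin_drop Saturating glucose drop in mg/dL (must exceed
#'   `amplitude` for `IOB_FALL`).
#' @param hypo_probability Probability that a meal drawn from this scenario
#'   plants a hypoglycemic excursion.
#' @return An object of class `meal_scenario`.
#' @export
meal_scenario <- function(pattern, baseline, amplitude, time_to_peak,
                          decay_halflife, insulin_drop,
                          hypo_probability = 0) {
  pattern <- match.arg(pattern, c("NO_PEAK", "LOW_PEAK_FALL",
                                  "STEEP_PEAK_FALL", "IOB_FALL"))
  stopifnot(amplitude >= 0, time_to_peak > 0, decay_halflife > 0,
            insulin_drop >= 0,
            hypo_probability >= 0, hypo_probability <= 1)
  if (pattern == "NO_PEAK" && amplitude > 15) {
    stop("NO_PEAK scenarios must have near-zero amplitude", call. = FALSE)
  }
  if (pattern == "IOB_FALL" && insulin_drop <= amplitude) {
    stop("IOB_FALL scenarios require insulin_drop > amplitude", call. = FALSE)
  }
  structure(
    list(pattern = pattern, baseline = baseline, amplitude = amplitude,
         time_to_peak = time_to_peak, decay_halflife = decay_halflife,
         insulin_drop = insulin_drop, hypo_probability = hypo_probability),
    class = "meal_scenario"
  )
}

#' Noiseless glucose curve after one meal
#'
#' Evaluates the scenario's response on the 5-minute grid from the meal
#' (`tau = 0`) to `duration` minutes, floored at 40 mg/dL.
#'
#' @param scenario A [meal_scenario()].
#' @param duration Length of the curve in minutes (>= 240).
#' @return Numeric glucose vector of length `duration / 5 + 1`.
#' @export
simulate_meal_response <- function(scenario, duration = 300) {
  stopifnot(inherits(scenario, "meal_scenario"), duration >= 240)
  tau <- seq(0, duration, by = 5)
  pmax(scenario$baseline + meal_contribution(scenario, tau, taper = FALSE), 40)
}

# Deviation of the response from baseline at tau minutes post-meal. With
# taper = TRUE the contribution ramps back to zero between 270 and 330 min
# (meal effects in assembled series wear off rather than persisting all day);
# simulate_meal_response() reports the untapered form.
meal_contribution <- function(scenario, tau, taper = TRUE) {
  tp <- scenario$time_to_peak
  rise <- scenario$amplitude * (tau / tp) * exp(1 - tau / tp)
  drop <- scenario$insulin_drop * (1 - 2^(-tau / scenario$decay_halflife))
  contrib <- rise - drop
  if (taper) {
    fac <- pmin(pmax((330 - tau) / 60, 0), 1)
    contrib <- contrib * fac
  }
  contrib
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' 5-minute sampling over 3 days per series, 3 daytime meals per day
#' (around 08:00, 13:00 and 19:00), mildly autocorrelated sensor noise of a
#' retrospectively smoothed CGM, occasional missing points, and a scenario
#' mixture calibrated so that roughly a tenth of all points are below
#' 70 mg/dL and negative samples outnumber positive ones by an order of
#' magnitude.
#'
#' @param n_series Number of CGM series in the cohort.
#' @param days Days per series (series span `days * 24` h).
#' @param meals_per_day Daytime meals per day (3 supported: 08:00/13:00/19:00).
#' @param weights Mixture weights of the four archetypes, in the order
#'   NO_PEAK, LOW_PEAK_FALL, STEEP_PEAK_FALL, IOB_FALL; must sum to 1.
#' @param noise_sd Stationary standard deviation of the AR(1) sensor noise in
#'   mg/dL.
#' @param ar_coefficient AR(1) coefficient in \[0, 1).
#' @param missing_rate Independent per-point deletion probability.
#' @param hypo_probability Optional single value overriding every archetype's
#'   planting probability (e.g. 0 for an event-free cohort); `NULL` keeps the
#'   per-archetype defaults.
#' @param seed Integer seed making the cohort reproducible.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_series = 100L, days = 3L, meals_per_day = 3L,
                          weights = c(0.25, 0.25, 0.25, 0.25),
                          noise_sd = 5, ar_coefficient = 0.7,
                          missing_rate = 0.01, hypo_probability = NULL,
                          seed = 1L) {
  stopifnot(n_series >= 0, days >= 1, meals_per_day == 3L,
            length(weights) == 4L, abs(sum(weights) - 1) < 1e-8,
            noise_sd >= 0, ar_coefficient >= 0, ar_coefficient < 1,
            missing_rate >= 0, missing_rate < 1)
  structure(
    list(n_series = as.integer(n_series), days = as.integer(days),
         meals_per_day = 3L, weights = weights, noise_sd = noise_sd,
         ar_coefficient = ar_coefficient, missing_rate = missing_rate,
         hypo_probability = hypo_probability, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Archetype shape templates: rise amplitude, time to peak, insulin half-life
# and the default probability that a meal of this archetype plants a
# hypoglycemic excursion. Steep-peak and insulin-on-board meals are the
# hypoglycemia-prone patterns.
pattern_templates <- function() {
  list(
    NO_PEAK         = list(amplitude = 5,   tp = 30, hl = 70, hypo = 0.15),
    LOW_PEAK_FALL   = list(amplitude = 45,  tp = 40, hl = 70, hypo = 0.20),
    STEEP_PEAK_FALL = list(amplitude = 120, tp = 30, hl = 50, hypo = 0.35),
    IOB_FALL        = list(amplitude = 8,   tp = 25, hl = 45, hypo = 0.40)
  )
}

#' Simulate one synthetic CGM series
#'
#' Places jittered meals at about 08:00, 13:00 and 19:00 on each day, draws an
#' archetype for each meal from the configured mixture, sums the (possibly
#' overlapping) meal contributions on a per-series baseline, adds AR(1)
#' sensor noise, rounds to 1 mg/dL, and deletes points independently at the
#' configured missing rate. Meals that plant a hypoglycemic excursion (drawn
#' with the archetype's planting probability) have their insulin drop sized so
#' the noiseless curve reaches a nadir of 48-62 mg/dL; other meals stay above
#' about 85 mg/dL. Ground truth is defined on the noiseless curve so that
#' label noise is attributable to the sensor model.
#'
#' Consumes the current RNG stream; seed management is done by
#' [simulate_cohort()].
#'
#' @param config A [cohort_config()].
#' @param series_id,patient_id Identifiers for the generated series.
#' @return A list with `series` (a [cgm_series()] whose `raw_meal_times`
#'   include occasional nocturnal and duplicate announcements), `noiseless`
#'   (numeric vector), `meal_grid` (grid indices of the true meals) and
#'   `truth` (data.frame of planted events: `series_id`,
#'   `event_start_minute`, `event_end_minute`, `min_glucose`).
#' @export
simulate_series <- function(config, series_id = "S1", patient_id = "P1") {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$days * 288L
  templates <- pattern_templates()
  base <- stats::runif(1, 110, 160)

  meal_minutes <- integer()
  patterns <- character()
  for (d in seq_len(config$days) - 1L) {
    for (clock in c(480L, 780L, 1140L)) {           # 08:00, 13:00, 19:00
      jitter <- 5L * sample(-3:3, 1L)               # +- 15 min on the grid
      meal_minutes <- c(meal_minutes, d * 1440L + clock + jitter)
      patterns <- c(patterns,
                    sample(names(templates), 1L, prob = config$weights))
    }
  }

  minutes <- 5 * (seq_len(n) - 1)
  noiseless <- rep(base, n)
  truth_plant <- logical(length(meal_minutes))
  for (m in seq_along(meal_minutes)) {
    tmpl <- templates[[patterns[m]]]
    p_hypo <- if (is.null(config$hypo_probability)) tmpl$hypo else
      config$hypo_probability
    plant <- stats::runif(1) < p_hypo
    truth_plant[m] <- plant
    drop <- if (plant) {
      base - stats::runif(1, 48, 62)
    } else {
      max(base - stats::runif(1, 88, 112), 0)
    }
    if (patterns[m] == "IOB_FALL") drop <- max(drop, tmpl$amplitude + 5)
    sc <- meal_scenario(
      pattern = patterns[m], baseline = base,
      amplitude = tmpl$amplitude * stats::runif(1, 0.85, 1.15),
      time_to_peak = tmpl$tp, decay_halflife = tmpl$hl,
      insulin_drop = drop, hypo_probability = p_hypo
    )
    tau <- minutes - meal_minutes[m]
    active <- tau >= 0 & tau <= 330
    noiseless[active] <- noiseless[active] +
      meal_contribution(sc, tau[active], taper = TRUE)
  }
  noiseless <- pmax(noiseless, 40)

  # AR(1) sensor noise with stationary sd = noise_sd
  g <- noiseless
  if (config$noise_sd > 0) {
    ar <- config$ar_coefficient
    e <- numeric(n)
    e[1] <- stats::rnorm(1, sd = config$noise_sd)
    innov_sd <- config$noise_sd * sqrt(1 - ar^2)
    innov <- stats::rnorm(n - 1L, sd = innov_sd)
    for (k in 2:n) e[k] <- ar * e[k - 1L] + innov[k - 1L]
    g <- g + e
  }
  g <- pmin(pmax(round(g), 40), 400)

  if (config$missing_rate > 0) {
    g[stats::runif(n) < config$missing_rate] <- NA_real_
  }

  meal_grid <- as.integer(meal_minutes / 5L) + 1L
  announce <- meal_grid
  for (d in seq_len(config$days) - 1L) {
    if (stats::runif(1) < 0.3) {          # nocturnal calibration finger-stick
      noct <- d * 1440L + 5L * sample(24:60, 1L)   # 02:00-05:00
      announce <- c(announce, as.integer(noct / 5L) + 1L)
    }
  }
  for (m in meal_grid) {                  # occasional duplicate announcement
    if (stats::runif(1) < 0.15) {
      announce <- c(announce, m - sample(12:18, 1L))   # 60-90 min earlier
    }
  }
  announce <- sort(unique(announce[announce >= 1L & announce <= n]))

  series <- cgm_series(series_id = series_id, patient_id = patient_id,
                       glucose = g, start_clock = 0L,
                       raw_meal_times = announce)
  truth <- scan_planted_events(noiseless, meal_minutes, series_id)
  list(series = series, noiseless = noiseless, meal_grid = meal_grid,
       truth = truth)
}

# Ground-truth scan of the noiseless curve: maximal runs of >= 2 consecutive
# points < 70 mg/dL, runs separated by <= 10 min merged, kept when starting
# within (meal + 5, meal + 240] minutes of a true meal.
scan_planted_events <- function(noiseless, meal_minutes, series_id) {
  hypo <- noiseless < 70
  n <- length(hypo)
  runs <- list()
  k <- 1L
  while (k <= n) {
    if (hypo[k]) {
      s <- k
      while (k < n && hypo[k + 1L]) k <- k + 1L
      if (k - s + 1L >= 2L) runs[[length(runs) + 1L]] <- c(s, k)
    }
    k <- k + 1L
  }
  merged <- list()
  for (r in runs) {
    last <- if (length(merged)) merged[[length(merged)]] else NULL
    if (!is.null(last) && (r[1] - last[2] - 1L) * 5 <= 10) {
      merged[[length(merged)]] <- c(last[1], r[2])
    } else {
      merged[[length(merged) + 1L]] <- r
    }
  }
  keep <- Filter(function(r) {
    start_min <- 5 * (r[1] - 1L)
    any(start_min > meal_minutes + 5 & start_min <= meal_minutes + 240)
  }, merged)
  data.frame(
    series_id = rep(series_id, length(keep)),
    event_start_minute = vapply(keep, function(r) 5 * (r[1] - 1), 0),
    event_end_minute = vapply(keep, function(r) 5 * (r[2] - 1), 0),
    min_glucose = vapply(keep, function(r) min(noiseless[r[1]:r[2]]), 0),
    stringsAsFactors = FALSE
  )
}

#' Simulate a labeled synthetic CGM cohort
#'
#' Generates `n_series` series reproducibly from the configuration seed,
#' together with the ground-truth list of planted postprandial hypoglycemic
#' excursions (defined on the noiseless curves). About 3% of subjects
#' contribute a second series, mirroring cohorts in which a few participants
#' are monitored twice.
#'
#' @param config A [cohort_config()].
#' @return A list with `series` (list of [cgm_series()]), `truth` (row-bound
#'   ground-truth events of all series), `meal_grid` (named list of true meal
#'   grid indices per series) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_series
  if (n == 0L) {
    return(list(series = list(),
                truth = data.frame(series_id = character(),
                                   event_start_minute = numeric(),
                                   event_end_minute = numeric(),
                                   min_glucose = numeric(),
                                   stringsAsFactors = FALSE),
                meal_grid = list(), config = config))
  }
  n_repeat <- round(0.03 * n)
  n_pat <- n - n_repeat
  patient_of <- seq_len(n)
  if (n_repeat > 0L && n_pat >= 1L) {
    patient_of[(n_pat + 1L):n] <- sample(seq_len(n_pat), n_repeat,
                                         replace = n_repeat > n_pat)
  }
  series <- vector("list", n)
  truth <- vector("list", n)
  meal_grid <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sprintf("S%03d", i)
    sim <- simulate_series(config, series_id = sid,
                           patient_id = sprintf("P%03d", patient_of[i]))
    series[[i]] <- sim$series
    truth[[i]] <- sim$truth
    meal_grid[[i]] <- sim$meal_grid
  }
  names(meal_grid) <- vapply(series, function(s) s$series_id, "")
  list(series = series, truth = do.call(rbind, truth),
       meal_grid = meal_grid, config = config)
}

#' Write a cohort's ground-truth event list
#'
#' @param truth Ground-truth data.frame from [simulate_cohort()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
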