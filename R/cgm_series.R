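#' CGM series objects
#'
#' A `cgm_series` holds one subject-session continuous glucose monitoring
#' trace on a strict 5-minute grid, together with the raw meal-announcement
#' positions recorded during the session. Grid index `k` (1-based) corresponds
#' to minute `5 * (k - 1)` from the start of the series; the wall-clock time
#' of sample `k` is `(start_clock + 5 * (k - 1)) %% 1440` minutes of day.
#'
#' @param series_id Identifier of the trace (one subject may contribute
#'   several traces).
#' @param patient_id Identifier of the subject.
#' @param glucose Numeric vector of glucose values in mg/dL; `NA` marks a
#'   missing sensor reading. Present values must lie in \[20, 600\].
#' @param start_clock Clock time of the first sample, in minutes of day
#'   (0-1439).
#' @param raw_meal_times Strictly increasing integer vector of 1-based grid
#'   indices at which a meal announcement (pre-meal finger-stick) was made.
#'
#' @return An object of class `cgm_series`.
#' @export
cgm_series <- function(series_id, patient_id, glucose,
                       start_clock = 0L, raw_meal_times = integer()) {
  x <- structure(
    list(
      series_id = as.character(series_id),
      patient_id = as.character(patient_id),
      start_clock = as.integer(start_clock),
      glucose = as.numeric(glucose),
      raw_meal_times = as.integer(raw_meal_times)
    ),
    class = "cgm_series"
  )
  validate_cgm_series(x)
  x
}

validate_cgm_series <- function(x) {
  g <- x$glucose
  if (length(g) == 0L) {
    stop("cgm_series '", x$series_id, "': glucose trace is empty", call. = FALSE)
  }
  present <- g[!is.na(g)]
  if (any(present < 20 | present > 600)) {
    stop("cgm_series '", x$series_id,
         "': glucose values outside [20, 600] mg/dL", call. = FALSE)
  }
  if (x$start_clock < 0L || x$start_clock > 1439L) {
    stop("cgm_series '", x$series_id,
         "': start_clock must be in 0..1439", call. = FALSE)
  }
  m <- x$raw_meal_times
  if (length(m)) {
    if (any(diff(m) <= 0L)) {
      stop("cgm_series '", x$series_id,
           "': raw_meal_times must be strictly increasing", call. = FALSE)
    }
    if (any(m < 1L) || any(m > length(g))) {
      stop("cgm_series '", x$series_id,
           "': raw_meal_times outside the series", call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.cgm_series <- function(x, ...) {
  n <- length(x$glucose)
  nmiss <- sum(is.na(x$glucose))
  cat(sprintf(
    "<cgm_series '%s' (patient '%s')>\n  %d points (%.1f h), %d missing, %d raw meal announcements\n",
    x$series_id, x$patient_id, n, n * 5 / 60, nmiss, length(x$raw_meal_times)
  ))
  invisible(x)
}

#' @export
length.cgm_series <- function(x) length(x$glucose)

#' Clock time (minutes of day) of each grid index
#' @param series A [cgm_series()].
#' @param grid_index Integer vector of 1-based grid indices.
#' @return Integer minutes of day in 0..1439.
#' @keywords internal
clock_minutes <- function(series, grid_index) {
  (series$start_clock + 5L * (as.integer(grid_index) - 1L)) %% 1440L
}

#' Read CGM traces from a delimited text file
#'
#' The expected dialect has a header and columns
#' `series_id,patient_id,minute,glucose,is_meal`: `minute` is the integer
#' offset (a multiple of 5) from the start of the series, `glucose` is in
#' mg/dL (or mmol/L with `units = "mmol"`) and may be empty to mark a missing
#' reading, and `is_meal` is 0/1. Rows must be grouped by series and each
#' series' offsets must advance in steps of exactly 5 minutes.
#'
#' @param path Path to the CSV file.
#' @param units Either `"mgdl"` (default) or `"mmol"`; mmol/L values are
#'   converted to mg/dL (x 18.016) on read.
#' @param start_clock Clock time (minutes of day) of each series' first
#'   sample: a single value recycled over series, or a named vector keyed by
#'   `series_id`. Defaults to 0 (midnight).
#' @return A list of [cgm_series()] objects, one per `series_id`, in file
#'   order.
#' @export
read_cgm_csv <- function(path, units = c("mgdl", "mmol"), start_clock = 0L) {
  units <- match.arg(units)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(glucose = "character"))
  need <- c("series_id", "patient_id", "minute", "glucose", "is_meal")
  if (!all(need %in% names(df))) {
    stop("CGM CSV must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  glucose <- suppressWarnings(as.numeric(df$glucose))
  bad_num <- !is.na(df$glucose) & nzchar(trimws(df$glucose)) & is.na(glucose)
  if (any(bad_num)) {
    stop("non-numeric glucose value at row ", which(bad_num)[1], call. = FALSE)
  }
  if (units == "mmol") glucose <- glucose * 18.016

  ids <- unique(df$series_id)
  lapply(ids, function(sid) {
    rows <- df[df$series_id == sid, , drop = FALSE]
    minute <- as.integer(rows$minute)
    if (any(minute %% 5L != 0L) || any(diff(minute) != 5L)) {
      bad <- which(minute %% 5L != 0L | c(5L, diff(minute)) != 5L)[1]
      stop("series '", sid, "': sampling grid is not 5 min at row ", bad,
           call. = FALSE)
    }
    g <- glucose[df$series_id == sid]
    present <- g[!is.na(g)]
    if (any(present < 20 | present > 600)) {
      stop("series '", sid, "': glucose outside [20, 600] mg/dL", call. = FALSE)
    }
    sc <- if (length(start_clock) > 1L) {
      if (is.null(names(start_clock)) || !sid %in% names(start_clock)) {
        stop("start_clock vector must be named by series_id", call. = FALSE)
      }
      start_clock[[sid]]
    } else start_clock
    cgm_series(
      series_id = sid,
      patient_id = rows$patient_id[1],
      glucose = g,
      start_clock = sc,
      raw_meal_times = which(as.integer(rows$is_meal) == 1L)
    )
  })
}

#' Write CGM traces to the package's CSV dialect
#'
#' @param series_list A list of [cgm_series()] objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cgm_csv <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    n <- length(s$glucose)
    data.frame(
      series_id = s$series_id,
      patient_id = s$patient_id,
      minute = 5L * (seq_len(n) - 1L),
      glucose = ifelse(is.na(s$glucose), "", format(s$glucose, trim = TRUE)),
      is_meal = as.integer(seq_len(n) %in% s$raw_meal_times),
      stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
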