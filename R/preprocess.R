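#' Fill short sensor gaps by cubic-spline interpolation
#'
#' Maximal runs of 1 or 2 consecutive missing readings are replaced by values
#' from a natural cubic spline fitted on all present points of the series
#' (grid index as abscissa). Runs of 3 or more consecutive missing readings
#' are left untouched, as are all present values. The operation is idempotent.
#'
#' @param series A [cgm_series()].
#' @param max_gap Longest run of consecutive missing points that is filled
#'   (default 2).
#' @return A [cgm_series()] with short gaps filled.
#' @export
interpolate_gaps <- function(series, max_gap = 2L) {
  g <- series$glucose
  miss <- is.na(g)
  if (!any(miss)) return(series)
  if (sum(!miss) < 4L) {
    stop("series '", series$series_id,
         "': fewer than 4 present points, spline interpolation is underdetermined",
         call. = FALSE)
  }
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  fill_idx <- integer()
  for (i in seq_along(r$lengths)) {
    if (r$values[i] && r$lengths[i] <= max_gap) {
      fill_idx <- c(fill_idx, starts[i]:ends[i])
    }
  }
  if (length(fill_idx)) {
    sf <- stats::splinefun(x = which(!miss), y = g[!miss], method = "natural")
    vals <- sf(fill_idx)
    # keep filled values inside the physical sensor range
    g[fill_idx] <- pmin(pmax(vals, 20), 600)
  }
  series$glucose <- g
  series
}

#' Filter raw meal announcements: nocturnal exclusion and 2-hour merging
#'
#' Announcements whose clock time falls in the nocturnal interval
#' (\[23:00, 07:00) by default, half-open so an 07:00 announcement survives)
#' are removed. The survivors are then merged: an announcement is kept iff it
#' is at least `merge_minutes` before the nearest kept later announcement
#' (scanning backward from the last, which is always kept), so of any chain of
#' announcements pairwise closer than the merge interval only the last
#' survives, and the result is invariant to pre-dropping announcements the
#' rule would drop anyway.
#'
#' @param series A [cgm_series()] with `raw_meal_times`.
#' @param nocturnal_start,nocturnal_end Bounds of the excluded clock interval
#'   in minutes of day (defaults 1380 = 23:00 and 420 = 07:00).
#' @param merge_minutes Two announcements closer than this many minutes are
#'   merged, keeping the later one (default 120).
#' @return A data.frame with columns `series_id`, `meal_index` (1..M, after
#'   filtering) and `grid_index`. Zero rows when nothing survives.
#' @export
filter_meal_announcements <- function(series, nocturnal_start = 1380L,
                                      nocturnal_end = 420L,
                                      merge_minutes = 120L) {
  idx <- series$raw_meal_times
  if (length(idx)) {
    clock <- clock_minutes(series, idx)
    nocturnal <- if (nocturnal_start > nocturnal_end) {
      clock >= nocturnal_start | clock < nocturnal_end
    } else {
      clock >= nocturnal_start & clock < nocturnal_end
    }
    idx <- idx[!nocturnal]
  }
  kept <- integer()
  for (i in rev(idx)) {
    if (!length(kept) || (kept[1L] - i) * 5L >= merge_minutes) {
      kept <- c(i, kept)
    }
  }
  data.frame(
    series_id = rep(series$series_id, length(kept)),
    meal_index = seq_along(kept),
    grid_index = kept,
    stringsAsFactors = FALSE
  )
}

#' Extract the postprandial window after one meal announcement
#'
#' Returns the glucose values at grid positions `meal, meal + 1, ...,
#' meal + W`, i.e. postprandial steps t = 0..W where t = 0 is the meal-time
#' point itself and step t is minute `5 * t` after the meal. The window is
#' truncated at the end of the series; missing values propagate. Windows of
#' different meals may overlap in underlying series time.
#'
#' @param series A [cgm_series()].
#' @param grid_index 1-based grid index of the meal announcement.
#' @param W Number of postprandial steps (default 42, i.e. 3.5 h).
#' @return Numeric vector of length `min(W, n - grid_index) + 1`; element
#'   `t + 1` is postprandial step t.
#' @export
postprandial_window <- function(series, grid_index, W = 42L) {
  n <- length(series$glucose)
  grid_index <- as.integer(grid_index)
  if (grid_index < 1L || grid_index > n) {
    stop("meal grid_index ", grid_index, " outside series '",
         series$series_id, "'", call. = FALSE)
  }
  if (grid_index == n) {
    stop("meal at the last point of series '", series$series_id,
         "': postprandial window is empty", call. = FALSE)
  }
  series$glucose[grid_index:min(grid_index + W, n)]
}
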