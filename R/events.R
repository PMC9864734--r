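#' Hot-day mask
#'
#' Marks each day 1 where TI >= TI' and 0 otherwise; pixels without a valid
#' threshold are fully `NA`. A day exactly at the threshold counts as hot:
#' the heatwave definition uses `TI >= TI'`, and ties are measure-zero on
#' continuous data.
#'
#' @param ti Daily TI array `(n_time, ny, nx)`.
#' @param threshold A `"threshold_field"` from [ti_threshold()].
#' @return Integer array of 0/1 (and `NA`), same shape as `ti`.
#' @export
hot_day_mask <- function(ti, threshold) {
  stopifnot(inherits(threshold, "threshold_field"))
  d <- dim(ti)
  if (length(d) != 3L || !all(d[2:3] == dim(threshold$ti_prime))) {
    stop("`ti` and `threshold` shapes do not match", call. = FALSE)
  }
  tp <- aperm(array(threshold$ti_prime, c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
  out <- array(NA_integer_, d)
  ok <- !is.na(tp) & !is.na(ti)
  out[ok] <- as.integer(ti[ok] >= tp[ok])
  out
}

#' Maximal runs of 1s in a binary sequence
#'
#' @param mask Vector of 0/1 (logicals accepted; `NA` treated as 0 and noted
#'   as a gap).
#' @return Data frame with columns `start` (1-based index) and `length`, one
#'   row per maximal run, in order. Zero rows when there is no 1.
#' @examples
#' find_runs(c(0, 1, 1, 1, 0))  # start 2, length 3
#' @export
find_runs <- function(mask) {
  if (is.logical(mask)) mask <- as.integer(mask)
  mask[is.na(mask)] <- 0L
  if (!all(mask %in% c(0L, 1L))) {
    stop("`mask` must be binary", call. = FALSE)
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  keep <- r$values == 1L
  data.frame(start = (ends - r$lengths + 1L)[keep],
             length = r$lengths[keep])
}

#' Detect heatwave events in one daily series
#'
#' A heatwave is a run of at least `min_duration` (default 3) consecutive hot
#' days (TI >= TI') within one May-September season whose event-level
#' heatwave index HWI is at least `hwi_threshold` (default 2.8). HWI is the
#' mean of the run's daily heat indices by default (`hwi_mode = "mean"`; the
#' 2.8 cutoff is a daily heat grade, coherent with an average); the plain sum
#' of daily HI is available as `hwi_mode = "sum"`. Runs never bridge the gap
#' between September 30 and the following May 1, and an event is attributed
#' to the calendar year in which it starts.
#'
#' @param ti Numeric vector of daily TI for one location.
#' @param ti_prime Scalar local threshold TI'; must be finite.
#' @param dates `Date` vector aligned with `ti` (May-September days).
#' @param min_duration Minimum run length in days.
#' @param hwi_threshold Minimum HWI for a run to count as a heatwave.
#' @param hwi_mode `"mean"` (default) or `"sum"` aggregation of daily HI.
#' @return Data frame, one row per event: `year`, `start` (day-of-season,
#'   1-153), `start_date`, `end_date`, `duration`, `hwi`, `max_hi`.
#' @export
detect_events <- function(ti, ti_prime, dates,
                          min_duration = 3L, hwi_threshold = 2.8,
                          hwi_mode = c("mean", "sum")) {
  hwi_mode <- match.arg(hwi_mode)
  if (length(ti_prime) != 1L || !is.finite(ti_prime)) {
    stop("`ti_prime` must be a single finite value", call. = FALSE)
  }
  if (length(ti) != length(dates)) {
    stop("`ti` and `dates` must be aligned", call. = FALSE)
  }
  if (min_duration < 1L || hwi_threshold < 0) {
    stop("invalid detection configuration", call. = FALSE)
  }
  dates <- as.Date(dates)
  years <- as.integer(format(dates, "%Y"))
  dos <- day_of_season(dates)
  out <- list()
  for (idx in split(seq_along(ti), years)) {
    hot <- !is.na(ti[idx]) & ti[idx] >= ti_prime
    runs <- find_runs(hot)
    runs <- runs[runs$length >= min_duration, , drop = FALSE]
    for (r in seq_len(nrow(runs))) {
      sel <- idx[runs$start[r] + seq_len(runs$length[r]) - 1L]
      hi <- hi_for_run(ti[sel] - ti_prime)
      hwi <- if (hwi_mode == "mean") mean(hi) else sum(hi)
      if (hwi >= hwi_threshold) {
        out[[length(out) + 1L]] <- data.frame(
          year = years[sel[1L]],
          start = dos[sel[1L]],
          start_date = dates[sel[1L]],
          end_date = dates[sel[length(sel)]],
          duration = length(sel),
          hwi = hwi,
          max_hi = max(hi)
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(year = integer(), start = integer(),
                      start_date = as.Date(character()),
                      end_date = as.Date(character()),
                      duration = integer(), hwi = numeric(),
                      max_hi = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect heatwave events over a climate grid
#'
#' Runs [detect_events()] independently for every pixel with a valid
#' threshold.
#'
#' @param ti Daily TI array `(n_time, ny, nx)`.
#' @param threshold A `"threshold_field"`.
#' @param dates `Date` vector aligned with the time axis.
#' @inheritParams detect_events
#' @return Event data frame as in [detect_events()] with additional pixel
#'   columns `y`, `x`.
#' @export
detect_events_grid <- function(ti, threshold, dates,
                               min_duration = 3L, hwi_threshold = 2.8,
                               hwi_mode = c("mean", "sum")) {
  hwi_mode <- match.arg(hwi_mode)
  stopifnot(inherits(threshold, "threshold_field"))
  d <- dim(ti)
  out <- list()
  for (x in seq_len(d[3L])) {
    for (y in seq_len(d[2L])) {
      tp <- threshold$ti_prime[y, x]
      if (is.na(tp)) next
      ev <- detect_events(ti[, y, x], tp, dates, min_duration,
                          hwi_threshold, hwi_mode)
      if (nrow(ev) > 0L) {
        ev$y <- y; ev$x <- x
        out[[length(out) + 1L]] <- ev
      }
    }
  }
  if (length(out) == 0L) {
    empty <- detect_events(numeric(0), 0 + 1, as.Date(character()))
    empty$y <- integer(); empty$x <- integer()
    return(empty)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annual hazard indicators from detected events
#'
#' Per pixel and year: HWF, the number of heatwave events; HWMHI, the highest
#' daily HI reached by any of the year's events (running-max update); HWMD,
#' the longest event duration in days. Pixel-years without events get zeros
#' for all three.
#'
#' @param events Event data frame from [detect_events_grid()] (columns `y`,
#'   `x`, `year`, `duration`, `max_hi`).
#' @param years Integer vector of all years to tabulate (including eventless
#'   ones).
#' @param ny,nx Grid shape.
#' @return Object of class `"annual_indicators"`: list of arrays `hwf`,
#'   `hwmhi`, `hwmd`, each `(n_years, ny, nx)`, plus `years`.
#' @export
annual_indicators <- function(events, years, ny, nx) {
  years <- as.integer(years)
  hwf <- array(0, c(length(years), ny, nx))
  hwmhi <- array(0, c(length(years), ny, nx))
  hwmd <- array(0, c(length(years), ny, nx))
  if (nrow(events) > 0L) {
    if (!all(events$year %in% years)) {
      stop("event years outside the tabulated `years`", call. = FALSE)
    }
    for (i in seq_len(nrow(events))) {
      t <- match(events$year[i], years)
      y <- events$y[i]; x <- events$x[i]
      hwf[t, y, x] <- hwf[t, y, x] + 1
      hwmhi[t, y, x] <- max(hwmhi[t, y, x], events$max_hi[i])
      hwmd[t, y, x] <- max(hwmd[t, y, x], events$duration[i])
    }
  }
  structure(list(hwf = hwf, hwmhi = hwmhi, hwmd = hwmd, years = years),
            class = "annual_indicators")
}

#' @export
print.annual_indicators <- function(x, ...) {
  cat("<annual_indicators>\n")
  cat(sprintf("  %d years x %d x %d pixels\n",
              dim(x$hwf)[1L], dim(x$hwf)[2L], dim(x$hwf)[3L]))
  cat(sprintf("  HWF mean %.2f events/yr, HWMD max %g d, HWMHI max %.2f\n",
              mean(x$hwf), max(x$hwmd), max(x$hwmhi)))
  invisible(x)
}
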