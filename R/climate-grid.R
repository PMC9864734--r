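#' Dates of the extended-summer analysis window
#'
#' The analysis season is the extended summer, May 1 to September 30: 153 days
#' per year regardless of leap years (31 + 30 + 31 + 31 + 30).
#'
#' @param years Integer vector of calendar years.
#' @return A `Date` vector, 153 consecutive dates per year, in order.
#' @examples
#' length(season_dates(1990:2019))  # 4590
#' @export
season_dates <- function(years) {
  years <- as.integer(years)
  if (length(years) < 1L || anyNA(years)) {
    stop("`years` must be a non-empty integer vector", call. = FALSE)
  }
  do.call(c, lapply(years, function(y) {
    seq(as.Date(sprintf("%d-05-01", y)), as.Date(sprintf("%d-09-30", y)),
        by = "day")
  }))
}

#' Number of days in one extended-summer season
#' @keywords internal
SEASON_LENGTH <- 153L

#' Assemble a daily climate grid
#'
#' Container for aligned daily stacks of maximum temperature (MT, degrees C)
#' and mean relative humidity (RH, %) on a regular lon/lat grid, restricted to
#' extended-summer (May-September) windows. Arrays are indexed
#' `[time, y, x]`.
#'
#' @param mt Numeric array `(n_time, ny, nx)` of daily maximum temperature
#'   (degrees C).
#' @param rh Numeric array of the same shape, relative humidity in `[0, 100]`.
#' @param dates `Date` vector of length `n_time`, strictly increasing, all
#'   within May-September.
#' @param lon,lat Numeric coordinate vectors of length `nx` and `ny`.
#' @return An object of class `"climate_grid"`: a list with elements `mt`,
#'   `rh`, `dates`, `years` (per-layer calendar year), `lon`, `lat`.
#' @export
climate_grid <- function(mt, rh, dates, lon, lat) {
  if (!identical(dim(mt), dim(rh))) {
    stop("`mt` and `rh` must have identical dimensions", call. = FALSE)
  }
  if (length(dim(mt)) != 3L) {
    stop("`mt` must be a 3-d array (time, y, x)", call. = FALSE)
  }
  dates <- as.Date(dates)
  if (length(dates) != dim(mt)[1L]) {
    stop("length(dates) must equal the time dimension of `mt`", call. = FALSE)
  }
  if (is.unsorted(dates, strictly = TRUE)) {
    stop("`dates` must be strictly increasing", call. = FALSE)
  }
  mon <- as.integer(format(dates, "%m"))
  if (any(mon < 5L | mon > 9L)) {
    stop("all dates must fall in May-September", call. = FALSE)
  }
  if (length(lat) != dim(mt)[2L] || length(lon) != dim(mt)[3L]) {
    stop("coordinate lengths must match grid dimensions", call. = FALSE)
  }
  bad_rh <- !is.na(rh) & (rh < 0 | rh > 100)
  if (any(bad_rh)) {
    stop("RH values must lie in [0, 100]", call. = FALSE)
  }
  structure(
    list(mt = mt, rh = rh, dates = dates,
         years = as.integer(format(dates, "%Y")),
         lon = as.numeric(lon), lat = as.numeric(lat)),
    class = "climate_grid"
  )
}

#' @export
print.climate_grid <- function(x, ...) {
  d <- dim(x$mt)
  cat("<climate_grid>\n")
  cat(sprintf("  grid: %d x %d pixels, %d daily layers\n", d[2L], d[3L], d[1L]))
  cat(sprintf("  years: %s (%d seasons of %d days)\n",
              paste(range(x$years), collapse = "-"),
              length(unique(x$years)), SEASON_LENGTH))
  cat(sprintf("  MT range: [%.1f, %.1f] degC; RH range: [%.1f, %.1f] %%\n",
              min(x$mt, na.rm = TRUE), max(x$mt, na.rm = TRUE),
              min(x$rh, na.rm = TRUE), max(x$rh, na.rm = TRUE)))
  invisible(x)
}

#' Day-of-season index (1..153) for each date
#' @keywords internal
day_of_season <- function(dates) {
  yr <- as.integer(format(dates, "%Y"))
  as.integer(dates - as.Date(sprintf("%d-05-01", yr))) + 1L
}
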