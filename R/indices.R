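#' Torridity index from temperature and humidity
#'
#' The torridity index (TI) is an apparent-heat metric combining daily
#' maximum temperature MT (degrees C) and mean relative humidity RH (%):
#'
#' \deqn{TI = 1.8\,MT - 0.55\,(1.8\,MT - 26)\,(1 - r) + 32}
#'
#' where the humidity factor is fixed at `r = 0.6` for `RH <= 60` and
#' `r = RH/100` above 60% (humidity only worsens apparent heat once the air is
#' more than 60% saturated). The two branches agree at RH = 60%. The result is
#' a dimensionless index on a Fahrenheit-like scale.
#'
#' @param mt Maximum temperature, degrees C (vector or array).
#' @param rh Relative humidity, %, in `[0, 100]`; recycled/elementwise with
#'   `mt`.
#' @return TI, same shape as `mt`. `NA` inputs give `NA`.
#' @examples
#' torridity_index(35, 40)   # 86.86
#' torridity_index(35, 60) - torridity_index(35, 60 + 1e-9)  # ~0: continuity
#' @export
torridity_index <- function(mt, rh) {
  if (any(!is.na(rh) & (rh < 0 | rh > 100))) {
    stop("RH must lie in [0, 100]", call. = FALSE)
  }
  r <- pmax(rh / 100, 0.6)
  out <- 1.8 * mt - 0.55 * (1.8 * mt - 26) * (1 - r) + 32
  if (!is.null(dim(mt))) dim(out) <- dim(mt)
  out
}

#' Quantile with one-third plotting-position interpolation
#'
#' Order statistic quantile with index `h = p * n + (1 + p) / 3`,
#' `j = floor(h)`, `gamma = h - j`, returning
#' `(1 - gamma) * X[j] + gamma * X[j + 1]` on the ascending sort of `x`
#' (1-based). When the index falls off either end the nearest order statistic
#' is returned (`X[1]` for `j < 1`, `X[n]` for `j >= n`). This is the
#' approximately median-unbiased quantile definition (type 8 in
#' [stats::quantile()]'s taxonomy), used here to calibrate the local
#' torridity threshold.
#'
#' @param x Non-empty numeric vector (any order; `NA`s dropped).
#' @param p Quantile level in (0, 1); default 0.50 (the local-threshold
#'   median).
#' @return The quantile value (length 1 per `p`; vectorised over `p`).
#' @examples
#' quantile_paper(c(1, 2, 3, 4, 5), 0.5)   # 3
#' quantile_paper(c(10, 20, 30, 40), 0.5)  # 25
#' @export
quantile_paper <- function(x, p = 0.5) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("empty sample", call. = FALSE)
  if (any(p <= 0 | p >= 1)) stop("`p` must lie in (0, 1)", call. = FALSE)
  xs <- sort(x)
  n <- length(xs)
  vapply(p, function(pp) {
    h <- pp * n + (1 + pp) / 3
    j <- floor(h)
    if (j < 1) return(xs[1L])
    if (j >= n) return(xs[n])
    g <- h - j
    (1 - g) * xs[j] + g * xs[j + 1L]
  }, numeric(1L))
}

#' Locally calibrated torridity threshold TI'
#'
#' Per pixel, pools every day across all years with `MT > hot_sample_cutoff`
#' (33 degrees C by default), computes the torridity index of those hot
#' samples, and takes their [quantile_paper()] at level `p` (default the
#' median) as the local threshold TI'. Pixels with fewer than `min_samples`
#' hot days get no threshold and are flagged invalid rather than zero-filled.
#'
#' A single all-years threshold per pixel keeps hot-day status, and hence the
#' hazard score, comparable from year to year.
#'
#' @param grid A [climate_grid()].
#' @param hot_sample_cutoff MT cutoff (degrees C, strict `>`) selecting the
#'   hot samples.
#' @param p Quantile level for the threshold.
#' @param min_samples Minimum hot-sample count for a valid threshold.
#' @return An object of class `"threshold_field"`: list with `ti_prime`
#'   (ny x nx matrix, `NA` where invalid), `n_hot` (hot-sample counts),
#'   `valid` (logical matrix), and the calibration settings.
#' @export
ti_threshold <- function(grid, hot_sample_cutoff = 33, p = 0.5,
                         min_samples = 10L) {
  stopifnot(inherits(grid, "climate_grid"))
  ny <- dim(grid$mt)[2L]; nx <- dim(grid$mt)[3L]
  ti_prime <- matrix(NA_real_, ny, nx)
  n_hot <- matrix(0L, ny, nx)
  for (x in seq_len(nx)) {
    for (y in seq_len(ny)) {
      mt <- grid$mt[, y, x]; rh <- grid$rh[, y, x]
      hot <- !is.na(mt) & mt > hot_sample_cutoff & !is.na(rh)
      n_hot[y, x] <- sum(hot)
      if (n_hot[y, x] >= min_samples) {
        ti_prime[y, x] <- quantile_paper(torridity_index(mt[hot], rh[hot]), p)
      }
    }
  }
  if (all(n_hot < min_samples)) {
    warning("no pixel has enough hot samples for a threshold", call. = FALSE)
  }
  structure(
    list(ti_prime = ti_prime, n_hot = n_hot, valid = !is.na(ti_prime),
         hot_sample_cutoff = hot_sample_cutoff, p = p,
         min_samples = as.integer(min_samples)),
    class = "threshold_field"
  )
}

#' @export
print.threshold_field <- function(x, ...) {
  cat("<threshold_field>\n")
  cat(sprintf("  valid pixels: %d / %d (min %d hot samples, MT > %g degC)\n",
              sum(x$valid), length(x$valid), x$min_samples,
              x$hot_sample_cutoff))
  if (any(x$valid)) {
    cat(sprintf("  TI' range: [%.2f, %.2f] (quantile p = %g)\n",
                min(x$ti_prime, na.rm = TRUE), max(x$ti_prime, na.rm = TRUE),
                x$p))
  }
  invisible(x)
}

#' Daily heat index for one hot day
#'
#' Scores the current hot day (TI >= TI') from its run prefix: with `N = k`
#' immediately preceding consecutive hot days, `TI_i` the TI of the i-th day
#' back and `nd_i = i` days of separation,
#'
#' \deqn{HI = 1.2 (TI - TI') + 0.35 \sum_{i=1}^{N} (TI_i - TI')/nd_i
#'       + 0.15 \sum_{i=1}^{N-1} 1/nd_{i+1}}
#'
#' The first term grades today's exceedance, the second adds hyperbolically
#' discounted exceedances of the preceding hot days (heat stress accumulates
#' over consecutive hot days), and the third is a pure persistence bonus
#' depending only on the run length.
#'
#' @param ti_run Numeric vector: TI of the `k >= 0` immediately preceding
#'   consecutive hot days followed by the current day's TI (current day last).
#' @param ti_prime The local threshold TI'.
#' @return The current day's HI.
#' @examples
#' heat_index_day(2 + 84, 84)            # first hot day: 1.2 * 2 = 2.4
#' heat_index_day(c(1, 2) + 84, 84)      # 2.75
#' heat_index_day(c(1, 1, 1) + 84, 84)   # 1.8
#' @export
heat_index_day <- function(ti_run, ti_prime) {
  L <- length(ti_run)
  if (L < 1L) stop("empty run prefix", call. = FALSE)
  delta <- ti_run - ti_prime
  if (any(delta < 0)) {
    stop("all days in the run prefix must be hot (TI >= TI')", call. = FALSE)
  }
  k <- L - 1L
  hi <- 1.2 * delta[L]
  if (k >= 1L) hi <- hi + 0.35 * sum(delta[L - seq_len(k)] / seq_len(k))
  if (k >= 2L) hi <- hi + 0.15 * sum(1 / (1L + seq_len(k - 1L)))
  hi
}

# HI for every day of one uninterrupted hot run (vector of TI - TI' deltas).
hi_for_run <- function(delta) {
  L <- length(delta)
  hi <- numeric(L)
  for (t in seq_len(L)) {
    k <- t - 1L
    hi[t] <- 1.2 * delta[t]
    if (k >= 1L) hi[t] <- hi[t] + 0.35 * sum(delta[t - seq_len(k)] / seq_len(k))
    if (k >= 2L) hi[t] <- hi[t] + 0.15 * sum(1 / (1L + seq_len(k - 1L)))
  }
  hi
}

#' Daily heat-index stack
#'
#' Applies [heat_index_day()] along time for every pixel: HI is defined on
#' hot days (TI >= TI') only and is `NA` elsewhere; the cumulative lag terms
#' never reach across a non-hot day or across the gap between one
#' May-September season and the next.
#'
#' @param ti Daily TI array `(n_time, ny, nx)` (from [torridity_index()]).
#' @param threshold A `"threshold_field"` from [ti_threshold()].
#' @param years Integer vector, the calendar year of each time layer.
#' @return HI array of the same shape as `ti`; fully `NA` over pixels without
#'   a valid threshold.
#' @export
heat_index_field <- function(ti, threshold, years) {
  stopifnot(inherits(threshold, "threshold_field"))
  d <- dim(ti)
  if (length(d) != 3L || !all(d[2:3] == dim(threshold$ti_prime))) {
    stop("`ti` and `threshold` shapes do not match", call. = FALSE)
  }
  if (length(years) != d[1L]) {
    stop("`years` must have one entry per time layer", call. = FALSE)
  }
  hi <- array(NA_real_, d)
  season_idx <- split(seq_len(d[1L]), years)
  for (x in seq_len(d[3L])) {
    for (y in seq_len(d[2L])) {
      tp <- threshold$ti_prime[y, x]
      if (is.na(tp)) next
      for (idx in season_idx) {
        tiv <- ti[idx, y, x]
        hot <- !is.na(tiv) & tiv >= tp
        if (!any(hot)) next
        runs <- find_runs(as.integer(hot))
        for (r in seq_len(nrow(runs))) {
          sel <- runs$start[r] + seq_len(runs$length[r]) - 1L
          hi[idx[sel], y, x] <- hi_for_run(tiv[sel] - tp)
        }
      }
    }
  }
  hi
}
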