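#' End-to-end heatwave hazard assessment
#'
#' Runs the full pipeline on a daily climate grid: torridity index, local
#' threshold calibration, heat-index scoring, heatwave detection, annual
#' indicators, normalized composite hazard, average hazard, per-pixel trend,
#' and the five-level spatial/temporal natural-breaks classifications crossed
#' into the four spatiotemporal categories.
#'
#' @param grid A [climate_grid()].
#' @param hot_sample_cutoff MT cutoff (degrees C) for threshold calibration.
#' @param p Quantile level of the local threshold.
#' @param min_samples Minimum hot-sample count for a valid threshold.
#' @param min_duration Minimum heatwave length, days.
#' @param hwi_threshold Minimum event HWI.
#' @param hwi_mode `"mean"` or `"sum"` HWI aggregation.
#' @param alpha Significance level for trend masks.
#' @param normalization `"global"` or `"pixel"` indicator normalization.
#' @param classify Logical: fit the natural-breaks classifications (needs
#'   enough distinct AH values; disable for tiny grids).
#' @return Object of class `"hazard_assessment"` bundling `threshold`
#'   (threshold_field), `events` (data frame), `indicators`
#'   (annual_indicators), `hazard` (hazard_surface), `ah` (matrix), `trend`
#'   (trend_surface), and when `classify = TRUE` the `spatial`/`temporal`
#'   classifications and `category` matrix, plus the settings used.
#' @examples
#' cfg <- synthetic_config(seed = 7, ny = 4, nx = 4, years = 2000:2009)
#' fit <- hazard_assessment(synthetic_climate_grid(cfg), classify = FALSE)
#' print(fit)
#' @export
hazard_assessment <- function(grid,
                              hot_sample_cutoff = 33, p = 0.5,
                              min_samples = 10L,
                              min_duration = 3L, hwi_threshold = 2.8,
                              hwi_mode = c("mean", "sum"),
                              alpha = 0.05,
                              normalization = c("global", "pixel"),
                              classify = TRUE) {
  hwi_mode <- match.arg(hwi_mode)
  normalization <- match.arg(normalization)
  stopifnot(inherits(grid, "climate_grid"))
  ti <- torridity_index(grid$mt, grid$rh)
  threshold <- ti_threshold(grid, hot_sample_cutoff, p, min_samples)
  events <- detect_events_grid(ti, threshold, grid$dates,
                               min_duration, hwi_threshold, hwi_mode)
  yrs <- sort(unique(grid$years))
  ind <- annual_indicators(events, yrs, dim(grid$mt)[2L], dim(grid$mt)[3L])
  hz <- hazard_score(normalize_indicators(ind, normalization))
  ah <- average_hazard(hz)
  trend <- if (length(yrs) >= 3L) trend_surface(hz$hazard, yrs, alpha) else NULL
  out <- list(threshold = threshold, events = events, indicators = ind,
              hazard = hz, ah = ah, trend = trend,
              lon = grid$lon, lat = grid$lat, years = yrs,
              settings = list(hot_sample_cutoff = hot_sample_cutoff, p = p,
                              min_samples = min_samples,
                              min_duration = min_duration,
                              hwi_threshold = hwi_threshold,
                              hwi_mode = hwi_mode, alpha = alpha,
                              normalization = normalization),
              call = match.call())
  if (classify && !is.null(trend)) {
    spatial <- tryCatch(classify_hazard(ah), error = function(e) NULL)
    temporal <- tryCatch(classify_trend(trend), error = function(e) NULL)
    if (!is.null(spatial) && !is.null(temporal)) {
      out$spatial <- spatial
      out$temporal <- temporal
      out$category <- spatiotemporal_category(spatial$classes,
                                              temporal$classes)
    }
  }
  structure(out, class = "hazard_assessment")
}

#' @export
print.hazard_assessment <- function(x, ...) {
  cat("Heatwave hazard assessment\n")
  cat(sprintf("  grid: %d x %d pixels, years %s\n",
              nrow(x$ah), ncol(x$ah), paste(range(x$years), collapse = "-")))
  cat(sprintf("  valid thresholds: %d / %d pixels\n",
              sum(x$threshold$valid), length(x$threshold$valid)))
  cat(sprintf("  heatwave events: %d (>= %d days, HWI >= %g, %s mode)\n",
              nrow(x$events), x$settings$min_duration,
              x$settings$hwi_threshold, x$settings$hwi_mode))
  cat(sprintf("  average hazard: mean %.3f, max %.3f\n",
              mean(x$ah, na.rm = TRUE), max(x$ah, na.rm = TRUE)))
  if (!is.null(x$trend)) {
    cat(sprintf("  hazard trend: mean slope %.4g / yr, %.1f%% significant\n",
                mean(x$trend$slope, na.rm = TRUE),
                100 * mean(x$trend$significant, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
summary.hazard_assessment <- function(object, ...) {
  x <- object
  print(x)
  cat("\nAnnual indicators (grid means):\n")
  tab <- data.frame(
    year = x$years,
    hwf = round(apply(x$indicators$hwf, 1L, mean), 3),
    hwmhi = round(apply(x$indicators$hwmhi, 1L, mean), 3),
    hwmd = round(apply(x$indicators$hwmd, 1L, mean), 3),
    hazard = round(apply(x$hazard$hazard, 1L, mean), 4)
  )
  print(tab, row.names = FALSE)
  if (!is.null(x$category)) {
    cat("\nSpatiotemporal categories (pixel counts):\n")
    print(table(factor(x$category, levels = 1:4)))
  }
  invisible(tab)
}

#' @export
plot.hazard_assessment <- function(x, which = c("ah", "trend", "category"),
                                   ...) {
  which <- match.arg(which)
  z <- switch(which,
              ah = x$ah,
              trend = if (is.null(x$trend)) {
                stop("no trend surface fitted", call. = FALSE)
              } else x$trend$slope,
              category = if (is.null(x$category)) {
                stop("no classification fitted", call. = FALSE)
              } else x$category)
  main <- switch(which, ah = "Average hazard (AH)",
                 trend = "Hazard trend slope (per year)",
                 category = "Spatiotemporal hazard category")
  # image() wants z[x, y]: transpose the [y, x] matrix
  image(x = x$lon, y = x$lat, z = t(z)[, , drop = TRUE],
        col = hcl.colors(if (which == "category") 4L else 12L,
                         "YlOrRd", rev = TRUE),
        xlab = "lon", ylab = "lat", main = main, ...)
  invisible(x)
}
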