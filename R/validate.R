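#' Mean absolute and root-mean-square error
#'
#' @param predicted,true Aligned numeric vectors (length >= 1).
#' @return Named vector `c(mae, rmse)`.
#' @examples
#' error_metrics(c(1, 2), c(2, 4))  # mae 1.5, rmse sqrt(2.5)
#' @export
error_metrics <- function(predicted, true) {
  if (length(predicted) != length(true)) {
    stop("`predicted` and `true` must have equal length", call. = FALSE)
  }
  if (length(predicted) < 1L) stop("empty input", call. = FALSE)
  e <- predicted - true
  c(mae = mean(abs(e)), rmse = sqrt(mean(e^2)))
}

#' Max-min normalization
#'
#' Maps a comparison set of values onto `[0, 1]`:
#' `(v - min(v)) / (max(v) - min(v))`. Used to put error metrics from
#' different validation units on a common scale (NMAE, NRMSE); the minimum of
#' the set maps to 0 and the maximum to 1. Invariant under positive affine
#' transformations of the input.
#'
#' @param values Numeric vector of at least 2 values, not all equal.
#' @return Normalized vector in `[0, 1]`; all-`NA` with a warning when the
#'   range is degenerate.
#' @export
minmax_normalize <- function(values) {
  if (length(values) < 2L) {
    stop("need at least 2 values to normalize", call. = FALSE)
  }
  rng <- range(values, na.rm = TRUE)
  if (!is.finite(diff(rng)) || diff(rng) == 0) {
    warning("degenerate range: all values equal", call. = FALSE)
    return(rep(NA_real_, length(values)))
  }
  (values - rng[1L]) / (rng[2L] - rng[1L])
}

#' Truth-on-prediction regression
#'
#' OLS with the predicted values as the independent variable and the true
#' values as the dependent variable; a slope near 1 with high R-squared
#' indicates an unbiased, precise prediction.
#'
#' @param predicted,true Aligned numeric vectors, >= 3 pairs, non-constant
#'   predictor.
#' @return List with `slope`, `intercept`, `r2`, `p` (two-sided, for the
#'   slope).
#' @export
truth_on_prediction_fit <- function(predicted, true) {
  if (length(predicted) != length(true)) {
    stop("`predicted` and `true` must have equal length", call. = FALSE)
  }
  ok <- is.finite(predicted) & is.finite(true)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(predicted[ok]) == 0) {
    stop("constant predictor: degenerate fit", call. = FALSE)
  }
  tr <- linear_trend(true[ok], predicted[ok])
  list(slope = tr$slope, intercept = tr$intercept, r2 = tr$r2, p = tr$p)
}

#' Cross-validation report over timescale units
#'
#' Builds the interpolation validation table: rows are validation units
#' (days, months or years), one per variable; columns are the
#' truth-on-prediction regression (slope, R-squared, p), MAE and RMSE, and
#' NMAE/NRMSE obtained by max-min normalizing MAE and RMSE across the units
#' of each variable group (the comparison set).
#'
#' @param data Data frame with columns `date` (Date), `variable`,
#'   `predicted`, `true`.
#' @param group_by Timescale of the validation unit: `"day"`, `"month"` or
#'   `"year"`.
#' @return Data frame with columns `unit`, `variable`, `slope`, `r2`, `p`,
#'   `mae`, `nmae`, `rmse`, `nrmse`.
#' @export
validation_report <- function(data, group_by = c("day", "month", "year")) {
  group_by <- match.arg(group_by)
  need <- c("date", "variable", "predicted", "true")
  if (!all(need %in% names(data))) {
    stop("`data` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  dt <- as.Date(data$date)
  unit <- switch(group_by,
                 day = format(dt, "%Y-%m-%d"),
                 month = format(dt, "%Y-%m"),
                 year = format(dt, "%Y"))
  out <- list()
  for (v in unique(data$variable)) {
    rows <- list()
    for (u in unique(unit[data$variable == v])) {
      sel <- data$variable == v & unit == u
      em <- error_metrics(data$predicted[sel], data$true[sel])
      fit <- truth_on_prediction_fit(data$predicted[sel], data$true[sel])
      rows[[length(rows) + 1L]] <- data.frame(
        unit = u, variable = v, slope = fit$slope, r2 = fit$r2, p = fit$p,
        mae = em[["mae"]], rmse = em[["rmse"]])
    }
    tab <- do.call(rbind, rows)
    tab$nmae <- if (nrow(tab) >= 2L) minmax_normalize(tab$mae) else NA_real_
    tab$nrmse <- if (nrow(tab) >= 2L) minmax_normalize(tab$rmse) else NA_real_
    out[[v]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("unit", "variable", "slope", "r2", "p", "mae", "nmae",
          "rmse", "nrmse")]
}
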