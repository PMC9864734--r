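#' Max-normalize the annual indicators
#'
#' Divides each indicator (HWF, HWMHI, HWMD) by a single maximum so the
#' results lie in `[0, 1]` and are comparable across years. The default
#' (`scope = "global"`) uses one domain-wide maximum per indicator over all
#' pixels and years, which keeps regions comparable on hazard maps;
#' `scope = "pixel"` normalizes each pixel by its own across-year maximum.
#' An all-zero indicator stays all-zero (0/0 guarded to 0).
#'
#' @param ind An [annual_indicators()] object (values must be non-negative).
#' @param scope `"global"` (default) or `"pixel"`.
#' @return Object of class `"normalized_indicators"`: arrays `hwf`, `hwmhi`,
#'   `hwmd` in `[0, 1]`, `years`, and `maxima` (the normalization maxima
#'   used).
#' @export
normalize_indicators <- function(ind, scope = c("global", "pixel")) {
  scope <- match.arg(scope)
  stopifnot(inherits(ind, "annual_indicators"))
  norm_one <- function(a) {
    if (any(a < 0, na.rm = TRUE)) {
      stop("indicator values must be non-negative", call. = FALSE)
    }
    if (scope == "global") {
      m <- max(a, na.rm = TRUE)
      list(values = if (m > 0) a / m else a * 0, max = m)
    } else {
      m <- apply(a, c(2L, 3L), max, na.rm = TRUE)
      d <- dim(a)
      mm <- aperm(array(m, c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
      out <- a / mm
      out[mm == 0] <- 0
      list(values = out, max = m)
    }
  }
  f <- norm_one(ind$hwf); i <- norm_one(ind$hwmhi); d <- norm_one(ind$hwmd)
  structure(
    list(hwf = f$values, hwmhi = i$values, hwmd = d$values,
         years = ind$years,
         maxima = list(hwf = f$max, hwmhi = i$max, hwmd = d$max),
         scope = scope),
    class = "normalized_indicators"
  )
}

#' Composite annual hazard score
#'
#' Equal-weight mean of the three normalized indicators:
#' `hazard = (HWF_n + HWMD_n + HWMHI_n) / 3`, per pixel and year, in
#' `[0, 1]`. A pixel-year scores 1 exactly when all three indicators attain
#' their normalization maxima there, and 0 where no heatwave ever occurs.
#'
#' @param nind A [normalize_indicators()] result.
#' @return Object of class `"hazard_surface"`: `hazard` array
#'   `(n_years, ny, nx)`, `years`, `maxima`.
#' @export
hazard_score <- function(nind) {
  stopifnot(inherits(nind, "normalized_indicators"))
  rng <- range(c(nind$hwf, nind$hwmhi, nind$hwmd), na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 1) {
    stop("normalized indicators must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(hazard = (nind$hwf + nind$hwmd + nind$hwmhi) / 3,
         years = nind$years, maxima = nind$maxima),
    class = "hazard_surface"
  )
}

#' @export
print.hazard_surface <- function(x, ...) {
  cat("<hazard_surface>\n")
  cat(sprintf("  %d years x %d x %d pixels; hazard in [%.3f, %.3f]\n",
              dim(x$hazard)[1L], dim(x$hazard)[2L], dim(x$hazard)[3L],
              min(x$hazard, na.rm = TRUE), max(x$hazard, na.rm = TRUE)))
  invisible(x)
}

#' Average hazard (AH) per pixel
#'
#' Arithmetic mean of the annual hazard over years; the quantity that is
#' mapped, classified and ranked.
#'
#' @param hz A [hazard_score()] result.
#' @return `ny x nx` matrix of AH in `[0, 1]`.
#' @export
average_hazard <- function(hz) {
  stopifnot(inherits(hz, "hazard_surface"))
  apply(hz$hazard, c(2L, 3L), mean)
}

#' Linear trend of an annual series
#'
#' Ordinary least squares of value on year: slope (units per year), two-sided
#' p from the t distribution, and R-squared, plus a significance flag at
#' `alpha`. A constant series has slope 0, R-squared 0 and is reported as
#' non-significant (p = 1).
#'
#' @param values Numeric vector, one value per year.
#' @param years Numeric vector of years (length >= 3, non-constant).
#' @param alpha Significance level for the flag.
#' @return List with `slope`, `intercept`, `p`, `r2`, `significant`.
#' @export
linear_trend <- function(values, years, alpha = 0.05) {
  ok <- is.finite(values) & is.finite(years)
  values <- values[ok]; years <- years[ok]
  n <- length(values)
  if (n < 3L || length(unique(years)) < 2L) {
    return(list(slope = NA_real_, intercept = NA_real_, p = NA_real_,
                r2 = NA_real_, significant = NA))
  }
  xc <- years - mean(years)
  sxx <- sum(xc^2)
  slope <- sum(xc * values) / sxx
  intercept <- mean(values) - slope * mean(years)
  fitted <- intercept + slope * years
  sse <- sum((values - fitted)^2)
  sst <- sum((values - mean(values))^2)
  if (sst <= 0) {
    return(list(slope = 0, intercept = mean(values), p = 1, r2 = 0,
                significant = FALSE))
  }
  se <- sqrt(sse / (n - 2L) / sxx)
  p <- if (se > 0) 2 * pt(-abs(slope / se), df = n - 2L) else 0
  list(slope = slope, intercept = intercept, p = p, r2 = 1 - sse / sst,
       significant = p < alpha)
}

#' Per-pixel linear trend surface
#'
#' Vectorised OLS of an annual stack on the year axis, giving per-pixel
#' slope, two-sided p, R-squared and a significance mask at `alpha`.
#'
#' @param values Array `(n_years, ny, nx)` (e.g. the hazard stack or an
#'   indicator).
#' @param years Numeric year axis (length `n_years`, >= 3).
#' @param alpha Significance level for the mask.
#' @return Object of class `"trend_surface"`: matrices `slope`, `p`, `r2`,
#'   logical `significant`, plus `alpha`.
#' @export
trend_surface <- function(values, years, alpha = 0.05) {
  d <- dim(values)
  if (length(d) != 3L || d[1L] != length(years)) {
    stop("`values` must be (n_years, ny, nx) aligned with `years`",
         call. = FALSE)
  }
  n <- length(years)
  if (n < 3L) stop("need at least 3 years for a trend", call. = FALSE)
  Y <- matrix(values, nrow = n)            # n_years x n_pixels
  xc <- years - mean(years)
  sxx <- sum(xc^2)
  slope <- as.vector(crossprod(Y, xc)) / sxx
  ybar <- colMeans(Y)
  fitted <- outer(xc, slope) + rep(ybar, each = n)
  sse <- colSums((Y - fitted)^2)
  sst <- colSums((Y - rep(ybar, each = n))^2)
  se2 <- sse / (n - 2L) / sxx
  tstat <- ifelse(se2 > 0, slope / sqrt(se2), ifelse(slope == 0, 0, Inf))
  p <- ifelse(sst > 0, 2 * pt(-abs(tstat), df = n - 2L), 1)
  p[sst > 0 & se2 <= 0] <- 0               # exact non-constant line
  r2 <- ifelse(sst > 0, 1 - sse / sst, 0)
  slope[sst <= 0] <- 0
  shape <- c(d[2L], d[3L])
  structure(
    list(slope = matrix(slope, shape[1L], shape[2L]),
         p = matrix(p, shape[1L], shape[2L]),
         r2 = matrix(r2, shape[1L], shape[2L]),
         significant = matrix(p < alpha, shape[1L], shape[2L]),
         alpha = alpha, years = years),
    class = "trend_surface"
  )
}

#' @export
print.trend_surface <- function(x, ...) {
  cat("<trend_surface>\n")
  cat(sprintf("  slope range [%.4g, %.4g] per year; %.1f%% of pixels significant at alpha = %g\n",
              min(x$slope, na.rm = TRUE), max(x$slope, na.rm = TRUE),
              100 * mean(x$significant, na.rm = TRUE), x$alpha))
  invisible(x)
}

#' Relative change between the first and last five years
#'
#' `RC = (mean over the last window - mean over the first window) / mean over
#' the full period`, a dimensionless change measure that is invariant to
#' rescaling the whole series. For a 30-year study the windows default to the
#' first and last five years. `RC > 0.8` is read as a sharp increase.
#'
#' @param values Numeric vector of annual values.
#' @param years Integer years aligned with `values`.
#' @param fy_years,ly_years Year vectors of the first and last windows
#'   (default: first and last five of `years`); must be disjoint and covered
#'   by `years`.
#' @return The RC value; `NA` with a warning when the full-period mean is
#'   zero.
#' @examples
#' relative_change(c(rep(10, 5), rep(11, 20), rep(12, 5)), 1990:2019)
#' @export
relative_change <- function(values, years,
                            fy_years = head(sort(years), 5L),
                            ly_years = utils::tail(sort(years), 5L)) {
  if (length(values) != length(years)) {
    stop("`values` and `years` must be aligned", call. = FALSE)
  }
  if (length(intersect(fy_years, ly_years)) > 0L) {
    stop("FY and LY windows must be disjoint", call. = FALSE)
  }
  if (!all(c(fy_years, ly_years) %in% years)) {
    stop("FY/LY windows must be covered by `years`", call. = FALSE)
  }
  full_mean <- mean(values)
  if (!is.finite(full_mean) || full_mean == 0) {
    warning("full-period mean is zero; RC undefined", call. = FALSE)
    return(NA_real_)
  }
  (mean(values[years %in% ly_years]) - mean(values[years %in% fy_years])) /
    full_mean
}
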