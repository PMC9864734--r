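#' Fisher-Jenks natural breaks
#'
#' Exact optimal 1-D classification into `k` classes minimizing the total
#' within-class sum of squared deviations, by dynamic programming over the
#' sorted values (O(k n^2)); deterministic, unlike the iterative
#' Jenks-Caspall heuristic.
#'
#' @param values Numeric vector (`NA`s dropped); must contain at least `k`
#'   distinct values.
#' @param k Number of classes (>= 1).
#' @param labels Optional character vector of `k` ordered class labels (low
#'   to high).
#' @return Object of class `"breaks_scheme"`: `k`, `breaks` (the `k - 1`
#'   ascending cut values, each the maximum of its class), `labels`, and the
#'   achieved `within_ss`.
#' @examples
#' jenks_breaks(c(1, 2, 3, 10, 11, 12), 2)$breaks  # 3
#' @export
jenks_breaks <- function(values, k, labels = NULL) {
  v <- sort(values[!is.na(values)])
  n <- length(v)
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  if (length(unique(v)) < k) {
    stop("`k` exceeds the number of distinct values", call. = FALSE)
  }
  if (!is.null(labels) && length(labels) != k) {
    stop("`labels` must have length `k`", call. = FALSE)
  }
  cs <- c(0, cumsum(v))
  cs2 <- c(0, cumsum(v^2))
  ssd <- function(i, j) {         # within-SS of v[i..j]
    s <- cs[j + 1L] - cs[i]
    cs2[j + 1L] - cs2[i] - s^2 / (j - i + 1L)
  }
  # cost[j]: optimal within-SS of v[1..j] using the current number of classes
  cost <- vapply(seq_len(n), function(j) ssd(1L, j), numeric(1L))
  back <- matrix(1L, k, n)        # back[c, j]: start index of the last class
  if (k > 1L) {
    for (cls in 2:k) {
      new_cost <- rep(Inf, n)
      for (j in cls:n) {
        for (s in cls:j) {        # last class is v[s..j]
          val <- cost[s - 1L] + ssd(s, j)
          if (val < new_cost[j]) {
            new_cost[j] <- val
            back[cls, j] <- s
          }
        }
      }
      cost <- new_cost
    }
  }
  # recover class boundaries
  ends <- integer(k)
  j <- n
  for (cls in k:1L) {
    ends[cls] <- j
    j <- back[cls, j] - 1L
  }
  breaks <- if (k > 1L) v[ends[-k]] else numeric(0)
  structure(
    list(k = k, breaks = breaks,
         labels = labels %||% paste0("class", seq_len(k)),
         within_ss = cost[n], range = range(v)),
    class = "breaks_scheme"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.breaks_scheme <- function(x, ...) {
  cat(sprintf("<breaks_scheme> k = %d, within-SS = %.4g\n", x$k, x$within_ss))
  if (x$k > 1L) {
    cat("  cuts:", paste(signif(x$breaks, 6), collapse = ", "), "\n")
  }
  cat("  labels:", paste(x$labels, collapse = " < "), "\n")
  invisible(x)
}

#' Assign values to natural-breaks classes
#'
#' Intervals are right-closed at each cut (a value equal to a cut value falls
#' in the lower class) and unbounded at both ends, so every finite value maps
#' to exactly one class. Non-finite values get `NA`.
#'
#' @param values Numeric vector, matrix or array.
#' @param scheme A [jenks_breaks()] result.
#' @return Ordered factor of class labels, same shape as `values` (dim
#'   preserved for matrices via an integer-coded matrix wrapped in labels
#'   attribute; use the returned factor for vectors).
#' @export
classify_values <- function(values, scheme) {
  stopifnot(inherits(scheme, "breaks_scheme"))
  idx <- rep(NA_integer_, length(values))
  ok <- is.finite(values)
  # left.open: intervals (cut_i, cut_{i+1}], so a value equal to a cut falls
  # in the lower class
  idx[ok] <- findInterval(values[ok], scheme$breaks, left.open = TRUE) + 1L
  out <- factor(scheme$labels[idx], levels = scheme$labels, ordered = TRUE)
  if (!is.null(dim(values))) {
    out <- array(as.character(out), dim(values))
  }
  out
}

#' Five-level spatial hazard labels
#' @keywords internal
#' @export
spatial_labels <- function() {
  c("low", "medium-low", "middle", "medium-high", "high")
}

#' Five-level temporal trend labels
#' @keywords internal
#' @export
temporal_labels <- function() {
  c("decreased", "slightly decreased", "basically unchanged",
    "slightly increased", "increased")
}

#' Classify average hazard into five spatial levels
#'
#' Natural-breaks classification of AH into low ... high.
#'
#' @param ah Matrix of average hazard (from [average_hazard()]).
#' @param k Number of classes (default 5).
#' @return List: `classes` (character matrix of labels), `scheme`.
#' @export
classify_hazard <- function(ah, k = 5L) {
  scheme <- jenks_breaks(as.vector(ah), k, labels = spatial_labels()[seq_len(k)])
  list(classes = classify_values(ah, scheme), scheme = scheme)
}

#' Classify hazard trends into five temporal levels
#'
#' Natural-breaks classification of the per-pixel trend slope into
#' decreased ... increased, fitted on the pixels passing the significance
#' mask; non-significant pixels are labelled "basically unchanged" (no
#' demonstrated trend).
#'
#' @param trend A [trend_surface()] result.
#' @param k Number of classes (default 5).
#' @return List: `classes` (character matrix), `scheme` (fitted on
#'   significant slopes only).
#' @export
classify_trend <- function(trend, k = 5L) {
  stopifnot(inherits(trend, "trend_surface"))
  labs <- temporal_labels()
  sig <- trend$significant & is.finite(trend$slope)
  if (sum(sig, na.rm = TRUE) < k || length(unique(trend$slope[sig])) < k) {
    classes <- matrix("basically unchanged", nrow(trend$slope),
                      ncol(trend$slope))
    classes[!is.finite(trend$slope)] <- NA_character_
    return(list(classes = classes, scheme = NULL))
  }
  scheme <- jenks_breaks(trend$slope[sig], k, labels = labs[seq_len(k)])
  classes <- matrix(NA_character_, nrow(trend$slope), ncol(trend$slope))
  classes[which(sig)] <- as.character(classify_values(trend$slope[sig],
                                                      scheme))
  classes[!sig & is.finite(trend$slope)] <- "basically unchanged"
  list(classes = classes, scheme = scheme)
}

#' Default spatial x temporal category table
#'
#' Maps the 5 x 5 cross of spatial and temporal labels to the four
#' spatiotemporal hazard categories: 1 "high hazard and rapidly increasing"
#' ({high, medium-high} x {increased, slightly increased}); 2 "high hazard
#' and decreasing or unchanged" ({high, medium-high} x the rest); 3 "low
#' hazard and continually increasing" ({middle, medium-low, low} x
#' {increased, slightly increased}); 4 "others". The table is an argument of
#' [spatiotemporal_category()] so the band assignment can be overridden.
#'
#' @return 5 x 5 integer matrix, rows = spatial labels, columns = temporal
#'   labels.
#' @export
default_category_table <- function() {
  sp <- spatial_labels(); tp <- temporal_labels()
  m <- matrix(4L, 5L, 5L, dimnames = list(sp, tp))
  up <- c("slightly increased", "increased")
  m[c("high", "medium-high"), up] <- 1L
  m[c("high", "medium-high"), setdiff(tp, up)] <- 2L
  m[c("low", "medium-low", "middle"), up] <- 3L
  m
}

#' Spatiotemporal hazard category
#'
#' Crosses a spatial hazard label with a temporal trend label through the
#' category table (default [default_category_table()]). Vectorised;
#' `NA` labels give `NA`.
#'
#' @param spatial Character vector/matrix of spatial labels.
#' @param temporal Character vector/matrix of temporal labels (same shape).
#' @param table Category table (rows = spatial labels, columns = temporal).
#' @return Integer categories 1-4, same shape as the inputs.
#' @examples
#' spatiotemporal_category("high", "increased")  # 1
#' @export
spatiotemporal_category <- function(spatial, temporal,
                                    table = default_category_table()) {
  if (length(spatial) != length(temporal)) {
    stop("label vectors must be aligned", call. = FALSE)
  }
  ri <- match(spatial, rownames(table))
  ci <- match(temporal, colnames(table))
  bad <- (!is.na(spatial) & is.na(ri)) | (!is.na(temporal) & is.na(ci))
  if (any(bad)) {
    stop("unknown class label(s): ",
         paste(unique(c(spatial[is.na(ri) & !is.na(spatial)],
                        temporal[is.na(ci) & !is.na(temporal)])),
               collapse = ", "),
         call. = FALSE)
  }
  out <- rep(NA_integer_, length(spatial))
  ok <- !is.na(ri) & !is.na(ci)
  out[ok] <- table[cbind(ri[ok], ci[ok])]
  if (!is.null(dim(spatial))) dim(out) <- dim(spatial)
  out
}
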