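# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by the most literal route available, without calling the
# package implementations they check.

# Literal one-third plotting-position quantile: sort, index, interpolate.
quantile_oracle <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- p * n + (1 + p) / 3
  j <- floor(h)
  if (j < 1) return(xs[1])
  if (j >= n) return(xs[n])
  g <- h - j
  (1 - g) * xs[j] + g * xs[j + 1]
}

# Scan a binary vector element by element and collect maximal runs of 1s.
runs_oracle <- function(mask) {
  starts <- integer(0)
  lens <- integer(0)
  in_run <- FALSE
  for (i in seq_along(mask)) {
    if (mask[i] == 1L) {
      if (!in_run) {
        starts <- c(starts, i)
        lens <- c(lens, 0L)
        in_run <- TRUE
      }
      lens[length(lens)] <- lens[length(lens)] + 1L
    } else {
      in_run <- FALSE
    }
  }
  data.frame(start = starts, length = lens)
}

# Daily heat index for day t of a run, composed from first principles.
hi_oracle <- function(delta, t) {
  k <- t - 1
  out <- 1.2 * delta[t]
  if (k >= 1) {
    for (i in 1:k) out <- out + 0.35 * delta[t - i] / i
  }
  if (k >= 2) {
    for (i in 1:(k - 1)) out <- out + 0.15 / (i + 1)
  }
  out
}

# Minimum within-class SS over every contiguous partition of sorted v into k
# groups (exhaustive enumeration of split points).
jenks_oracle_ss <- function(v, k) {
  v <- sort(v)
  n <- length(v)
  ss <- function(g) sum((g - mean(g))^2)
  if (k == 1L) return(ss(v))
  best <- Inf
  splits <- utils::combn(n - 1L, k - 1L)
  for (col in seq_len(ncol(splits))) {
    cuts <- c(0L, splits[, col], n)
    total <- 0
    for (cls in seq_len(k)) {
      total <- total + ss(v[(cuts[cls] + 1L):cuts[cls + 1L]])
    }
    best <- min(best, total)
  }
  best
}

# All non-decreasing integer sequences of length n over alphabet 1..a.
multisets <- function(n, a) {
  if (n == 1L) return(matrix(seq_len(a), ncol = 1L))
  prev <- multisets(n - 1L, a)
  out <- list()
  for (i in seq_len(nrow(prev))) {
    last <- prev[i, n - 1L]
    for (v in last:a) out[[length(out) + 1L]] <- c(prev[i, ], v)
  }
  do.call(rbind, out)
}

# Small station-free config used by several tests.
tiny_config <- function(...) {
  synthetic_config(seed = 11, ny = 2L, nx = 2L, years = 2001:2003, ...)
}

# A hand-built single-pixel climate grid from explicit MT/RH day values.
grid_1px <- function(mt, rh, years) {
  dates <- season_dates(years)
  stopifnot(length(mt) == length(dates))
  climate_grid(array(mt, c(length(mt), 1L, 1L)),
               array(rh, c(length(rh), 1L, 1L)),
               dates, lon = 0, lat = 0)
}
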