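#' Configuration for the synthetic climate generator
#'
#' Defines a reproducible synthetic study: a regular lon/lat grid (and
#' optionally stations), a multi-year extended-summer period, a smooth
#' seasonal temperature cycle with day-to-day autocorrelated anomalies,
#' humidity weakly coupled to the temperature anomaly, and a set of injected
#' multi-day heat episodes with known location, timing and magnitude.
#'
#' Temperature follows `seasonal cycle + AR(1) anomaly`; the anomaly has
#' stationary standard deviation `anomaly_sd` and lag-1 autocorrelation
#' `anomaly_ar`, restarted each season. Humidity is a clipped Gaussian
#' `rh_mean + rh_coupling * anomaly + noise`; a negative coupling makes hot
#' spells drier (the default), a positive one makes them more humid.
#'
#' Episodes are injected on top of the background: on each episode day MT is
#' raised to at least `episode_mt_floor` plus a margin proportional to the
#' episode's `exceedance` (so the day's torridity index clears the local
#' threshold by at least that many index units), and the single day on either
#' side is capped at `guard_mt_cap` so the injected run has unambiguous
#' boundaries. The background fields never depend on the episode list, so an
#' episode-free run with the same seed gives the identical background.
#'
#' @param seed Integer random seed; the generator is fully deterministic given
#'   the config.
#' @param ny,nx Grid shape (rows = latitudes, columns = longitudes).
#' @param cell_size Grid spacing in degrees.
#' @param origin `c(lon, lat)` of the first grid cell centre.
#' @param years Integer vector of calendar years (inclusive range).
#' @param baseline Seasonal-minimum mean temperature, degrees C.
#' @param amplitude Seasonal half-range, degrees C: the seasonal mean peaks at
#'   `baseline + amplitude` in mid-season.
#' @param anomaly_ar AR(1) coefficient of daily anomalies, in `[0, 1)`.
#' @param anomaly_sd Stationary standard deviation of anomalies, degrees C
#'   (> 0; may be set to 0 for the noise-free limit).
#' @param rh_mean,rh_sd Humidity mean and noise standard deviation, %.
#' @param rh_coupling Humidity response to a +1 degree C temperature anomaly,
#'   percentage points.
#' @param episodes `NULL`, or a data frame of injected episodes with columns
#'   `x`, `y` (pixel indices) or `station` (station id), `year`,
#'   `start` (day-of-season, 1-153), `duration` (days >= 1) and optionally
#'   `exceedance` (index units, default `default_exceedance`).
#' @param stations `NULL`, or a data frame with columns `station_id`, `lon`,
#'   `lat`, `elev` declaring point stations.
#' @param episode_mt_floor Minimum MT (degrees C) forced on episode days
#'   before the exceedance margin is added.
#' @param guard_mt_cap MT cap (degrees C) on the guard day each side of an
#'   episode.
#' @param default_exceedance Default torridity-index margin for episodes that
#'   do not specify one.
#' @return An object of class `"synthetic_config"`.
#' @seealso [synthetic_climate_grid()], [synthetic_station_series()],
#'   [truth_catalog()]
#' @export
synthetic_config <- function(seed = 1L,
                             ny = 10L, nx = 10L,
                             cell_size = 0.5,
                             origin = c(100, 30),
                             years = 1990:2019,
                             baseline = 26,
                             amplitude = 7,
                             anomaly_ar = 0.7,
                             anomaly_sd = 2.5,
                             rh_mean = 60,
                             rh_sd = 8,
                             rh_coupling = -2,
                             episodes = NULL,
                             stations = NULL,
                             episode_mt_floor = 40,
                             guard_mt_cap = 26,
                             default_exceedance = 8) {
  ny <- as.integer(ny); nx <- as.integer(nx)
  if (ny < 1L || nx < 1L) stop("grid shape must be positive", call. = FALSE)
  years <- as.integer(years)
  if (length(years) < 1L) stop("`years` must be non-empty", call. = FALSE)
  if (anomaly_ar < 0 || anomaly_ar >= 1) {
    stop("`anomaly_ar` must lie in [0, 1)", call. = FALSE)
  }
  if (anomaly_sd < 0) stop("`anomaly_sd` must be >= 0", call. = FALSE)
  if (!is.null(episodes)) {
    episodes <- as.data.frame(episodes)
    need <- c("year", "start", "duration")
    if (!all(need %in% names(episodes))) {
      stop("`episodes` needs columns year, start, duration", call. = FALSE)
    }
    if (!("exceedance" %in% names(episodes))) {
      episodes$exceedance <- default_exceedance
    }
    if (any(episodes$duration < 1L)) {
      stop("episode duration must be >= 1 day", call. = FALSE)
    }
    if (any(episodes$start < 1L |
            episodes$start + episodes$duration - 1L > SEASON_LENGTH)) {
      stop("episodes must lie within the May-September window", call. = FALSE)
    }
    if (!any(c("x", "station") %in% names(episodes))) {
      stop("`episodes` needs pixel columns x/y or a station column",
           call. = FALSE)
    }
    if (!all(episodes$year %in% years)) {
      stop("episode years must be generated years", call. = FALSE)
    }
  }
  if (!is.null(stations)) {
    stations <- as.data.frame(stations)
    if (!all(c("station_id", "lon", "lat") %in% names(stations))) {
      stop("`stations` needs columns station_id, lon, lat", call. = FALSE)
    }
    if (is.null(stations$elev)) stations$elev <- 0
  }
  structure(
    list(seed = as.integer(seed), ny = ny, nx = nx, cell_size = cell_size,
         origin = origin, years = years, baseline = baseline,
         amplitude = amplitude, anomaly_ar = anomaly_ar,
         anomaly_sd = anomaly_sd, rh_mean = rh_mean, rh_sd = rh_sd,
         rh_coupling = rh_coupling, episodes = episodes, stations = stations,
         episode_mt_floor = episode_mt_floor, guard_mt_cap = guard_mt_cap,
         default_exceedance = default_exceedance),
    class = "synthetic_config"
  )
}

#' Seasonal mean temperature for a day of season
#'
#' Half-sine over the 153-day window: `baseline` at the season edges,
#' `baseline + amplitude` at mid-season. This is the noise-free limit of the
#' generated MT.
#'
#' @param config A [synthetic_config()].
#' @param day Day-of-season index, 1-153 (vectorised).
#' @return Mean MT in degrees C.
#' @export
seasonal_cycle <- function(config, day) {
  config$baseline + config$amplitude * sin(pi * (day - 0.5) / SEASON_LENGTH)
}

# Evaluate `expr` under a private RNG stream without disturbing the caller's.
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# AR(1) anomaly series restarted each season, stationary sd = sd.
ar1_seasons <- function(n_years, phi, sd) {
  n <- n_years * SEASON_LENGTH
  if (sd == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - phi^2)
  out <- numeric(n)
  for (s in seq_len(n_years)) {
    i0 <- (s - 1L) * SEASON_LENGTH
    a <- rnorm(1L, 0, sd)
    out[i0 + 1L] <- a
    eps <- rnorm(SEASON_LENGTH - 1L, 0, innov_sd)
    for (t in 2:SEASON_LENGTH) {
      a <- phi * a + eps[t - 1L]
      out[i0 + t] <- a
    }
  }
  out
}

# Background MT/RH for one location from an already-seeded RNG stream.
background_series <- function(config) {
  n_years <- length(config$years)
  dos <- rep(seq_len(SEASON_LENGTH), n_years)
  anom <- ar1_seasons(n_years, config$anomaly_ar, config$anomaly_sd)
  mt <- seasonal_cycle(config, dos) + anom
  rh_noise <- if (config$rh_sd > 0) {
    rnorm(length(mt), 0, config$rh_sd)
  } else numeric(length(mt))
  rh <- config$rh_mean + config$rh_coupling * anom + rh_noise
  list(mt = mt, rh = pmin(100, pmax(0, rh)))
}

# Apply injected episodes (already merged per location-year) to one series.
inject_episodes <- function(mt, years_axis, truth, config) {
  if (is.null(truth) || nrow(truth) == 0L) return(mt)
  for (i in seq_len(nrow(truth))) {
    yr <- truth$year[i]
    base <- which(years_axis == yr)[1L] - 1L
    idx <- base + seq(truth$start[i], length.out = truth$duration[i])
    # dry-branch TI slope in MT is 1.8 * (1 - 0.55 * 0.4) = 1.404 index/degC;
    # raising MT by exceedance/1.404 above the floor guarantees the margin
    mt[idx] <- pmax(mt[idx], config$episode_mt_floor) +
      truth$exceedance[i] / 1.404
    g <- c(base + truth$start[i] - 1L,
           base + truth$start[i] + truth$duration[i])
    g <- g[g >= base + 1L & g <= base + SEASON_LENGTH]
    mt[g] <- pmin(mt[g], config$guard_mt_cap)
  }
  mt
}

#' Generate a synthetic daily climate grid
#'
#' Produces one MT and one RH layer per day of each extended summer
#' (May 1 - September 30) of the configured years, with any configured heat
#' episodes injected. Identical config (including seed) gives bit-identical
#' output; the background fields do not depend on the episode list.
#'
#' @param config A [synthetic_config()].
#' @return A [climate_grid()].
#' @examples
#' cfg <- synthetic_config(seed = 42, ny = 3, nx = 3, years = 2000:2001)
#' g <- synthetic_climate_grid(cfg)
#' dim(g$mt)  # 306 x 3 x 3
#' @export
synthetic_climate_grid <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n_years <- length(config$years)
  nt <- n_years * SEASON_LENGTH
  dates <- season_dates(config$years)
  years_axis <- as.integer(format(dates, "%Y"))
  truth_all <- truth_catalog(config)
  mt <- array(NA_real_, c(nt, config$ny, config$nx))
  rh <- array(NA_real_, c(nt, config$ny, config$nx))
  with_private_seed(config$seed, {
    for (x in seq_len(config$nx)) {
      for (y in seq_len(config$ny)) {
        bg <- background_series(config)
        tr <- if (nrow(truth_all) > 0L && "x" %in% names(truth_all)) {
          truth_all[!is.na(truth_all$x) & truth_all$x == x & truth_all$y == y, ]
        } else truth_all[0L, ]
        mt[, y, x] <- inject_episodes(bg$mt, years_axis, tr, config)
        rh[, y, x] <- bg$rh
      }
    }
  })
  lon <- config$origin[1L] + (seq_len(config$nx) - 1L) * config$cell_size
  lat <- config$origin[2L] + (seq_len(config$ny) - 1L) * config$cell_size
  climate_grid(mt, rh, dates, lon, lat)
}

#' Generate a synthetic station series
#'
#' Station analogue of [synthetic_climate_grid()]: a date-sorted daily MT/RH
#' table for one declared station, restricted to the May-September windows.
#' Each station draws from its own seed offset so stations are independent,
#' and a station's background is unchanged by the episode list.
#'
#' @param config A [synthetic_config()] with a `stations` table.
#' @param station_id Id of a declared station.
#' @return A data frame (`station_id`, `date`, `mt`, `rh`), one row per
#'   season day.
#' @export
synthetic_station_series <- function(config, station_id) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(config$stations) ||
      !station_id %in% config$stations$station_id) {
    stop(sprintf("station '%s' is not declared in the config", station_id),
         call. = FALSE)
  }
  k <- match(station_id, config$stations$station_id)
  dates <- season_dates(config$years)
  years_axis <- as.integer(format(dates, "%Y"))
  truth_all <- truth_catalog(config)
  tr <- if (nrow(truth_all) > 0L && "station" %in% names(truth_all)) {
    truth_all[!is.na(truth_all$station) & truth_all$station == station_id, ]
  } else truth_all[0L, ]
  ser <- with_private_seed(config$seed + 7919L * k, background_series(config))
  mt <- inject_episodes(ser$mt, years_axis, tr, config)
  data.frame(station_id = station_id, date = dates, mt = mt, rh = ser$rh)
}

#' Ground-truth catalog of injected episodes
#'
#' One record per injected episode, with overlapping or contiguous episodes on
#' the same location and year merged into a single record spanning their union
#' (contiguous injections form one uninterrupted hot run, which is what the
#' detector can see). Records are sorted by (year, start).
#'
#' @param config A [synthetic_config()].
#' @return A data frame with the location columns of `config$episodes` plus
#'   `year`, `start`, `duration`, `exceedance` (the maximum over merged
#'   members). Zero rows when no episodes are configured.
#' @export
truth_catalog <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ep <- config$episodes
  if (is.null(ep) || nrow(ep) == 0L) {
    return(data.frame(year = integer(), start = integer(),
                      duration = integer(), exceedance = numeric()))
  }
  loc_key <- if ("station" %in% names(ep)) {
    as.character(ep$station)
  } else paste(ep$x, ep$y, sep = ",")
  out <- list()
  for (key in split(seq_len(nrow(ep)), paste(loc_key, ep$year))) {
    sub <- ep[key, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    cur <- sub[1L, , drop = FALSE]
    cur_end <- cur$start + cur$duration - 1L
    for (i in seq_len(nrow(sub))[-1L]) {
      s <- sub$start[i]; e <- s + sub$duration[i] - 1L
      if (s <= cur_end + 1L) {       # overlap or contiguity: one hot run
        cur_end <- max(cur_end, e)
        cur$exceedance <- max(cur$exceedance, sub$exceedance[i])
      } else {
        cur$duration <- cur_end - cur$start + 1L
        out[[length(out) + 1L]] <- cur
        cur <- sub[i, , drop = FALSE]
        cur_end <- e
      }
    }
    cur$duration <- cur_end - cur$start + 1L
    out[[length(out) + 1L]] <- cur
  }
  res <- do.call(rbind, out)
  res <- res[order(res$year, res$start), , drop = FALSE]
  res$year <- as.integer(res$year)
  res$start <- as.integer(res$start)
  res$duration <- as.integer(res$duration)
  rownames(res) <- NULL
  res
}

#' Randomly place non-interacting episodes on a grid
#'
#' Convenience sampler for recovery experiments: draws `n` episodes on
#' distinct pixels (so no two episodes can merge or share guard days), with
#' uniform years, durations and start days that keep each episode inside the
#' season.
#'
#' @param config A [synthetic_config()] (supplies grid shape and years).
#' @param n Number of episodes; must not exceed `ny * nx`.
#' @param durations Integer vector of candidate durations (days).
#' @param seed Integer seed for the placement draw.
#' @param exceedance Torridity-index margin for every placed episode.
#' @return An `episodes` data frame suitable for [synthetic_config()].
#' @export
sample_episode_placements <- function(config, n, durations, seed = 1L,
                                      exceedance = config$default_exceedance) {
  stopifnot(inherits(config, "synthetic_config"))
  npix <- config$ny * config$nx
  if (n > npix) {
    stop("cannot place more episodes than pixels without interaction",
         call. = FALSE)
  }
  with_private_seed(seed, {
    pix <- sample.int(npix, n)
    dur <- sample(rep(durations, length.out = n))
    data.frame(
      x = ((pix - 1L) %/% config$ny) + 1L,
      y = ((pix - 1L) %% config$ny) + 1L,
      year = sample(config$years, n, replace = TRUE),
      start = vapply(dur, function(d) {
        sample.int(SEASON_LENGTH - d + 1L, 1L)
      }, integer(1L)),
      duration = dur,
      exceedance = exceedance
    )
  })
}
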