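make_threshold <- function(ti_prime_matrix) {
  structure(list(ti_prime = ti_prime_matrix,
                 n_hot = matrix(100L, nrow(ti_prime_matrix),
                                ncol(ti_prime_matrix)),
                 valid = !is.na(ti_prime_matrix),
                 hot_sample_cutoff = 33, p = 0.5, min_samples = 10L),
            class = "threshold_field")
}

test_that("hot-day mask applies the >= convention and masks invalid pixels", {
  thr <- make_threshold(matrix(c(90, NA), 1, 2))
  ti <- array(c(89, 90, 91, 95, 96, 97), c(3, 1, 2))
  m <- hot_day_mask(ti, thr)
  expect_identical(m[, 1, 1], c(0L, 1L, 1L))   # equality counts as hot
  expect_true(all(is.na(m[, 1, 2])))           # no threshold, no mask
  low <- array(80, c(3, 1, 2))
  expect_identical(hot_day_mask(low, thr)[, 1, 1], rep(0L, 3))
  expect_error(hot_day_mask(array(1, c(2, 2, 2)), thr), "shapes")
})

test_that("hot-day mask agrees with the elementwise oracle on random fields", {
  set.seed(12)
  tp <- matrix(runif(6, 85, 95), 2, 3)
  ti <- array(runif(5 * 6, 80, 100), c(5, 2, 3))
  thr <- make_threshold(tp)
  m <- hot_day_mask(ti, thr)
  for (t in 1:5) for (y in 1:2) for (x in 1:3) {
    expect_identical(m[t, y, x], as.integer(ti[t, y, x] >= tp[y, x]))
  }
})

test_that("find_runs reproduces hand-enumerated runs", {
  r <- find_runs(c(0, 1, 1, 1, 0))
  expect_identical(r$start, 2L)
  expect_identical(r$length, 3L)
  r2 <- find_runs(c(1, 1, 0, 1))
  expect_identical(r2$start, c(1L, 4L))
  expect_identical(r2$length, c(2L, 1L))
  expect_identical(nrow(find_runs(rep(0, 6))), 0L)
  expect_error(find_runs(c(0, 2, 1)), "binary")
})

test_that("find_runs matches the brute-force scan on all short masks", {
  for (n in 1:8) {
    for (code in 0:(2^n - 1)) {
      mask <- as.integer(intToBits(code)[1:n])
      expect_identical(find_runs(mask), runs_oracle(mask))
    }
  }
})

test_that("detection enforces the duration and HWI filters", {
  dates <- season_dates(2010)
  tp <- 90
  ti <- rep(80, 153)
  # 2-day run, however hot, is never an event
  ti[20:21] <- 120
  ev <- detect_events(ti, tp, dates)
  expect_identical(nrow(ev), 0L)
  # 3-day run with large exceedance passes both filters
  ti <- rep(80, 153)
  ti[30:32] <- tp + 2.5                 # daily HI 3.0, 3.875, 4.3875
  ev <- detect_events(ti, tp, dates)
  expect_identical(nrow(ev), 1L)
  delta <- rep(2.5, 3)
  his <- vapply(1:3, function(t) hi_oracle(delta, t), numeric(1))
  expect_equal(ev$hwi, mean(his))
  expect_equal(ev$max_hi, max(his))
  expect_identical(ev$duration, 3L)
  expect_identical(ev$start, 30L)
  expect_identical(ev$year, 2010L)
  # 3-day run with mean HI below 2.8 is rejected
  ti <- rep(80, 153)
  ti[30:32] <- tp + 1                   # daily HI 1.2, 1.55, 1.8
  expect_identical(nrow(detect_events(ti, tp, dates)), 0L)
})

test_that("sum-mode HWI is duration times mean-mode HWI", {
  set.seed(77)
  dates <- season_dates(2005:2006)
  ti <- 85 + as.vector(stats::filter(rnorm(306, 0, 4), 0.7,
                                     method = "recursive"))
  ev_mean <- detect_events(ti, 88, dates, hwi_threshold = 0)
  ev_sum <- detect_events(ti, 88, dates, hwi_threshold = 0, hwi_mode = "sum")
  expect_gt(nrow(ev_mean), 0L)
  expect_equal(ev_sum$hwi, ev_mean$duration * ev_mean$hwi)
})

test_that("runs never bridge the September-to-May gap", {
  dates <- season_dates(2010:2011)
  ti <- rep(80, 306)
  ti[150:156] <- 95                     # 4 hot days end of 2010 + 3 in 2011
  ev <- detect_events(ti, 90, dates)
  expect_identical(nrow(ev), 2L)
  expect_identical(ev$year, c(2010L, 2011L))
  expect_identical(ev$duration, c(4L, 3L))
  expect_identical(ev$start, c(150L, 1L))
})

test_that("events are attributed to the year of their start date", {
  dates <- season_dates(2010)
  ti <- rep(80, 153); ti[151:153] <- 95
  ev <- detect_events(ti, 90, dates)
  expect_identical(ev$year, 2010L)
  expect_identical(ev$end_date, as.Date("2010-09-30"))
})

test_that("annual indicators follow the running-max update rules", {
  ev <- data.frame(year = c(2001L, 2001L), y = 1L, x = 1L,
                   start = c(10L, 60L), duration = c(3L, 5L),
                   max_hi = c(4, 6), hwi = c(3, 5))
  ind <- annual_indicators(ev, 2001:2002, 1, 1)
  expect_equal(ind$hwf[1, 1, 1], 2)
  expect_equal(ind$hwmd[1, 1, 1], 5)
  expect_equal(ind$hwmhi[1, 1, 1], 6)
  # eventless year is all zeros
  expect_equal(ind$hwf[2, 1, 1], 0)
  expect_equal(ind$hwmd[2, 1, 1], 0)
  expect_equal(ind$hwmhi[2, 1, 1], 0)
  # single event copies its own duration and max HI
  one <- annual_indicators(ev[1, ], 2001, 1, 1)
  expect_equal(c(one$hwf[1, 1, 1], one$hwmd[1, 1, 1], one$hwmhi[1, 1, 1]),
               c(1, 3, 4))
})

test_that("indicators are order-invariant and monotone under added events", {
  set.seed(5)
  ev <- data.frame(year = sample(2001:2003, 10, TRUE),
                   y = sample(1:2, 10, TRUE), x = sample(1:2, 10, TRUE),
                   start = sample(1:100, 10), duration = sample(3:9, 10, TRUE),
                   max_hi = runif(10, 3, 9), hwi = runif(10, 3, 9))
  a <- annual_indicators(ev, 2001:2003, 2, 2)
  b <- annual_indicators(ev[sample(nrow(ev)), ], 2001:2003, 2, 2)
  expect_equal(a$hwf, b$hwf)
  expect_equal(a$hwmhi, b$hwmhi)
  expect_equal(a$hwmd, b$hwmd)
  extra <- data.frame(year = 2002L, y = 1L, x = 2L, start = 120L,
                      duration = 4L, max_hi = 5, hwi = 4)
  m <- annual_indicators(rbind(ev, extra), 2001:2003, 2, 2)
  expect_true(all(m$hwf >= a$hwf))
  expect_true(all(m$hwmhi >= a$hwmhi))
  expect_true(all(m$hwmd >= a$hwmd))
})

test_that("synthetic episodes are recovered exactly and short decoys never are", {
  cfg0 <- synthetic_config(seed = 91, ny = 6, nx = 6, years = 2001:2010)
  eps <- sample_episode_placements(cfg0, 12L,
                                   durations = c(rep(3:6, 2), 1, 1, 2, 2),
                                   seed = 17)
  cfg <- synthetic_config(seed = 91, ny = 6, nx = 6, years = 2001:2010,
                          episodes = eps)
  g <- synthetic_climate_grid(cfg)
  ti <- torridity_index(g$mt, g$rh)
  thr <- ti_threshold(g)
  ev <- detect_events_grid(ti, thr, g$dates)
  truth <- truth_catalog(cfg)
  true_eps <- truth[truth$duration >= 3L, ]
  for (i in seq_len(nrow(true_eps))) {
    hit <- ev$x == true_eps$x[i] & ev$y == true_eps$y[i] &
      ev$year == true_eps$year[i] & ev$start == true_eps$start[i] &
      ev$duration == true_eps$duration[i]
    expect_identical(sum(hit), 1L)
  }
  decoys <- truth[truth$duration <= 2L, ]
  for (i in seq_len(nrow(decoys))) {
    overlap <- ev$x == decoys$x[i] & ev$y == decoys$y[i] &
      ev$year == decoys$year[i] &
      ev$start <= decoys$start[i] + decoys$duration[i] - 1L &
      ev$start + ev$duration - 1L >= decoys$start[i]
    expect_identical(sum(overlap), 0L)
  }
})
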