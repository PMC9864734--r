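test_that("natural breaks split the two-cluster example and handle edge k", {
  v <- c(1, 2, 3, 10, 11, 12)
  b <- jenks_breaks(v, 2)
  expect_equal(b$breaks, 3)
  expect_equal(b$within_ss, jenks_oracle_ss(v, 2))
  expect_identical(as.character(classify_values(v, b)),
                   rep(c("class1", "class2"), each = 3))
  # k = 1: single class, no cuts
  b1 <- jenks_breaks(v, 1)
  expect_length(b1$breaks, 0L)
  # k = n distinct values: zero within-class deviation
  bn <- jenks_breaks(v, 6)
  expect_equal(bn$within_ss, 0)
  expect_error(jenks_breaks(c(1, 1, 2), 3), "distinct")
})

test_that("natural breaks achieve the exhaustive-search optimum", {
  set.seed(66)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    v <- sample(1:6, n, replace = TRUE)
    k <- sample(seq_len(min(4, length(unique(v)))), 1)
    expect_equal(jenks_breaks(v, k)$within_ss, jenks_oracle_ss(v, k),
                 tolerance = 1e-9)
  }
})

test_that("classification is a partition with right-closed intervals", {
  scheme <- jenks_breaks(c(1, 2, 3, 10, 11, 12, 30, 31), 3)
  # below the first cut -> lowest class; at a cut -> lower class
  expect_identical(as.character(classify_values(-5, scheme)), "class1")
  expect_identical(as.character(classify_values(scheme$breaks[1], scheme)),
                   "class1")
  expect_identical(as.character(classify_values(scheme$breaks[2], scheme)),
                   "class2")
  expect_identical(as.character(classify_values(1e6, scheme)), "class3")
  expect_true(is.na(classify_values(NA_real_, scheme)))
  # oracle agreement + every finite value gets exactly one label
  set.seed(9)
  v <- runif(200, -10, 50)
  lab <- classify_values(v, scheme)
  cuts <- c(-Inf, scheme$breaks, Inf)
  oracle <- vapply(v, function(z) {
    which(z <= cuts[-1] & z > cuts[-length(cuts)])[1]
  }, integer(1))
  expect_identical(as.integer(lab), oracle)
  expect_identical(sum(table(lab)), 200L)
})

test_that("the category table is exhaustive, exclusive, and matches the stated scenarios", {
  tab <- default_category_table()
  grid <- expand.grid(spatial = spatial_labels(),
                      temporal = temporal_labels(),
                      stringsAsFactors = FALSE)
  cat <- spatiotemporal_category(grid$spatial, grid$temporal)
  expect_false(anyNA(cat))
  expect_identical(as.integer(table(factor(cat, 1:4))), c(4L, 6L, 6L, 9L))
  # the four enumerated high-hazard/increasing scenarios are category 1
  expect_identical(spatiotemporal_category("high", "increased"), 1L)
  expect_identical(spatiotemporal_category("high", "slightly increased"), 1L)
  expect_identical(spatiotemporal_category("medium-high", "increased"), 1L)
  expect_identical(spatiotemporal_category("medium-high",
                                           "slightly increased"), 1L)
  expect_identical(spatiotemporal_category("low", "decreased"), 4L)
  expect_true(is.na(spatiotemporal_category("high", NA)))
  expect_error(spatiotemporal_category("high", "way up"), "unknown")
})

test_that("the category table can be overridden", {
  tab <- default_category_table()
  tab["middle", "increased"] <- 4L
  expect_identical(
    spatiotemporal_category("middle", "increased", table = tab), 4L)
})

test_that("trend classification maps non-significant pixels to 'basically unchanged'", {
  set.seed(14)
  n_years <- 20
  arr <- array(0, c(n_years, 2, 3))
  slopes <- c(0.05, -0.04, 0.001, 0.02, -0.01, 0.09)
  i <- 1
  for (x in 1:3) for (y in 1:2) {
    arr[, y, x] <- slopes[i] * (1:n_years) + rnorm(n_years, 0, 0.02)
    i <- i + 1
  }
  tr <- trend_surface(arr, 2000 + 1:n_years)
  cl <- classify_trend(tr, k = min(5L, sum(tr$significant)))
  expect_true(all(cl$classes[!tr$significant] == "basically unchanged"))
  expect_true(all(cl$classes %in% temporal_labels()))
})

test_that("zonal statistics aggregate, rank, and flag empty zones", {
  ny <- 4; nx <- 6
  lon <- seq(0.5, by = 1, length.out = nx)
  lat <- seq(0.5, by = 1, length.out = ny)
  yrs <- 2001:2010
  hazard <- array(0, c(length(yrs), ny, nx))
  left <- 0.2; right <- 0.8
  for (x in 1:nx) {
    base <- if (x <= 3) left else right
    hazard[, , x] <- base + 0.001 * seq_along(yrs)
  }
  ah <- apply(hazard, c(2, 3), mean)
  rect <- function(x0, x1, y0, y1) {
    cbind(c(x0, x1, x1, x0, x0), c(y0, y0, y1, y1, y1 * 0 + y0))
  }
  zones <- list(
    all = rect(0, nx, 0, ny),
    left = rect(0, 3, 0, ny),
    right = rect(3, nx, 0, ny),
    offshore = rect(100, 101, 100, 101)
  )
  zs <- zonal_statistics(ah, hazard, yrs, lon, lat, zones)
  expect_equal(zs$mean_ah[zs$zone == "all"], mean(ah))
  expect_equal(zs$mean_ah[zs$zone == "left"], mean(ah[, 1:3]))
  expect_identical(zs$n_pixels[zs$zone == "offshore"], 0L)
  expect_true(is.na(zs$rank_ah[zs$zone == "offshore"]))
  # right half is hotter: rank 1 by AH; left is last
  expect_identical(zs$rank_ah[zs$zone == "right"], 1L)
  expect_identical(zs$rank_ah[zs$zone == "left"], 3L)
  # ranks are a permutation of 1..n over valid zones
  expect_identical(sort(zs$rank_ah[zs$n_pixels > 0]), 1:3)
  expect_identical(sort(zs$rank_slope[zs$n_pixels > 0]), 1:3)
  # zone-mean trend matches a direct fit
  direct <- linear_trend(rowMeans(matrix(hazard, length(yrs))), yrs)
  expect_equal(zs$slope[zs$zone == "all"], direct$slope)
  expect_error(zonal_statistics(ah, hazard, yrs, lon, lat, list()), "empty")
})

test_that("rank by AH is the inverse permutation of the descending sort order", {
  set.seed(3)
  ny <- 3; nx <- 3
  lon <- seq(0.5, by = 1, length.out = nx)
  lat <- seq(0.5, by = 1, length.out = ny)
  yrs <- 2001:2005
  hazard <- array(runif(5 * ny * nx), c(5, ny, nx))
  ah <- apply(hazard, c(2, 3), mean)
  zones <- lapply(1:nx, function(x) {
    cbind(c(x - 1, x, x, x - 1, x - 1), c(0, 0, ny, ny, 0))
  })
  names(zones) <- paste0("col", 1:nx)
  zs <- zonal_statistics(ah, hazard, yrs, lon, lat, zones)
  expect_identical(zs$rank_ah[order(-zs$mean_ah)], seq_len(nx))
})

test_that("GeoJSON zones round-trip into zonal statistics", {
  gj <- list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature", properties = list(name = "west"),
           geometry = list(type = "Polygon",
                           coordinates = list(list(list(0, 0), list(2, 0),
                                                   list(2, 3), list(0, 3),
                                                   list(0, 0))))),
      list(type = "Feature", properties = list(name = "east"),
           geometry = list(
             type = "MultiPolygon",
             coordinates = list(list(list(list(2, 0), list(4, 0), list(4, 3),
                                          list(2, 3), list(2, 0)))))))
  )
  path <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE)
  zones <- read_zones_geojson(path)
  expect_named(zones, c("west", "east"))
  ah <- matrix(rep(c(0.1, 0.1, 0.9, 0.9), each = 3), 3, 4)
  hazard <- array(rep(ah, each = 2), c(2, 3, 4))
  zs <- zonal_statistics(ah, hazard, 2001:2002, lon = c(0.5, 1.5, 2.5, 3.5),
                         lat = c(0.5, 1.5, 2.5), zones = zones)
  expect_equal(zs$mean_ah, c(0.1, 0.9))
  expect_identical(zs$rank_ah, c(2L, 1L))
})
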