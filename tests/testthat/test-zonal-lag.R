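test_that("nearest-neighbour resampling maps indices exactly", {
  # uniform stays uniform
  u <- resample_nearest(const_grid(7, 2, 2, 1000), 250)
  expect_true(all(u$values == 7))
  expect_equal(dim(u$values), c(8L, 8L))
  # 2x2 source -> 8x8 output in constant 4x4 quadrants
  src <- rh_grid(matrix(c(1, 3, 2, 4), 2, 2), 0, 2000, 1000)
  out <- resample_nearest(src, 250)
  for (qi in 1:2) for (qj in 1:2) {
    q <- out$values[(qi - 1) * 4 + 1:4, (qj - 1) * 4 + 1:4]
    expect_equal(length(unique(as.vector(q))), 1L)
    expect_equal(q[1, 1], src$values[qi, qj])
  }
  # no new values introduced
  expect_true(all(out$values %in% src$values))
  # identity at the same resolution
  same <- resample_nearest(src, 1000)
  expect_identical(same$values, src$values)
  expect_error(resample_nearest(src, -5), "positive")
})

test_that("area-weighted means match hand-computed cases", {
  # uniform raster -> the constant, any block
  g <- const_grid(42, 3, 3, 1000)
  blk <- cbind(c(300, 2700, 2700, 300), c(300, 300, 1700, 1700))
  expect_equal(as.numeric(area_weighted_mean(g, blk)), 42)

  # two pixels, equal areas, values 2 and 4 -> 3
  g2 <- rh_grid(matrix(c(2, 4), 1, 2), 0, 1000, 1000)
  blk2 <- cbind(c(500, 1500, 1500, 500), c(250, 250, 750, 750))
  expect_equal(as.numeric(area_weighted_mean(g2, blk2)), 3, tolerance = 1e-12)

  # one full pixel (value 0) + quarter pixel (value 8) -> 1.6
  g3 <- rh_grid(matrix(c(0, 8), 1, 2), 0, 1000, 1000)
  blk3 <- cbind(c(0, 1500, 1500, 1000, 1000, 0),
                c(0, 0, 500, 500, 1000, 1000))
  expect_equal(as.numeric(area_weighted_mean(g3, blk3)), 1.6, tolerance = 1e-12)

  # result bounded by covered pixel values; NaN pixels excluded
  set.seed(4)
  g4 <- rh_grid(matrix(runif(9, 0, 100), 3, 3), 0, 3000, 1000)
  v <- as.numeric(area_weighted_mean(g4, blk))
  expect_gte(v, min(g4$values)); expect_lte(v, max(g4$values))
  g5 <- g4; g5$values[1, 1] <- NaN
  expect_true(is.finite(as.numeric(area_weighted_mean(g5, blk))))
  # below-threshold coverage -> NA with warning
  g6 <- g4; g6$values[1:2, 1:3] <- NaN
  blk_top <- cbind(c(100, 2900, 2900, 100), c(1200, 1200, 2900, 2900))
  expect_warning(v6 <- area_weighted_mean(g6, blk_top), "coverage")
  expect_true(is.na(as.numeric(v6)))
  # disjoint block errors
  far <- cbind(c(10000, 11000, 11000, 10000), c(0, 0, 500, 500))
  expect_error(area_weighted_mean(g4, far), "intersect")
})

test_that("block series extraction is faithful to constant fields", {
  lay <- estate_layout()
  g1 <- rh_grid(matrix(55, 6, 7), lay$grid$xmin, lay$grid$ymax, 1000,
                date = as.Date("2014-01-01"))
  g2 <- rh_grid(matrix(60, 6, 7), lay$grid$xmin, lay$grid$ymax, 1000,
                date = as.Date("2014-01-02"))
  s1 <- build_block_series(list(g1), lay)
  expect_equal(nrow(s1), 26L)
  expect_true(all(s1$rh == 55))
  s2 <- build_block_series(list(g1, g2), lay)
  expect_equal(nrow(s2), 52L)
  expect_true(all(s2$rh[s2$date == as.Date("2014-01-02")] == 60))
  expect_error(build_block_series(list(g1, g1), lay), "duplicate")
  g3 <- rh_grid(matrix(1, 3, 3), 0, 3000, 1000, date = as.Date("2014-01-03"))
  expect_error(build_block_series(list(g1, g3), lay), "geometry")
})

test_that("lag assembly uses windows ending 7k days before the census", {
  blocks <- c("B01", "B02")
  dates <- seq(as.Date("2014-01-01"), by = "1 day", length.out = 120)
  # linear-trend series: rh = day index, so window means are arithmetic means
  series <- do.call(rbind, lapply(blocks, function(b)
    data.frame(block_id = b, date = dates, rh = as.numeric(dates - dates[1] + 1))))
  class(series) <- c("block_rh_series", "data.frame")
  census <- data.frame(block_id = blocks, cycle_index = 1L,
                       census_date = as.Date("2014-04-01"),
                       mean_count_per_palm = c(3, 4))
  ds <- assemble_lagged(series, census, window_days = 8L)
  expect_equal(nrow(ds), 2L)
  for (k in 1:6) {
    hi <- as.Date("2014-04-01") - 7 * k
    expected <- mean(as.numeric(hi - dates[1] + 1) - 0:7)
    expect_equal(ds[[paste0("rh_T", k)]][1], expected)
  }
  # constant series -> all six lag columns equal the constant
  series$rh <- 63
  ds2 <- assemble_lagged(series, census)
  expect_true(all(as.matrix(ds2[, paste0("rh_T", 1:6)]) == 63))
  # removing the T3 window of one block drops that row and logs it
  t3_window <- seq(as.Date("2014-04-01") - 21 - 7, as.Date("2014-04-01") - 21, by = "1 day")
  gap <- series[!(series$block_id == "B01" & series$date %in% t3_window), ]
  class(gap) <- class(series)
  ds3 <- assemble_lagged(gap, census)
  expect_equal(nrow(ds3), 1L)
  log <- attr(ds3, "cleaning_log")
  expect_equal(nrow(log), 1L)
  expect_equal(log$block_id, "B01")
  # row count never exceeds the census row count
  expect_lte(nrow(ds3), nrow(census))
  expect_error(assemble_lagged(series, census[0, ]), "empty census")
})

test_that("dataset cleaning rules remove what they should, idempotently", {
  d <- make_lagged_df(40, seed = 2, signal = function(x) 1, noise_sd = 0.1)
  ds <- structure(d, cleaning_log = data.frame(), class = c("lagged_dataset", "data.frame"))
  clean <- clean_dataset(ds)
  expect_equal(nrow(clean), 40L)                  # no outliers: unchanged
  expect_identical(nrow(clean_dataset(clean)), nrow(clean))  # idempotent here
  # one extreme count among ~1s removed under zscore3 (z-score by hand)
  d2 <- d; d2$mean_count_per_palm[5] <- 40
  z <- (40 - mean(d2$mean_count_per_palm)) / sd(d2$mean_count_per_palm)
  expect_gt(abs(z), 3)
  ds2 <- structure(d2, cleaning_log = data.frame(), class = class(ds))
  clean2 <- clean_dataset(ds2)
  expect_equal(nrow(clean2), 39L)
  expect_match(attr(clean2, "cleaning_log")$reason, "zscore3")
  # rule "none" keeps outliers, drops only missing rows
  d3 <- d2; d3$rh_T2[7] <- NA
  ds3 <- structure(d3, cleaning_log = data.frame(), class = class(ds))
  clean3 <- clean_dataset(ds3, "none")
  expect_equal(nrow(clean3), 39L)
  expect_match(attr(clean3, "cleaning_log")$reason, "missing")
  expect_error(clean_dataset(ds, "mad"), "arg")
})

test_that("lagged dataset CSV + sidecar JSON round-trips", {
  d <- make_lagged_df(12, seed = 3, signal = function(x) x$rh_T1 / 10)
  d$census_date <- as.Date("2014-06-01") + seq_len(12)
  ds <- structure(d, lag_definition = setNames(7L * (1:6), paste0("T", 1:6)),
                  window_days = 8L,
                  cleaning_log = data.frame(block_id = "B01",
                                            census_date = as.Date("2014-05-01"),
                                            reason = "missing value"),
                  class = c("lagged_dataset", "data.frame"))
  p <- tempfile(fileext = ".csv")
  write_lagged_csv(ds, p)
  back <- read_lagged_csv(p)
  expect_equal(back$rh_T4, ds$rh_T4)
  expect_equal(attr(back, "window_days"), 8L)
  expect_equal(nrow(attr(back, "cleaning_log")), 1L)
})
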