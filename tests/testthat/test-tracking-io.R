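mb_csv <- function(rows) {
  path <- tempfile(fileext = ".csv")
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(`individual-local-identifier` = r[[1]], timestamp = r[[2]],
               `location-long` = r[[3]], `location-lat` = r[[4]],
               check.names = FALSE)
  }))
  write.csv(df, path, row.names = FALSE)
  path
}

test_that("reading collapses duplicates, sorts, and drops missing coordinates", {
  path <- mb_csv(list(
    list("b1", "2016-01-01 04:00:00", -80.2, 26.5),
    list("b1", "2016-01-01 00:00:00", -80.21, 26.51),
    list("b1", "2016-01-01 00:00:00", -80.21, 26.51)))
  fx <- read_relocations(path)
  expect_equal(nrow(fx), 2)
  expect_false(is.unsorted(fx$timestamp))

  path2 <- mb_csv(list(
    list("b1", "2016-01-01 00:00:00", -80.2, 26.5),
    list("b1", "2016-01-01 02:00:00", -80.2, NA)))
  expect_warning(fx2 <- read_relocations(path2), "dropped 1")
  expect_equal(nrow(fx2), 1)
  expect_equal(attr(fx2, "n_dropped"), 1)
})

test_that("an unparseable timestamp is a hard error naming the row", {
  path <- mb_csv(list(
    list("b1", "2016-01-01 00:00:00", -80.2, 26.5),
    list("b1", "not-a-time", -80.2, 26.5)))
  expect_error(read_relocations(path), "row 2")
})

test_that("season subsetting uses closed windows and splits bird-years", {
  t0 <- as.POSIXct("2016-01-01 00:00:00", tz = "UTC")
  fx <- data.frame(individual_id = "b1", timestamp = t0 + (0:9) * 7200,
                   lon = -80.2, lat = 26.5)
  w <- data.frame(individual_id = "b1", season_label = "1",
                  start = "2016-01-01 00:00:00", end = "2016-01-01 06:00:00")
  tr <- subset_seasons(fx, read_season_windows(w))
  expect_length(tr, 1)
  expect_equal(nrow(tr[[1]]), 4)   # fixes at 0,2,4,6 h; end boundary included
  expect_equal(tr[[1]]$track_id[1], "b1_1")

  w2 <- rbind(w, data.frame(individual_id = "b1", season_label = "2",
                            start = "2016-01-01 10:00:00",
                            end = "2016-01-01 18:00:00"))
  tr2 <- subset_seasons(fx, read_season_windows(w2))
  expect_length(tr2, 2)
  expect_setequal(names(tr2), c("b1_1", "b1_2"))
})

test_that("fix-rate normalization follows the greedy anchor walk", {
  t0 <- as.POSIXct("2016-01-01 00:00:00", tz = "UTC")
  mk <- function(mins) data.frame(individual_id = "b", track_id = "b_1",
                                  timestamp = t0 + mins * 60,
                                  lon = -80.2, lat = 26.5)
  # 0:30 is closer than interval - tolerance to the anchor: skipped
  out <- normalize_fix_rate(mk(c(0, 30, 125)))
  expect_equal(as.numeric(out$timestamp - t0, units = "mins"), c(0, 125))
  # both gaps inside [1:40, 2:20]: everything kept, one burst
  out <- normalize_fix_rate(mk(c(0, 105, 230)))
  expect_equal(nrow(out), 3)
  expect_equal(unique(out$burst_id), 1L)
  # exact 2-h spacing is the identity
  out <- normalize_fix_rate(mk(seq(0, 600, by = 120)))
  expect_equal(nrow(out), 6)
  # a long gap starts a new burst instead of dropping the fix
  out <- normalize_fix_rate(mk(c(0, 120, 600)))
  expect_equal(out$burst_id, c(1L, 1L, 2L))
})

test_that("normalization is idempotent on random irregular tracks", {
  t0 <- as.POSIXct("2016-01-01 00:00:00", tz = "UTC")
  set.seed(42)
  for (rep in 1:10) {
    ts <- t0 + sort(sample.int(3e5, 80))
    tr <- data.frame(individual_id = "b", track_id = "b_1", timestamp = ts,
                     lon = -80.2, lat = 26.5)
    once <- normalize_fix_rate(tr)
    twice <- normalize_fix_rate(once)
    expect_equal(twice, once)
  }
})

test_that("speed filtering removes later points of too-fast pairs until clean", {
  t0 <- as.POSIXct("2016-01-01 00:00:00", tz = "UTC")
  tr <- data.frame(individual_id = "b", track_id = "b_1",
                   timestamp = t0 + c(0, 7200), lon = NA, lat = NA,
                   x = c(0, 90000), y = 0)
  expect_equal(nrow(filter_speed(tr)), 1)      # 12.5 m/s > 12
  tr$x <- c(0, 86000)
  expect_equal(nrow(filter_speed(tr)), 2)      # 11.94 m/s kept
  expect_equal(nrow(filter_speed(tr[1, ])), 1) # single fix unchanged

  set.seed(7)
  tr2 <- data.frame(individual_id = "b", track_id = "b_1",
                    timestamp = t0 + (0:49) * 7200,
                    x = cumsum(rnorm(50, 0, 6e4)), y = 0)
  out <- filter_speed(tr2)
  v <- abs(diff(out$x)) / as.numeric(diff(out$timestamp), units = "secs")
  expect_true(all(v <= 12))
})

test_that("subsetting then splitting conserves fixes inside windows", {
  t0 <- as.POSIXct("2016-01-01 00:00:00", tz = "UTC")
  set.seed(3)
  fx <- data.frame(individual_id = rep(c("a", "b"), each = 40),
                   timestamp = t0 + sample.int(6e6, 80),
                   lon = -80.2, lat = 26.5)
  fx <- fx[order(fx$individual_id, fx$timestamp), ]
  w <- read_season_windows(data.frame(
    individual_id = c("a", "b"), season_label = "1",
    start = "2016-01-05 00:00:00", end = "2016-02-10 00:00:00"))
  tr <- subset_seasons(fx, w)
  n_in <- sum(fx$timestamp >= w$start[1] & fx$timestamp <= w$end[1])
  expect_equal(sum(vapply(tr, nrow, 0L)), n_in)
})
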