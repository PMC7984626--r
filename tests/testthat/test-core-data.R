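test_that("epi-week assignment matches an independent MMWR oracle", {
  dates <- seq(as.Date("2010-01-03"), by = "7 days", length.out = 1000)
  idx <- build_season_index(data.frame(week_start = dates))
  expect_equal(idx$epi_week, mmwr_oracle(dates))
})

test_that("seasons partition the weeks into 52/53-week blocks", {
  dates <- seq(as.Date("2012-08-26"), by = "7 days", length.out = 365)
  idx <- build_season_index(data.frame(week_start = dates))
  lens <- attr(idx, "season_lengths")
  expect_length(lens, 7)
  expect_true(all(lens %in% c(52L, 53L)))
  expect_equal(sum(lens), 365)
  # partition: every week in exactly one season, week-of-season 1..n
  expect_equal(unname(unlist(tapply(idx$week_of_season, idx$season_id,
                                    function(x) x == seq_along(x)))),
               rep(TRUE, 365))
  # the MMWR calendar contains a 53-week season in this range
  expect_true(any(lens == 53L))
})

test_that("a single season maps to one id with week-of-season 1..n", {
  dates <- seq(as.Date("2012-08-26"), by = "7 days", length.out = 30)
  idx <- build_season_index(data.frame(week_start = dates))
  expect_equal(length(unique(idx$season_id)), 1)
  expect_equal(idx$week_of_season, 1:30)
  expect_true(idx$season_id[1] %in% attr(idx, "partial_seasons"))
})

test_that("gaps and duplicates are rejected with the offending dates", {
  dates <- seq(as.Date("2012-08-26"), by = "7 days", length.out = 10)
  gap <- data.frame(week_start = dates[-5])
  expect_error(build_season_index(gap), "14 days")
  dup <- data.frame(week_start = dates[c(1:5, 5:10)])
  expect_error(build_season_index(dup), "7 days")
})

test_that("high-volume labels pick the top quarter per season", {
  s <- build_season_index(toy_series(1:8))
  hi <- label_high_volume(s)
  expect_equal(s$ili_count[hi], c(7, 8))

  # equal counts: the earliest ceiling(0.25 n) weeks win
  s2 <- build_season_index(toy_series(rep(5, 12)))
  expect_equal(which(label_high_volume(s2)), 1:3)
})

test_that("the reference season-length profile yields 89 high-volume weeks", {
  lens <- c(52, 53, 52, 52, 52, 53, 34)
  set.seed(11)
  fake <- data.frame(
    season_id = rep(sprintf("s%d", seq_along(lens)), lens),
    ili_count = sample.int(500, sum(lens), replace = TRUE))
  expect_equal(sum(lens), 348)
  expect_equal(sum(label_high_volume(fake)), 89)
  # per season the high share is within [0.25, 0.25 + 1/n]
  by_season <- tapply(label_high_volume(fake), fake$season_id, mean)
  expect_true(all(by_season >= 0.25 & by_season <= 0.25 + 1 / 34))
})

test_that("CSV round trip preserves counts, dates and floats", {
  set.seed(2)
  s <- toy_series(rpois(10, 100), temp_min = rnorm(10),
                  immunization_rate = runif(10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_weekly_csv(s, path)
  r <- read_weekly_csv(path)
  expect_equal(r$ili_count, s$ili_count)
  expect_equal(r$week_start, s$week_start)
  expect_equal(r$temp_min, s$temp_min, tolerance = 1e-6)
  expect_equal(r$immunization_rate, s$immunization_rate, tolerance = 1e-6)
})

test_that("malformed CSVs are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  s <- toy_series(c(5, 10, 8, 12))
  s$ili_count[3] <- -1
  utils::write.csv(s, path, row.names = FALSE)
  expect_error(read_weekly_csv(path), "row.*3")

  s2 <- toy_series(c(5, 10, 8, 12))
  s2$week_start <- as.character(s2$week_start)
  s2$week_start[2] <- "not-a-date"
  utils::write.csv(s2, path, row.names = FALSE)
  expect_error(read_weekly_csv(path), "week_start")

  s3 <- toy_series(c(5, 10))
  s3$ili_count <- NULL
  utils::write.csv(s3, path, row.names = FALSE)
  expect_error(read_weekly_csv(path), "ili_count")
})

test_that("forecast CSV carries the point, centiles and 90% interval", {
  f <- forecast_dist(as.Date("2015-01-04"), 2, 100,
                     seq(50, 148, length.out = 99), model = "lr")
  path <- withr::local_tempfile(fileext = ".csv")
  write_forecast_csv(list(f), path)
  r <- utils::read.csv(path)
  expect_equal(nrow(r), 1)
  expect_equal(r$point, 100)
  expect_equal(r$model, "lr")
  expect_equal(r$pi_lower_90, f$centiles[5])
  expect_equal(r$pi_upper_90, f$centiles[95])
  expect_equal(as.numeric(r[1, sprintf("q%02d", 1:99)]), f$centiles)
})
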