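test_that("pool-of-one with unit pacing is the identity transformation", {
  src <- toy_trajectory(bump_curve())
  b <- eb_sample_curves(list(src), 5, 52, pacing_range = c(1, 1))
  for (k in 1:5)
    expect_equal(b$values[k, ], src$values, tolerance = 1e-10)
})

test_that("transformed curves hit their sampled peak height and location", {
  set.seed(21)
  pool <- list(toy_trajectory(bump_curve(52, 135, 400, 24, 6)),
               toy_trajectory(bump_curve(52, 120, 320, 19, 8)),
               toy_trajectory(bump_curve(53, 150, 450, 29, 5)))
  b <- eb_sample_curves(pool, 1000, 52)
  peak_vals <- apply(b$values, 1, max)
  peak_wks <- apply(b$values, 1, which.max)
  expect_equal(peak_vals, b$height_target, tolerance = 1e-8)
  expect_equal(peak_wks, b$location_target)
  expect_true(all(b$pacing >= 0.75 & b$pacing <= 1.25))
  # sigma travels with the source trajectory
  expect_true(all(b$sigma %in% vapply(pool, `[[`, numeric(1), "sigma")))
})

test_that("likelihood weights follow the Gaussian closed form", {
  curves <- rbind(rep(10, 20), rep(12, 20), rep(20, 20))
  obs <- rep(10, 10)
  w <- eb_likelihood_weights(curves, obs, sigma = rep(4, 3))
  expect_equal(w[1], 1)          # exact fit gets the batch maximum
  # log-weight gap equals (E2 - E1) / (2 sigma^2)
  e2 <- sum((obs - 12)^2); e1 <- 0
  expect_equal(log(w[1]) - log(w[2]), (e2 - e1) / (2 * 16))
  expect_equal(eb_likelihood_weights(curves, numeric(0), rep(4, 3)),
               rep(1, 3))
  expect_error(eb_likelihood_weights(curves, obs, c(4, 0, 4)), "positive")
})

test_that("weighted median follows the half-weight rule", {
  expect_equal(weighted_median(c(1, 2, 3), c(0.2, 0.2, 0.6)), 3)
  # equal weights, odd n: ordinary median
  set.seed(8)
  for (i in 1:20) {
    x <- stats::rnorm(2 * sample(3:10, 1) + 1)
    expect_equal(weighted_median(x, rep(1, length(x))), stats::median(x))
  }
})

test_that("degenerate sample collapses the forecast to a point", {
  src <- toy_trajectory(rep(7, 52), sigma = 1)
  fc <- eb_season_forecasts(list(src), observed = rep(7, 10), 52,
                            origins = 10, horizons = 1:2, n_samples = 50,
                            pacing_range = c(1, 1), noise = FALSE)
  expect_equal(fc$point, c(7, 7))
  expect_equal(unname(unlist(fc[, sprintf("q%02d", 1:99)])),
               rep(7, 2 * 99))
})

test_that("a single identical past season is forecast exactly (no noise)", {
  curve <- bump_curve()
  src <- toy_trajectory(curve, sigma = 3)
  fc <- eb_season_forecasts(list(src), observed = curve[1:20], 52,
                            origins = 20, horizons = 1:4, n_samples = 100,
                            pacing_range = c(1, 1), noise = FALSE)
  expect_equal(fc$point, curve[21:24], tolerance = 1e-8)
})

test_that("forecast centiles are nondecreasing with the point inside", {
  set.seed(22)
  pool <- list(toy_trajectory(bump_curve(), sigma = 8),
               toy_trajectory(bump_curve(52, 120, 320, 20, 7), sigma = 6))
  obs <- bump_curve(52, 130, 380, 23, 6) + stats::rnorm(52, 0, 10)
  fc <- eb_season_forecasts(pool, obs, 52, origins = c(5, 15, 25),
                            horizons = 1:4, n_samples = 500)
  q <- as.matrix(fc[, sprintf("q%02d", 1:99)])
  expect_true(all(apply(q, 1, function(r) all(diff(r) >= -1e-9))))
  expect_true(all(fc$point >= q[, 1] - 1e-9 & fc$point <= q[, 99] + 1e-9))
})

test_that("accumulating observations sharpens the EB posterior", {
  # forecast the same target week (31) with 6 vs 30 weeks of season-to-date
  # evidence; replicate-averaged error must shrink as evidence accumulates
  set.seed(23)
  pool <- list(toy_trajectory(bump_curve(), sigma = 5),
               toy_trajectory(bump_curve(52, 125, 350, 21, 7), sigma = 5))
  err_scant <- err_rich <- numeric(50)
  for (i in 1:50) {
    truth <- bump_curve(52, 130, sample(320:420, 1), sample(20:27, 1),
                        stats::runif(1, 5, 7))
    obs <- truth + stats::rnorm(52, 0, 5)
    scant <- eb_season_forecasts(pool, obs, 52, origins = 6,
                                 horizons = 25, n_samples = 400)
    rich <- eb_season_forecasts(pool, obs, 52, origins = 30,
                                horizons = 1, n_samples = 400)
    err_scant[i] <- abs(scant$point[1] - truth[31])
    err_rich[i] <- abs(rich$point[1] - truth[31])
  }
  expect_lt(mean(err_rich), mean(err_scant))
})

test_that("the user-level EB forecast wraps the season machinery", {
  set.seed(24)
  d <- simulate_dataset(sim_config(n_seasons = 3, seed = 14))
  fc <- eb_forecast(d, current_week = 20, horizon = 2, n_samples = 400)
  expect_s3_class(fc, "forecast_dist")
  expect_equal(fc$horizon, 2L)
  expect_true(all(diff(fc$centiles) >= -1e-9))
  d2 <- d[d$season_id %in% unique(d$season_id)[1:2], ]
  expect_error(eb_forecast(d2, 20, 2, n_samples = 100),
               "2 complete past seasons")
})
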