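test_that("STL removes pure seasonality and leaves constants alone", {
  t <- 1:208
  sine <- 50 * sin(2 * pi * t / 52)
  sa <- stl_adjust(100 + sine, 52)
  expect_lt(stats::sd(sa$adjusted), 0.05 * 50)
  expect_equal(sa$adjusted + sa$seasonal, 100 + sine)  # exact reconstruction

  sc <- stl_adjust(rep(77, 156), 52)
  expect_lt(max(abs(sc$seasonal)), 1e-6)

  set.seed(41)
  noisy <- 100 + sine + 0.3 * t + stats::rnorm(208, 0, 5)
  sn <- stl_adjust(noisy, 52)
  expect_gt(stats::cor(sn$seasonal, sine), 0.95)

  expect_error(stl_adjust(rnorm(104), 52), "2 full periods")
})

test_that("the ARIMA recursion reproduces the hand-computed example", {
  fit <- structure(list(phi = c(0.5, 0), theta = 0, mu = 0, sigma2 = 1,
                        order = c(2, 0, 1),
                        seasonal_by_epiweek = rep(0, 52)),
                   class = "arima_fit")
  fc <- arima_forecast(fit, c(3, 7, 10), 2)
  expect_equal(fc$point, c(5, 2.5))
  expect_true(all(diff(fc$sd) >= 0))
})

test_that("white noise yields mean-reverting forecasts with flat sd", {
  set.seed(42)
  x <- stats::rnorm(300, mean = 50, sd = 4)
  raw <- stats::arima(x, order = c(2, 0, 1), method = "ML")
  cf <- stats::coef(raw)
  fit <- structure(list(phi = unname(cf[1:2]), theta = unname(cf[3]),
                        mu = unname(cf["intercept"]), sigma2 = raw$sigma2,
                        order = c(2, 0, 1),
                        seasonal_by_epiweek = rep(0, 52)),
                   class = "arima_fit")
  fc <- arima_forecast(fit, x, 4)
  expect_equal(fc$point, rep(mean(x), 4), tolerance = 0.05)
  expect_lt(fc$sd[4] / fc$sd[1], 1.15)
  expect_true(all(diff(fc$sd) >= 0))
})

test_that("seasonal re-addition recovers a noise-free periodic series", {
  dates <- seq(as.Date("2012-08-26"), by = "7 days", length.out = 260)
  idx <- build_season_index(data.frame(week_start = dates))
  amp <- 50
  s <- toy_series(numeric(260))
  s <- cbind(s[, names(s) != "ili_count"], idx[, c("epi_week", "epi_year",
                                                   "season_id",
                                                   "week_of_season")])
  s$ili_count <- round(150 + amp * sin(2 * pi * pmin(s$epi_week, 52) / 52))
  fit <- arima_fit_member(s[1:208, ])
  fcs <- arima_member_forecast(fit, s[1:208, ], s$epi_week[209:212])
  truth <- s$ili_count[209:212]
  expect_lt(max(abs(vapply(fcs, `[[`, numeric(1), "point") - truth)),
            0.05 * amp)
})

test_that("feature rows implement slope and upward-movement definitions", {
  s <- build_season_index(toy_series(c(8, 8, 8, 3, 5, 4, 6)))
  x <- build_feature_row(s, 7)
  expect_equal(x$slope, 2)          # 6 - 4
  expect_equal(x$upward, 2)         # rises 3->5 and 4->6, fall 5->4
  x2 <- build_feature_row(build_season_index(toy_series(c(1, 2, 3, 4, 5))), 5)
  expect_equal(x2$upward, 3)
  x3 <- build_feature_row(build_season_index(toy_series(rep(9, 6))), 6)
  expect_equal(x3$slope, 0)
  expect_equal(x3$upward, 0)
  expect_error(build_feature_row(s, 2), "burn-in")
})

test_that("the mtry heuristic and guard match the predictor count", {
  expect_equal(mtry_heuristic(16), 4)
  expect_equal(length(ilistack:::qrf_feature_cols(3)), 14)
  expect_error(qrf_fit(data.frame(x = rnorm(40)), rnorm(40), 10, m_try = 2),
               "exceeds")
})

test_that("constant targets collapse the forest to a point mass", {
  set.seed(43)
  X <- data.frame(a = rnorm(60), b = rnorm(60))
  f <- qrf_fit(X, rep(42, 60), n_trees = 20, m_try = 1, seed = 1)
  fc <- qrf_forecast(f, X[1, ])[[1]]
  expect_equal(fc$point, 42)
  expect_equal(fc$centiles, rep(42, 99))
})

test_that("a single root leaf reproduces type-7 empirical quantiles", {
  f <- qrf_fit(data.frame(x = rep(1:4, 25)), 1:100, n_trees = 1, m_try = 1,
               seed = 1, min_node_size = 1000, replace = FALSE,
               sample.fraction = 1)
  fc <- qrf_forecast(f, data.frame(x = 2))[[1]]
  expect_equal(fc$centiles[50], 50.5)
  expect_equal(fc$centiles[90], 90.1)
  expect_equal(fc$centiles, unname(stats::quantile(1:100, (1:99) / 100)))
})

test_that("the forest learns a noiseless linear signal", {
  set.seed(44)
  n <- 500
  X <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  y <- 10 * X$x1
  f <- qrf_fit(X, y, n_trees = 300, m_try = 2, seed = 2)
  Xt <- data.frame(x1 = runif(200, 0.1, 0.9), x2 = runif(200),
                   x3 = runif(200))
  fcs <- qrf_forecast(f, Xt)
  pred <- vapply(fcs, `[[`, numeric(1), "point")
  expect_lt(sqrt(mean((pred - 10 * Xt$x1)^2)), 0.1 * stats::sd(y))
  q <- t(vapply(fcs, `[[`, numeric(99), "centiles"))
  expect_true(all(apply(q, 1, function(r) all(diff(r) >= -1e-9))))
})

test_that("QRF point forecasts equal the plain forest mean", {
  set.seed(46)
  n <- 200
  X <- data.frame(x1 = runif(n), x2 = runif(n))
  y <- 5 * X$x1 + rnorm(n)
  f <- qrf_fit(X, y, n_trees = 100, m_try = 1, seed = 7)
  # independent route: the same forest's aggregate prediction via ranger
  rf <- ranger::ranger(y ~ ., data = cbind(X, y = y), num.trees = 100,
                       mtry = 1, seed = 7, num.threads = 1)
  xt <- data.frame(x1 = c(0.2, 0.8), x2 = c(0.5, 0.5))
  mine <- vapply(qrf_forecast(f, xt), `[[`, numeric(1), "point")
  expect_equal(mine, predict(rf, xt, num.threads = 1)$predictions)
})

test_that("LR recovers an exact linear law and flags collinearity", {
  set.seed(45)
  X <- data.frame(ili_lag0 = runif(60, 0, 10), tmin_lag0 = rnorm(60),
                  tmax_lag0 = rnorm(60), imm_lag0 = runif(60),
                  population = rnorm(60), year_trend = rep(1:3, 20),
                  epi_week = sample(rep(1:4, 15)), slope = rnorm(60),
                  upward = sample(rep(0:3, 15)))
  y <- 2 + 3 * X$ili_lag0
  f <- suppressWarnings(lr_fit(X, y))
  expect_lt(f$residual_sd, 1e-8)
  fc <- lr_forecast(f, X[3, ])[[1]]
  expect_equal(fc$point, y[3], tolerance = 1e-8)

  X2 <- X
  X2$tmax_lag0 <- X2$tmin_lag0 * 2   # exact collinearity
  expect_error(lr_fit(X2, y), "collinear")
})

test_that("LR prediction SE is smallest near the training centroid", {
  set.seed(47)
  X <- data.frame(ili_lag0 = rnorm(200, 100, 20), tmin_lag0 = rnorm(200),
                  tmax_lag0 = rnorm(200), imm_lag0 = runif(200),
                  population = rnorm(200), year_trend = rep(1:4, 50),
                  epi_week = sample(rep(1:4, 50)), slope = rnorm(200),
                  upward = sample(rep(0:3, 50)))
  y <- 50 + 0.8 * X$ili_lag0 + rnorm(200, 0, 5)
  f <- lr_fit(X, y)
  centroid <- X[1, ]
  for (v in c("ili_lag0", "tmin_lag0", "tmax_lag0", "imm_lag0",
              "population", "slope")) centroid[[v]] <- mean(X[[v]])
  far <- centroid
  far$ili_lag0 <- max(X$ili_lag0) + 50
  se_of <- function(x) {
    fc <- lr_forecast(f, x)[[1]]
    (fc$centiles[95] - fc$centiles[5]) / 2  # monotone in sigma(x)
  }
  expect_lt(se_of(centroid), se_of(far))
})
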