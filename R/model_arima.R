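#' STL seasonal adjustment
#'
#' Removes a periodic seasonal component estimated by STL
#' (`s.window = "periodic"`); `adjusted + seasonal` reconstructs the input
#' exactly.
#'
#' @param counts numeric series.
#' @param period seasonal period in weeks (52).
#' @return list with `seasonal` and `adjusted` vectors.
#' @export
stl_adjust <- function(counts, period = 52L) {
  if (length(counts) <= 2 * period)
    stop(sprintf("need more than %d points (2 full periods) for STL; got %d",
                 2 * period, length(counts)), call. = FALSE)
  x <- stats::ts(counts, frequency = period)
  dec <- stats::stl(x, s.window = "periodic")
  seasonal <- as.numeric(dec$time.series[, "seasonal"])
  list(seasonal = seasonal, adjusted = counts - seasonal)
}

#' Fit the STL-adjusted ARIMA(2,0,1) member
#'
#' Estimates a periodic seasonal index per epi-week (week 53 folded into
#' week 52) from STL on the training series, then fits an ARIMA(2,0,1) with
#' intercept to the seasonally adjusted counts by maximum likelihood.
#'
#' @param train a season-indexed weekly series (training data).
#' @param order ARIMA order, default `c(2, 0, 1)`.
#' @return an object of class `"arima_fit"` with elements `phi` (AR
#'   coefficients), `theta` (MA coefficients), `mu` (mean of the adjusted
#'   series), `sigma2` (innovation variance) and `seasonal_by_epiweek`.
#' @export
arima_fit_member <- function(train, order = c(2L, 0L, 1L)) {
  stopifnot(all(c("ili_count", "epi_week") %in% names(train)))
  adj <- stl_adjust(train$ili_count, 52L)
  ew <- pmin(train$epi_week, 52L)
  s_by_ew <- tapply(adj$seasonal, factor(ew, levels = 1:52), mean)
  s_by_ew[is.na(s_by_ew)] <- 0
  adjusted <- train$ili_count - as.numeric(s_by_ew[ew])
  # the ML optimizer probes invalid parameter regions and warns about the
  # NaN likelihoods it finds there; that exploration noise is expected
  fit <- suppressWarnings(
    stats::arima(adjusted, order = order, include.mean = TRUE,
                 method = "ML"))
  cf <- stats::coef(fit)
  phi <- unname(cf[grep("^ar", names(cf))])
  theta <- unname(cf[grep("^ma", names(cf))])
  mu <- if ("intercept" %in% names(cf)) unname(cf["intercept"]) else 0
  if (length(phi) > 0) {
    roots <- polyroot(c(1, -phi))
    if (any(Mod(roots) <= 1 + 1e-8))
      stop("non-stationary AR fit; root moduli: ",
           paste(sprintf("%.4f", Mod(roots)), collapse = ", "),
           call. = FALSE)
  }
  structure(list(phi = phi, theta = theta, mu = mu,
                 sigma2 = fit$sigma2,
                 order = order,
                 seasonal_by_epiweek = as.numeric(s_by_ew)),
            class = "arima_fit")
}

# innovations of a centered ARMA(p, q) series under the fitted coefficients
# (conditional recursion: pre-sample values and errors set to 0)
arma_innovations <- function(x, phi, theta) {
  n <- length(x)
  ar_part <- numeric(n)
  for (j in seq_along(phi)) {
    lag <- c(rep(0, j), x[seq_len(n - j)])
    ar_part <- ar_part + phi[j] * lag
  }
  resid0 <- x - ar_part
  if (length(theta) == 0) return(resid0)
  # e_t = resid0_t - sum_j theta_j e_{t-j}
  as.numeric(stats::filter(resid0, -theta, method = "recursive"))
}

#' Multi-step ARIMA forecast on an adjusted history
#'
#' Applies the fitted coefficients to a (seasonally adjusted) history by
#' the standard recursion: innovations are reconstructed conditionally,
#' future errors are set to zero and forecasts are fed back as lagged
#' values.  The l-step forecast SD accumulates the psi weights,
#' \eqn{\hat\sigma_l^2 = \sigma^2 \sum_{j<l} \psi_j^2}, and centiles are
#' Gaussian quantiles about the point forecast.
#'
#' @param fit an `"arima_fit"`.
#' @param adjusted_history seasonally adjusted counts up to the origin.
#' @param horizon steps ahead (vectorized over `1:horizon` internally).
#' @return list with vectors `point` and `sd` (length `horizon`) and a
#'   `centiles` matrix (`horizon` x 99), all on the adjusted scale.
#' @export
arima_forecast <- function(fit, adjusted_history, horizon) {
  stopifnot(inherits(fit, "arima_fit"), horizon >= 1)
  x <- adjusted_history - fit$mu
  e <- arma_innovations(x, fit$phi, fit$theta)
  n <- length(x)
  p <- length(fit$phi); q <- length(fit$theta)
  xx <- c(x, numeric(horizon))   # forecasts appended, centered scale
  ee <- c(e, numeric(horizon))   # future innovations are zero
  for (h in seq_len(horizon)) {
    t0 <- n + h
    val <- 0
    for (j in seq_len(p)) if (t0 - j >= 1) val <- val + fit$phi[j] * xx[t0 - j]
    for (j in seq_len(q)) if (t0 - j >= 1 && t0 - j <= n)
      val <- val + fit$theta[j] * ee[t0 - j]
    xx[t0] <- val
  }
  psi <- c(1, stats::ARMAtoMA(ar = fit$phi, ma = fit$theta,
                              lag.max = max(horizon - 1, 1)))
  sd_l <- sqrt(fit$sigma2 * cumsum(psi^2))[seq_len(horizon)]
  point <- fit$mu + xx[n + seq_len(horizon)]
  z <- stats::qnorm((1:99) / 100)
  centiles <- outer(point, rep(1, 99)) + outer(sd_l, z)
  list(point = point, sd = sd_l, centiles = centiles)
}

#' Forecast ILI counts with the ARIMA member
#'
#' Seasonally adjusts the conditioning history with the fit's per-epi-week
#' seasonal index, runs the ARIMA recursion, then re-adds the seasonal
#' component of each target week to the point and all centiles.
#'
#' @param fit an `"arima_fit"`.
#' @param history weekly series rows up to and including the origin week
#'   (chronological past of the forecast).
#' @param target_epiweeks epi-weeks of the target weeks, one per horizon
#'   `1..length(target_epiweeks)`.
#' @return list of [forecast_dist()], one per horizon.
#' @export
arima_member_forecast <- function(fit, history, target_epiweeks) {
  ew <- pmin(history$epi_week, 52L)
  adjusted <- history$ili_count - fit$seasonal_by_epiweek[ew]
  H <- length(target_epiweeks)
  fc <- arima_forecast(fit, adjusted, H)
  s_tgt <- fit$seasonal_by_epiweek[pmin(target_epiweeks, 52L)]
  lapply(seq_len(H), function(h) {
    forecast_dist(made_at_week = history$week_start[nrow(history)],
                  horizon = h,
                  point = fc$point[h] + s_tgt[h],
                  centiles = fc$centiles[h, ] + s_tgt[h],
                  model = "arima")
  })
}
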