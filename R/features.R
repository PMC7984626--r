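#' Regression features for the QRF and LR members
#'
#' At origin week t the feature row holds: the current and lagged ILI
#' counts (lags 0..`lags`-1), the current epi-week (week 53 folded into 52
#' so every level exists in every training year), current and lagged
#' weekly minimum/maximum temperature and immunization rate, city
#' population, a year trend (season number), the current slope of the ILI
#' curve (y_t - y_{t-1}) and the count of upward movements of ILI over the
#' preceding three weeks (0..3, treated as categorical by the LR member).
#'
#' @param series a season-indexed weekly series.
#' @param lags number of lagged weeks per dynamic variable (default 3:
#'   lags 0, 1, 2 relative to the origin).
#' @return a `data.frame` aligned with `series` rows; rows within the
#'   burn-in window hold `NA`.
#' @export
build_features <- function(series, lags = 3L) {
  n <- nrow(series)
  lag_of <- function(x, k) c(rep(NA_real_, k), x[seq_len(n - k)])
  out <- data.frame(row = seq_len(n))
  for (k in 0:(lags - 1)) {
    out[[paste0("ili_lag", k)]] <- lag_of(series$ili_count, k)
    out[[paste0("tmin_lag", k)]] <- lag_of(series$temp_min, k)
    out[[paste0("tmax_lag", k)]] <- lag_of(series$temp_max, k)
    out[[paste0("imm_lag", k)]] <- lag_of(series$immunization_rate, k)
  }
  out$epi_week <- pmin(series$epi_week, 52L)
  out$population <- series$population
  out$year_trend <- as.integer(factor(series$season_id,
                                      levels = unique(series$season_id)))
  y <- series$ili_count
  out$slope <- y - lag_of(y, 1)
  up <- function(k) as.numeric(lag_of(y, k) > lag_of(y, k + 1))
  out$upward <- up(0) + up(1) + up(2)
  out$row <- NULL
  out
}

#' Feature row at one origin week
#'
#' @param series a season-indexed weekly series.
#' @param t origin row index.
#' @param lags lag depth.
#' @return single-row `data.frame` of features.
#' @export
build_feature_row <- function(series, t, lags = 3L) {
  burn_in <- max(lags - 1L, 3L)
  if (t <= burn_in)
    stop(sprintf(
      "insufficient history at row %d: burn-in of %d prior weeks required",
      t, burn_in), call. = FALSE)
  build_features(series, lags)[t, , drop = FALSE]
}

# predictor column sets for the two regression members
qrf_feature_cols <- function(lags = 3L) {
  c(t(outer(c("ili_lag", "tmin_lag", "tmax_lag", "imm_lag"),
            0:(lags - 1), paste0)),
    "epi_week", "population")
}

lr_feature_cols <- function() {
  c("ili_lag0", "tmin_lag0", "tmax_lag0", "imm_lag0",
    "population", "year_trend", "epi_week", "slope", "upward")
}
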