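#' Point-forecast accuracy metrics
#'
#' MAE, RMSE and MAPE (in percent) of a vector of point forecasts.
#'
#' @param predictions,observations equal-length numeric vectors;
#'   observations must be strictly positive for the MAPE.
#' @return list with `mae`, `rmse`, `mape_pct`.
#' @export
point_metrics <- function(predictions, observations) {
  stopifnot(length(predictions) == length(observations),
            length(predictions) >= 1)
  zero <- which(observations == 0)
  if (length(zero) > 0)
    stop("MAPE undefined: zero observation at index ",
         paste(utils::head(zero, 5), collapse = ", "), call. = FALSE)
  err <- observations - predictions
  list(mae = mean(abs(err)),
       rmse = sqrt(mean(err^2)),
       mape_pct = 100 * mean(abs(err / observations)))
}

#' Centile-band log score of a probabilistic forecast
#'
#' The natural log of the fraction of the forecast's 1st--98th centiles
#' falling within +/- `tolerance` visits of the observed count.  When the
#' observation falls below the 1st or above the 99th centile -- or no
#' centile is in the band -- the score is floored at `floor`.
#'
#' @param centiles numeric vector of the 99 forecast centiles.
#' @param observed realized count.
#' @param tolerance half-width of the acceptable band (visits).
#' @param floor score assigned outside the forecast's support.
#' @return a log score in `[floor, 0]`.
#' @export
log_score <- function(centiles, observed, tolerance = 25, floor = -5) {
  stopifnot(length(centiles) == 99)
  if (observed < centiles[1] || observed > centiles[99]) return(floor)
  hits <- sum(centiles[1:98] >= observed - tolerance &
                centiles[1:98] <= observed + tolerance)
  if (hits == 0) return(floor)
  max(log(hits / 98), floor)
}

#' Percentage of predictions within a relative tolerance of the observed
#'
#' @param predictions,observations numeric vectors; observations > 0.
#' @param rel_tol relative tolerance (0.20 = within 20%).
#' @return percentage in \[0, 100\].
#' @export
within_tolerance_rate <- function(predictions, observations,
                                  rel_tol = 0.20) {
  stopifnot(length(predictions) == length(observations),
            all(observations > 0))
  100 * mean(abs(predictions - observations) / observations <= rel_tol)
}

#' Coverage rate of central prediction intervals
#'
#' @param lower,upper interval bounds per forecast (for a 90% interval,
#'   the 5th and 95th forecast centiles).
#' @param observations realized counts.
#' @return percentage of observations inside \[lower, upper\].
#' @export
coverage_rate <- function(lower, upper, observations) {
  stopifnot(length(lower) == length(upper),
            length(lower) == length(observations))
  100 * mean(observations >= lower & observations <= upper)
}

#' Control settings for the forecasting harness
#'
#' @param eb_n_samples EB Monte-Carlo batch size (the reference value is
#'   1e5; the default trades a little Monte-Carlo precision for speed).
#' @param pacing_range EB pacing interval.
#' @param cv_folds trend-filter CV folds.
#' @param qrf_trees,qrf_mtry forest size and predictors per split.
#' @param lags lag depth of the regression features.
#' @param burn_in weeks of history required before the first forecast
#'   origin of a season.
#' @param arima_order ARIMA order.
#' @param within_tol relative tolerance of the hit-rate table.
#' @param logscore_tol half-width (visits) of the log-score band.
#' @param seed master seed; member-specific streams are derived from it.
#' @return a named list.
#' @export
eval_control <- function(eb_n_samples = 1e4, pacing_range = c(0.75, 1.25),
                         cv_folds = 5L, qrf_trees = 2000L, qrf_mtry = 4L,
                         lags = 3L, burn_in = 3L,
                         arima_order = c(2L, 0L, 1L),
                         within_tol = 0.20, logscore_tol = 25,
                         seed = 1L) {
  as.list(environment())
}

ALL_MEMBERS <- c("eb", "arima", "qrf", "lr")

# rows usable as training pairs (t, t+h): the feature window t-burn..t and
# the target t+h must lie entirely inside the training mask
eligible_training_rows <- function(n, h, train_mask, burn_in) {
  t <- seq(burn_in + 1L, n - h)
  ok <- vapply(t, function(i) all(train_mask[(i - burn_in):(i + h)]),
               logical(1))
  t[ok]
}

member_fit_all <- function(series, features, train_mask, members, horizons,
                           control, smoothed_cache, quantiles = TRUE) {
  fits <- list(failures = character())
  train <- series[train_mask, , drop = FALSE]
  n <- nrow(series)
  if ("eb" %in% members) {
    ids <- intersect(names(smoothed_cache), unique(train$season_id))
    if (length(ids) >= 1) fits$eb <- smoothed_cache[ids]
    else fits$failures <- c(fits$failures, "eb")
  }
  if ("arima" %in% members) {
    fits$arima <- tryCatch(
      arima_fit_member(train, order = control$arima_order),
      error = function(e) {
        fits$failures <<- c(fits$failures, paste0("arima: ", conditionMessage(e)))
        NULL
      })
  }
  for (m in intersect(c("qrf", "lr"), members)) {
    fits[[m]] <- list()
    for (h in horizons) {
      rows <- eligible_training_rows(n, h, train_mask, control$burn_in)
      X <- features[rows, , drop = FALSE]
      y <- series$ili_count[rows + h]
      fits[[m]][[as.character(h)]] <- tryCatch({
        if (m == "qrf") {
          qrf_fit(X[, qrf_feature_cols(control$lags), drop = FALSE], y,
                  n_trees = control$qrf_trees, m_try = control$qrf_mtry,
                  seed = sample.int(.Machine$integer.max / 2, 1),
                  quantiles = quantiles)
        } else {
          lr_fit(X, y)
        }
      }, error = function(e) {
        fits$failures <<- c(fits$failures,
                            paste0(m, "[h=", h, "]: ", conditionMessage(e)))
        NULL
      })
    }
  }
  fits
}

# forecast every origin of one season with every member; returns a long
# data.frame with q01..q99 columns (points only when centiles = FALSE)
member_predict_season <- function(fits, series, features, season,
                                  members, horizons, control,
                                  centiles = TRUE) {
  rows_s <- which(series$season_id == season)
  L <- length(rows_s)
  qcols <- sprintf("q%02d", 1:99)
  out <- list()
  add <- function(model, h, origin_row, point, cent) {
    rec <- data.frame(model = model, season_id = season, horizon = h,
                      origin_row = origin_row,
                      target_row = origin_row + h,
                      point = point)
    if (centiles) {
      cm <- as.matrix(cent)          # n x 99
      stopifnot(nrow(cm) == length(point), ncol(cm) == 99)
      colnames(cm) <- qcols
      rec <- cbind(rec, as.data.frame(cm))
    }
    out[[length(out) + 1L]] <<- rec
  }
  origins_wos <- function(h) seq(control$burn_in + 1L, L - h)

  if ("eb" %in% members && !is.null(fits$eb)) {
    obs <- series$ili_count[rows_s]
    all_wos <- seq(control$burn_in + 1L, L - min(horizons))
    fc <- eb_season_forecasts(fits$eb, obs, L, all_wos, horizons,
                              n_samples = control$eb_n_samples,
                              pacing_range = control$pacing_range)
    for (h in horizons) {
      sub <- fc[fc$horizon == h, , drop = FALSE]
      sub <- sub[sub$origin %in% origins_wos(h), , drop = FALSE]
      add("eb", h, rows_s[sub$origin], sub$point,
          if (centiles) as.matrix(sub[, qcols]))
    }
  }
  if ("arima" %in% members && !is.null(fits$arima)) {
    h_max <- max(horizons)
    res <- list()  # per origin: forecasts for all horizons in one recursion
    for (wos in origins_wos(min(horizons))) {
      r <- rows_s[wos]
      hh <- min(h_max, L - wos)
      res[[as.character(wos)]] <-
        arima_member_forecast(fits$arima, series[seq_len(r), , drop = FALSE],
                              series$epi_week[r + seq_len(hh)])
    }
    for (h in horizons) {
      ws <- origins_wos(h)
      pts <- vapply(as.character(ws), function(k) res[[k]][[h]]$point,
                    numeric(1))
      cents <- if (centiles)
        t(vapply(as.character(ws), function(k) res[[k]][[h]]$centiles,
                 numeric(99)))
      add("arima", h, rows_s[ws], unname(pts), cents)
    }
  }
  for (m in intersect(c("qrf", "lr"), members)) {
    for (h in horizons) {
      fit <- fits[[m]][[as.character(h)]]
      if (is.null(fit)) next
      orows <- rows_s[origins_wos(h)]
      X <- features[orows, , drop = FALSE]
      if (m == "qrf") {
        Xq <- X[, qrf_feature_cols(control$lags), drop = FALSE]
        if (centiles) {
          fcs <- qrf_forecast(fit, Xq, horizon = h)
          add(m, h, orows, vapply(fcs, `[[`, numeric(1), "point"),
              t(vapply(fcs, `[[`, numeric(99), "centiles")))
        } else {
          add(m, h, orows,
              stats::predict(fit$rf, Xq, num.threads = 1)$predictions, NULL)
        }
      } else {
        fcs <- lr_forecast(fit, X, horizon = h)
        add(m, h, orows, vapply(fcs, `[[`, numeric(1), "point"),
            if (centiles) t(vapply(fcs, `[[`, numeric(99), "centiles")))
      }
    }
  }
  do.call(rbind, out)
}

#' Build the leave-one-season-out stacking panel
#'
#' For every training season s' (the evaluation season is excluded
#' entirely), all members are refit on the data minus s' (and minus the
#' evaluation season) and predict s' week by week; rows are concatenated
#' across the held-out seasons.
#'
#' @param series season-indexed weekly series.
#' @param features precomputed [build_features()] table.
#' @param exclude_season evaluation season kept out of the whole loop.
#' @param members member names.
#' @param horizons forecast horizons.
#' @param control an [eval_control()].
#' @param smoothed_cache named list of smoothed trajectories per season.
#' @return list of per-horizon panels (`data.frame` with member columns
#'   and `y`), plus a count of dropped rows per member.
#' @export
build_stacking_panel <- function(series, features, exclude_season, members,
                                 horizons, control, smoothed_cache) {
  seasons <- setdiff(unique(series$season_id), exclude_season)
  if (length(seasons) < 3)
    stop("need at least 3 seasons besides the evaluation season",
         call. = FALSE)
  panels <- stats::setNames(
    lapply(horizons, function(h) NULL), as.character(horizons))
  for (s2 in seasons) {
    train_mask <- !series$season_id %in% c(exclude_season, s2)
    fits <- member_fit_all(series, features, train_mask, members, horizons,
                           control, smoothed_cache, quantiles = FALSE)
    ft <- member_predict_season(fits, series, features, s2, members,
                                horizons, control, centiles = FALSE)
    for (h in horizons) {
      sub <- ft[ft$horizon == h, , drop = FALSE]
      wide <- NULL
      for (m in unique(sub$model)) {
        mm <- sub[sub$model == m, c("origin_row", "target_row", "point")]
        names(mm)[3] <- m
        wide <- if (is.null(wide)) mm else
          merge(wide, mm, by = c("origin_row", "target_row"), all = TRUE)
      }
      if (is.null(wide)) next
      for (m in members)  # a member that failed on this fold: NA column
        if (!m %in% names(wide)) wide[[m]] <- NA_real_
      wide$y <- series$ili_count[wide$target_row]
      wide <- wide[order(wide$origin_row),
                   c("origin_row", "target_row", members, "y")]
      panels[[as.character(h)]] <- rbind(panels[[as.character(h)]], wide)
    }
  }
  panels
}

#' Leave-one-season-out evaluation of all members and ensembles
#'
#' Implements the full evaluation protocol: each season is held out in
#' turn; stacking weights are estimated per horizon from an inner
#' hold-one-season-out loop over the remaining seasons (the evaluation
#' season never contributes); members are then refit on all non-test data
#' and forecast every eligible week of the test season at every horizon;
#' the stacked and naive ensembles combine the member forecasts.  The
#' returned report carries pooled MAE/RMSE/MAPE per model and horizon,
#' mean log scores per season, within-20% hit rates (all weeks and
#' high-volume weeks) for the 1-week horizon, 90% interval coverage, and
#' the stacking-weight table.
#'
#' @param series a weekly series (indexed with [build_season_index()] if
#'   not already).
#' @param members member subset.
#' @param horizons horizons, subset of 1:4.
#' @param control an [eval_control()].
#' @return an object of class `"ili_evaluation"`.
#' @export
loso_evaluate <- function(series, members = ALL_MEMBERS, horizons = 1:4,
                          control = eval_control()) {
  if (!"season_id" %in% names(series))
    series <- build_season_index(series)
  stopifnot(all(members %in% ALL_MEMBERS), all(horizons %in% 1:4))
  seasons <- unique(series$season_id)
  if (length(seasons) < 4)
    stop(sprintf(paste0(
      "leave-one-season-out stacking needs at least 4 seasons ",
      "(3 besides each test season); got %d. Simulate or supply more seasons."),
      length(seasons)), call. = FALSE)
  set.seed(control$seed)
  lens <- table(series$season_id)[seasons]
  complete <- seasons[lens >= 52]
  smoothed <- stats::setNames(lapply(complete, function(s)
    smooth_season(series$ili_count[series$season_id == s],
                  cv_folds = control$cv_folds, season_id = s)), complete)
  features <- build_features(series, control$lags)

  weight_rows <- list()
  fts <- list()
  for (s in seasons) {
    panels <- build_stacking_panel(series, features, s, members, horizons,
                                   control, smoothed)
    W <- lapply(panels, stack_weights, members = members)
    train_mask <- series$season_id != s
    fits <- member_fit_all(series, features, train_mask, members, horizons,
                           control, smoothed)
    ft <- member_predict_season(fits, series, features, s, members,
                                horizons, control, centiles = TRUE)
    # ensemble rows: combine member forecasts per (origin, horizon)
    qcols <- sprintf("q%02d", 1:99)
    ens <- list()
    for (h in horizons) {
      w <- W[[as.character(h)]]
      sub <- ft[ft$horizon == h, , drop = FALSE]
      for (r in unique(sub$origin_row)) {
        rows <- sub[sub$origin_row == r, , drop = FALSE]
        if (!all(members %in% rows$model)) next
        P <- stats::setNames(rows$point, rows$model)
        Q <- as.matrix(rows[, qcols]); rownames(Q) <- rows$model
        for (lbl in c("stacked", "naive")) {
          wv <- if (lbl == "stacked") w else naive_weights(members)
          rec <- data.frame(model = lbl, season_id = s, horizon = h,
                            origin_row = r, target_row = r + h,
                            point = sum(wv * P[members]))
          cm <- matrix(as.numeric(wv %*% Q[members, , drop = FALSE]),
                       nrow = 1)
          colnames(cm) <- qcols
          ens[[length(ens) + 1L]] <- cbind(rec, cm)
        }
      }
      weight_rows[[length(weight_rows) + 1L]] <- data.frame(
        season_id = s, horizon = h, member = members,
        weight = as.numeric(w),
        panel_objective = attr(w, "objective"),
        naive_objective = attr(w, "naive_objective"))
    }
    fts[[length(fts) + 1L]] <- rbind(ft, do.call(rbind, ens))
  }
  ft_all <- do.call(rbind, fts)
  ft_all$observed <- series$ili_count[ft_all$target_row]
  report <- build_report(ft_all, series, control)
  report$weights <- do.call(rbind, weight_rows)
  report$forecasts <- ft_all
  report$control <- control
  class(report) <- "ili_evaluation"
  report
}

build_report <- function(ft, series, control) {
  qcols <- sprintf("q%02d", 1:99)
  models <- unique(ft$model)
  seasons <- unique(ft$season_id)
  high <- label_high_volume(series)

  pooled <- list(); cover <- list(); ls_rows <- list(); w20 <- list()
  for (m in models) for (h in sort(unique(ft$horizon))) {
    sub <- ft[ft$model == m & ft$horizon == h, , drop = FALSE]
    if (nrow(sub) == 0) next
    pm <- point_metrics(sub$point, sub$observed)
    pooled[[length(pooled) + 1L]] <- data.frame(
      model = m, horizon = h, n = nrow(sub),
      mae = pm$mae, rmse = pm$rmse, mape_pct = pm$mape_pct)
    cover[[length(cover) + 1L]] <- data.frame(
      model = m, horizon = h,
      coverage_90_pct = coverage_rate(sub$q05, sub$q95, sub$observed))
    qmat <- as.matrix(sub[, qcols])
    for (s in seasons) {
      si <- which(sub$season_id == s)
      if (length(si) == 0) next
      scores <- vapply(si, function(i)
        log_score(qmat[i, ], sub$observed[i],
                  tolerance = control$logscore_tol), numeric(1))
      ls_rows[[length(ls_rows) + 1L]] <- data.frame(
        model = m, horizon = h, season_id = s,
        mean_log_score = mean(scores), n = length(si))
    }
    if (h == 1L) {
      for (s in c(seasons, "all")) {
        ss <- if (s == "all") sub else sub[sub$season_id == s, , drop = FALSE]
        if (nrow(ss) == 0) next
        hi <- high[ss$target_row]
        w20[[length(w20) + 1L]] <- data.frame(
          model = m, season_id = s,
          within_pct_all = within_tolerance_rate(ss$point, ss$observed,
                                                 control$within_tol),
          within_pct_high = if (sum(hi) > 0)
            within_tolerance_rate(ss$point[hi], ss$observed[hi],
                                  control$within_tol) else NA_real_)
      }
    }
  }
  list(metrics_pooled = do.call(rbind, pooled),
       logscore_by_season = do.call(rbind, ls_rows),
       within20_by_season = do.call(rbind, w20),
       coverage = do.call(rbind, cover))
}

#' @export
print.ili_evaluation <- function(x, ...) {
  cat("Leave-one-season-out evaluation\n")
  cat("Pooled point-forecast metrics:\n")
  print(x$metrics_pooled, row.names = FALSE, digits = 4)
  cat("\n90% interval coverage (percent):\n")
  print(x$coverage, row.names = FALSE, digits = 4)
  invisible(x)
}
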