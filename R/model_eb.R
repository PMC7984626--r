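#' Empirical-Bayes forecaster
#'
#' The EB model forms a prior over the current season's epidemic curve by
#' transforming smoothed curves of past seasons: a source curve is drawn
#' uniformly from the pool, vertically rescaled to a peak height sampled
#' from the pool's peak heights, shifted so its peak lands on a peak week
#' sampled from the pool's peak weeks, and time-dilated about the peak by a
#' pacing factor drawn from U\[0.75, 1.25\].  Each transformed curve gets a
#' Gaussian likelihood weight from its fit to the season-to-date, and
#' N(0, sigma_s^2) observation noise (sigma_s from the source season's
#' smoothing residuals) is injected last.  The forecast at week t + l is
#' the weighted median of the noisy sample values at that week; forecast
#' centiles are weighted percentiles of the same sample.
#'
#' @name model-eb
NULL

#' Sample a batch of transformed candidate epidemic curves
#'
#' Peak-height and peak-week targets are drawn independently from the
#' pool's collections of smoothed peak heights and weeks; the pacing factor
#' rescales time about the (shifted) peak, and values outside the source
#' curve's domain use edge-hold extrapolation.
#'
#' @param pool list of [smooth_season()] trajectories.
#' @param n number of curves.
#' @param length_out length of the target season in weeks.
#' @param pacing_range pacing interval (default U\[0.75, 1.25\]).
#' @param transform if `FALSE`, curves are copied untransformed (pacing 1,
#'   own peak height/week) -- used for diagnostics.
#' @return list with `values` (n x length_out matrix), `sigma`, `source`,
#'   `height_target`, `location_target`, `pacing` (all length n).
#' @export
eb_sample_curves <- function(pool, n, length_out,
                             pacing_range = c(0.75, 1.25),
                             transform = TRUE) {
  stopifnot(length(pool) >= 1, n >= 1)
  heights <- vapply(pool, `[[`, numeric(1), "peak_height")
  locations <- vapply(pool, `[[`, numeric(1), "peak_week")
  sigmas <- vapply(pool, `[[`, numeric(1), "sigma")
  src <- sample.int(length(pool), n, replace = TRUE)
  if (transform) {
    h_t <- heights[sample.int(length(pool), n, replace = TRUE)]
    p_t <- locations[sample.int(length(pool), n, replace = TRUE)]
    pace <- stats::runif(n, pacing_range[1], pacing_range[2])
  } else {
    h_t <- heights[src]
    p_t <- locations[src]
    pace <- rep(1, n)
  }
  grid <- seq_len(length_out)
  values <- matrix(0, n, length_out)
  for (k in seq_len(n)) {
    s <- pool[[src[k]]]
    # evaluate source at p0 + (t - p_target) * pacing, rescale to h_target
    tt <- s$peak_week + (grid - p_t[k]) * pace[k]
    v <- stats::approx(seq_along(s$values), s$values, xout = tt,
                       rule = 2)$y
    values[k, ] <- v * (h_t[k] / s$peak_height)
  }
  list(values = values, sigma = sigmas[src], source = src,
       height_target = h_t, location_target = p_t, pacing = pace)
}

#' Gaussian likelihood weights for transformed curves
#'
#' Computed in log space; the batch maximum log-weight is subtracted before
#' exponentiating, so the best-fitting curve has weight 1 before
#' normalization.  An empty season-to-date gives uniform weights.
#'
#' @param values n x L matrix of candidate curves.
#' @param observed_to_date observed counts, weeks 1..t of the season.
#' @param sigma per-curve noise SD (length n).
#' @return nonnegative weights, max 1.
#' @export
eb_likelihood_weights <- function(values, observed_to_date, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  t_now <- length(observed_to_date)
  if (t_now == 0) return(rep(1, nrow(values)))
  err <- sweep(values[, seq_len(t_now), drop = FALSE], 2, observed_to_date)
  sse <- rowSums(err^2)
  lw <- -sse / (2 * sigma^2)
  w <- exp(lw - max(lw))
  if (!all(is.finite(w)) || sum(w) == 0) {
    warning("all likelihood weights numerically zero; falling back to uniform")
    w <- rep(1, nrow(values))
  }
  w
}

# point (weighted median) and 99 centiles from pre-sorted values/weights
eb_point_and_centiles <- function(x_sorted, w_sorted) {
  w <- w_sorted / sum(w_sorted)
  cw <- cumsum(w)
  below <- cw - w
  k <- which(below <= 0.5 & (1 - cw) <= 0.5)[1]
  point <- x_sorted[k]
  n <- length(x_sorted)
  denom <- 1 - w[n]
  if (denom <= 0) {
    cent <- rep(x_sorted[n], 99)
  } else {
    pos <- (cw - w) / denom
    pos[n] <- 1
    cent <- stats::approx(pos, x_sorted, xout = (1:99) / 100,
                          ties = "ordered", rule = 2)$y
  }
  list(point = point, centiles = cent)
}

#' Empirical-Bayes forecasts for a whole season pass
#'
#' Draws one Monte-Carlo batch of transformed curves and produces forecasts
#' for every requested origin week and horizon of the target season.  The
#' batch is shared across origins -- the candidates are i.i.d. draws from
#' the same prior regardless of the origin -- while the likelihood weights
#' are recomputed at each origin from the season-to-date via cumulative
#' squared errors.  Weighting uses the noise-free transformed curves; the
#' reported forecast sample has the injected N(0, sigma_s^2) noise.
#'
#' @param pool list of smoothed past-season trajectories.
#' @param observed target-season counts observed so far (forecasts at origin
#'   t use entries 1..t).
#' @param season_length full length of the target season.
#' @param origins integer vector of origin weeks (week-of-season).
#' @param horizons horizons to forecast, subset of 1:4.
#' @param n_samples Monte-Carlo batch size.
#' @param pacing_range pacing interval.
#' @param noise inject observation noise into the forecast sample.
#' @return data.frame with columns `origin`, `horizon`, `point`,
#'   `q01`..`q99` (one row per origin x horizon with origin + horizon
#'   inside the season).
#' @export
eb_season_forecasts <- function(pool, observed, season_length, origins,
                                horizons = 1:4, n_samples = 1e4,
                                pacing_range = c(0.75, 1.25),
                                noise = TRUE) {
  stopifnot(length(pool) >= 1)
  batch <- eb_sample_curves(pool, n_samples, season_length, pacing_range)
  vals <- batch$values
  n <- nrow(vals)
  noisy <- if (noise) {
    vals + matrix(stats::rnorm(n * season_length, 0, batch$sigma),
                  n, season_length)
  } else vals
  noisy <- pmax(noisy, 0)

  # cumulative log-likelihoods: column t holds sum over weeks 1..t
  t_max <- min(max(origins), length(observed))
  if (t_max >= 1) {
    cum_sse <- sweep(vals[, seq_len(t_max), drop = FALSE], 2,
                     observed[seq_len(t_max)])^2
    for (j in seq_len(t_max)[-1])
      cum_sse[, j] <- cum_sse[, j - 1] + cum_sse[, j]
  }

  # pre-sort each target week's noisy values once
  ords <- lapply(seq_len(season_length), function(j) order(noisy[, j]))

  out <- list()
  for (t0 in origins) {
    if (t0 > length(observed)) next
    lw <- if (t0 == 0) rep(0, n) else -cum_sse[, t0] / (2 * batch$sigma^2)
    w <- exp(lw - max(lw))
    if (!all(is.finite(w)) || sum(w) == 0) {
      warning("all likelihood weights numerically zero; falling back to uniform")
      w <- rep(1, n)
    }
    for (h in horizons) {
      tgt <- t0 + h
      if (tgt > season_length) next
      o <- ords[[tgt]]
      pc <- eb_point_and_centiles(noisy[o, tgt], w[o])
      out[[length(out) + 1L]] <-
        c(origin = t0, horizon = h, point = pc$point,
          stats::setNames(pc$centiles, sprintf("q%02d", 1:99)))
    }
  }
  as.data.frame(do.call(rbind, out))
}

#' One empirical-Bayes forecast
#'
#' User-level API: smooths every complete past season in `history` into the
#' trajectory pool (unless a pre-smoothed pool is supplied), then forecasts
#' `horizon` weeks past `current_week` of the current (last) season.
#'
#' @param history a season-indexed weekly series whose last season is the
#'   one being forecast.
#' @param current_week week-of-season of the forecast origin.
#' @param horizon forecast horizon, 1--4.
#' @param n_samples Monte-Carlo batch size (the reference configuration is
#'   1e5; smaller batches trade precision for speed).
#' @param pacing_range,noise see [eb_season_forecasts()].
#' @param cv_folds CV folds for season smoothing.
#' @param pool optional pre-computed list of smoothed trajectories.
#' @return a [forecast_dist()].
#' @export
eb_forecast <- function(history, current_week, horizon,
                        n_samples = 1e5, pacing_range = c(0.75, 1.25),
                        noise = TRUE, cv_folds = 5L, pool = NULL) {
  stopifnot("season_id" %in% names(history))
  seasons <- unique(history$season_id)
  cur <- seasons[length(seasons)]
  past <- setdiff(seasons, cur)
  if (is.null(pool)) {
    lens <- table(history$season_id)[past]
    complete <- past[lens >= 52]
    if (length(complete) < 2)
      stop("need at least 2 complete past seasons in history", call. = FALSE)
    pool <- lapply(complete, function(s)
      smooth_season(history$ili_count[history$season_id == s],
                    cv_folds = cv_folds, season_id = s))
  }
  cur_rows <- history$season_id == cur
  observed <- history$ili_count[cur_rows][seq_len(current_week)]
  season_length <- max(52L, current_week + horizon)
  fc <- eb_season_forecasts(pool, observed, season_length,
                            origins = current_week, horizons = horizon,
                            n_samples = n_samples,
                            pacing_range = pacing_range, noise = noise)
  if (nrow(fc) == 0)
    stop("current_week + horizon falls outside the season", call. = FALSE)
  forecast_dist(made_at_week = history$week_start[cur_rows][current_week],
                horizon = horizon, point = fc$point[1],
                centiles = as.numeric(fc[1, sprintf("q%02d", 1:99)]),
                model = "eb")
}
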