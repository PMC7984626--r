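#' Probabilistic forecast container
#'
#' Every member model and ensemble emits the same object: a point forecast
#' plus the 99 forecast centiles.  Centiles must be nondecreasing; negative
#' values are floored at zero on construction (counts cannot be negative),
#' while `point` is floored only when `floor_point = TRUE` (the default for
#' reported forecasts).
#'
#' @param made_at_week identifier of the forecast origin week (a `Date` or
#'   row index).
#' @param horizon forecast horizon in weeks, 1--4.
#' @param point point forecast.
#' @param centiles numeric vector of length 99, the 1st..99th forecast
#'   centiles.
#' @param model model label.
#' @param floor_point floor the point forecast at 0 as well.
#' @return an object of class `"forecast_dist"`.
#' @export
forecast_dist <- function(made_at_week, horizon, point, centiles,
                          model = "unknown", floor_point = TRUE) {
  stopifnot(length(centiles) == 99, length(point) == 1)
  if (!horizon %in% 1:4)
    stop("horizon must be in 1..4", call. = FALSE)
  if (any(diff(centiles) < -1e-8))
    stop("forecast centiles must be nondecreasing", call. = FALSE)
  centiles <- cummax(pmax(centiles, 0))
  if (floor_point) point <- max(point, 0)
  structure(list(made_at_week = made_at_week,
                 horizon = as.integer(horizon),
                 point = as.numeric(point),
                 centiles = as.numeric(centiles),
                 model = model),
            class = "forecast_dist")
}

#' @export
print.forecast_dist <- function(x, ...) {
  cat(sprintf("<forecast_dist> %s, %d wk ahead from %s\n", x$model,
              x$horizon, format(x$made_at_week)))
  cat(sprintf("  point %.1f, 90%% PI [%.1f, %.1f]\n",
              x$point, x$centiles[5], x$centiles[95]))
  invisible(x)
}

#' Weighted median of a sample
#'
#' Returns the smallest sample value \eqn{f_k} (after sorting) such that the
#' total normalized weight strictly below it is at most 1/2 and the total
#' weight strictly above it is at most 1/2.  With equal weights and an odd
#' sample size this is the ordinary median.
#'
#' @param x numeric sample.
#' @param w nonnegative weights (need not be normalized).
#' @return the weighted median value.
#' @export
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0))
  if (sum(w) <= 0) stop("all weights are zero", call. = FALSE)
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w)
  below <- cw - w        # weight strictly before position k
  above <- 1 - cw        # weight strictly after position k
  k <- which(below <= 0.5 & above <= 0.5)[1]
  x[k]
}

#' Weighted sample quantiles with interpolation
#'
#' Generalizes the standard continuous sample-quantile convention
#' (`stats::quantile` type 7) to weighted samples: sorted values are placed
#' at cumulative positions \eqn{(C_i - w_i) / (1 - w_n)} (so equal weights
#' reproduce type 7 exactly) and quantiles are linear interpolations.
#'
#' @param x numeric sample.
#' @param w nonnegative weights.
#' @param probs probabilities in \[0, 1\].
#' @return numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0))
  sw <- sum(w)
  if (sw <= 0) stop("all weights are zero", call. = FALSE)
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sw
  n <- length(x)
  if (n == 1) return(rep(x, length(probs)))
  denom <- 1 - w[n]
  if (denom <= 0) return(rep(x[n], length(probs)))  # all mass on the top value
  pos <- (cumsum(w) - w) / denom
  pos[n] <- 1  # guard rounding
  stats::approx(pos, x, xout = pmin(pmax(probs, 0), 1),
                ties = "ordered", rule = 2)$y
}

#' The 99 forecast centiles of a weighted sample
#'
#' @param x numeric sample.
#' @param w nonnegative weights.
#' @return numeric vector of length 99.
#' @keywords internal
centiles_of <- function(x, w = rep(1, length(x))) {
  weighted_quantile(x, w, probs = (1:99) / 100)
}
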