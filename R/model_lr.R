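#' Covariate linear regression member
#'
#' Ordinary least squares of the l-weeks-ahead ILI count on the current
#' count, temperature, immunization rate, population, year trend, epi-week
#' fixed effects, the current slope of the ILI curve and the categorical
#' count of upward movements over the preceding three weeks.  One fit per
#' forecast horizon (the target is shifted by l).  Prediction intervals
#' are Gaussian with SD equal to the prediction standard error, which
#' includes both the parameter uncertainty and the residual variance.
#'
#' @name model-lr
NULL

#' Fit the LR member
#'
#' @param features training feature `data.frame` containing the columns of
#'   `lr_feature_cols()`; `epi_week` and `upward` are coded as factors.
#' @param targets numeric response (counts l weeks ahead).
#' @return an object of class `"lr_fit"`.
#' @export
lr_fit <- function(features, targets) {
  cc <- stats::complete.cases(features) & !is.na(targets)
  dat <- features[cc, lr_feature_cols(), drop = FALSE]
  dat$epi_week <- droplevels(factor(dat$epi_week))
  dat$upward <- droplevels(factor(dat$upward))
  dat$.y <- targets[cc]
  fit <- stats::lm(.y ~ ., data = dat)
  bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(bad) > 0)
    stop("rank-deficient LR design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(lm = fit,
                 residual_sd = summary(fit)$sigma,
                 epi_week_levels = levels(dat$epi_week),
                 upward_levels = levels(dat$upward)),
            class = "lr_fit")
}

#' Forecast with the LR member
#'
#' @param fit an `"lr_fit"`.
#' @param x feature rows at the forecast origins.
#' @param made_at_week,horizon metadata for the returned forecasts.
#' @return a list of [forecast_dist()], one per row of `x`.
#' @export
lr_forecast <- function(fit, x, made_at_week = NA, horizon = 1L) {
  stopifnot(inherits(fit, "lr_fit"))
  nd <- x[, lr_feature_cols(), drop = FALSE]
  nd$epi_week <- clamp_level(nd$epi_week, fit$epi_week_levels, "epi_week")
  nd$upward <- clamp_level(nd$upward, fit$upward_levels, "upward")
  pr <- stats::predict(fit$lm, newdata = nd, se.fit = TRUE)
  sd_pred <- sqrt(pr$se.fit^2 + fit$residual_sd^2)
  z <- stats::qnorm((1:99) / 100)
  made <- rep(made_at_week, length.out = nrow(nd))
  lapply(seq_len(nrow(nd)), function(i)
    forecast_dist(made_at_week = made[i], horizon = horizon,
                  point = pr$fit[i],
                  centiles = pr$fit[i] + sd_pred[i] * z,
                  model = "lr"))
}

# map numeric values onto the nearest factor level seen in training
clamp_level <- function(x, levels_seen, what) {
  num <- as.numeric(levels_seen)
  xv <- as.numeric(as.character(x))
  unseen <- !xv %in% num
  if (any(unseen)) {
    warning(sprintf("unseen %s level(s) %s mapped to nearest training level",
                    what, paste(unique(xv[unseen]), collapse = ", ")))
    xv[unseen] <- vapply(xv[unseen],
                         function(v) num[which.min(abs(num - v))],
                         numeric(1))
  }
  factor(xv, levels = num)
}
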