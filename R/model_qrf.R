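#' Quantile regression forest member
#'
#' A bagged random forest (2000 trees, 4 predictors tried per split by
#' default -- the square-root heuristic for the predictor count) whose
#' point forecast is the forest mean and whose forecast centiles come from
#' the Meinshausen weighted empirical CDF: each training observation is
#' weighted by its average co-leaf bootstrap frequency with the query
#' point across trees.
#'
#' @name model-qrf
NULL

#' Square-root heuristic for the number of predictors per split
#'
#' @param p number of available predictors.
#' @return `floor(sqrt(p))`.
#' @export
mtry_heuristic <- function(p) max(1L, floor(sqrt(p)))

#' Fit the QRF member
#'
#' @param features training feature `data.frame` (numeric columns).
#' @param targets numeric response.
#' @param n_trees number of trees.
#' @param m_try predictors sampled per split.
#' @param seed RNG seed for the forest.
#' @param min_node_size minimal node size (ranger default if `NULL`).
#' @param quantiles retain the leaf maps needed for centile prediction
#'   (disable when only point forecasts are required).
#' @param ... further arguments passed to [ranger::ranger()]
#'   (e.g. `replace`, `sample.fraction`).
#' @return an object of class `"qrf_fit"` retaining the per-tree leaf
#'   membership and inbag counts of the training observations.
#' @export
qrf_fit <- function(features, targets, n_trees = 2000L, m_try = 4L,
                    seed = 1L, min_node_size = NULL, quantiles = TRUE,
                    ...) {
  stopifnot(nrow(features) == length(targets))
  if (m_try > ncol(features))
    stop(sprintf("m_try (%d) exceeds the number of predictors (%d)",
                 m_try, ncol(features)), call. = FALSE)
  cc <- stats::complete.cases(features) & !is.na(targets)
  features <- features[cc, , drop = FALSE]
  targets <- targets[cc]
  if (nrow(features) < 30)
    stop("need at least 30 complete training rows", call. = FALSE)
  dat <- cbind(features, .y = targets)
  rf <- ranger::ranger(
    dependent.variable.name = ".y", data = dat,
    num.trees = n_trees, mtry = m_try, keep.inbag = TRUE,
    min.node.size = if (is.null(min_node_size)) 5 else min_node_size,
    seed = seed, num.threads = 1, ...)
  if (quantiles) {
    leaf_train <- stats::predict(rf, features, type = "terminalNodes",
                                 num.threads = 1)$predictions
    inbag <- do.call(cbind, rf$inbag.counts)
  } else {
    leaf_train <- NULL
    inbag <- NULL
  }
  structure(list(rf = rf, targets = targets,
                 leaf_train = leaf_train, inbag = inbag,
                 schema = names(features),
                 n_trees = n_trees, m_try = m_try),
            class = "qrf_fit")
}

# Meinshausen weights: rows = query points, cols = training observations
qrf_weights <- function(fit, leaf_query) {
  n_train <- nrow(fit$leaf_train)
  n_query <- nrow(leaf_query)
  W <- matrix(0, n_query, n_train)
  B <- ncol(fit$leaf_train)
  for (b in seq_len(B)) {
    tl <- fit$leaf_train[, b]
    ib <- fit$inbag[, b]
    # bootstrap mass per leaf of this tree
    mass <- tapply(ib, tl, sum)
    wb <- ib / as.numeric(mass[as.character(tl)])
    match_mat <- outer(leaf_query[, b], tl, "==")
    W <- W + match_mat * rep(wb, each = n_query)
  }
  W / B
}

#' Forecast with the QRF member
#'
#' @param fit a `"qrf_fit"`.
#' @param x feature rows to predict (must match the training schema).
#' @param made_at_week,horizon metadata for the returned forecasts.
#' @return a list of [forecast_dist()], one per row of `x`.
#' @export
qrf_forecast <- function(fit, x, made_at_week = NA, horizon = 1L) {
  stopifnot(inherits(fit, "qrf_fit"))
  missing <- setdiff(fit$schema, names(x))
  if (length(missing) > 0)
    stop("feature row is missing predictor(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  x <- x[, fit$schema, drop = FALSE]
  if (anyNA(x))
    stop("feature row contains NA (insufficient history?)", call. = FALSE)
  if (is.null(fit$leaf_train))
    stop("fit was built with quantiles = FALSE; refit to get centiles",
         call. = FALSE)
  point <- stats::predict(fit$rf, x, num.threads = 1)$predictions
  leaf_q <- stats::predict(fit$rf, x, type = "terminalNodes",
                           num.threads = 1)$predictions
  W <- qrf_weights(fit, leaf_q)
  made <- rep(made_at_week, length.out = nrow(x))
  lapply(seq_len(nrow(x)), function(i)
    forecast_dist(made_at_week = made[i], horizon = horizon,
                  point = point[i],
                  centiles = weighted_quantile(fit$targets, W[i, ],
                                               (1:99) / 100),
                  model = "qrf"))
}
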