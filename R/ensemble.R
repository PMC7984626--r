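#' Stacked and naive ensembles
#'
#' Stacking weights minimize the held-out mean squared error of the
#' weighted member forecast subject to the weights lying on the
#' probability simplex (nonnegative, summing to one).  With M members the
#' problem is a tiny quadratic program; it is solved exactly by
#' enumerating all 2^M - 1 candidate supports and solving each
#' equality-constrained least-squares subproblem via its KKT system,
#' keeping the feasible solution with the smallest objective (ties broken
#' by the minimum-norm weight vector).
#'
#' @name ensemble
NULL

#' Exact simplex-constrained least squares
#'
#' Minimizes `mean((y - F w)^2)` subject to `sum(w) == 1`, `w >= 0`.
#'
#' @param F H x M matrix of member predictions.
#' @param y observed vector of length H.
#' @return list with `w`, `objective` (mean squared error at `w`) and
#'   `degenerate` (`TRUE` when all member columns coincide and equal
#'   weights are returned by convention).
#' @export
simplex_lsq <- function(F, y) {
  F <- as.matrix(F)
  M <- ncol(F); H <- nrow(F)
  stopifnot(length(y) == H, H >= 1, M >= 1)
  spread <- max(apply(F, 1, function(r) diff(range(r))))
  if (spread < 1e-10 * max(1, max(abs(F)))) {
    w <- rep(1 / M, M)
    return(list(w = w, objective = mean((y - F %*% w)^2), degenerate = TRUE))
  }
  G <- crossprod(F)          # M x M
  b <- crossprod(F, y)
  best <- NULL
  for (code in seq_len(2^M - 1)) {
    S <- which(bitwAnd(code, 2^(seq_len(M) - 1)) > 0)
    k <- length(S)
    KKT <- rbind(cbind(G[S, S, drop = FALSE], rep(1, k)),
                 c(rep(1, k), 0))
    rhs <- c(b[S], 1)
    sol <- tryCatch(solve(KKT, rhs), error = function(e) NULL)
    if (is.null(sol)) {
      # singular subsystem: minimum-norm KKT solution via pseudo-inverse
      sv <- svd(KKT)
      pos <- sv$d > 1e-10 * max(sv$d)
      sol <- sv$v[, pos, drop = FALSE] %*%
        ((crossprod(sv$u[, pos, drop = FALSE], rhs)) / sv$d[pos])
      sol <- as.numeric(sol)
    }
    wS <- sol[seq_len(k)]
    if (any(wS < -1e-9)) next
    w <- numeric(M)
    w[S] <- pmax(wS, 0)
    w <- w / sum(w)
    obj <- mean((y - F %*% w)^2)
    if (is.null(best) ||
        obj < best$objective - 1e-12 * (1 + best$objective) ||
        (abs(obj - best$objective) <= 1e-12 * (1 + best$objective) &&
         sum(w^2) < sum(best$w^2))) {
      best <- list(w = w, objective = obj, degenerate = FALSE)
    }
  }
  if (is.null(best)) {  # numerically pathological; equal weights fallback
    w <- rep(1 / M, M)
    best <- list(w = w, objective = mean((y - F %*% w)^2), degenerate = TRUE)
  }
  best
}

#' Stacking weights from a held-out prediction panel
#'
#' The panel must contain one column per member (named after the member)
#' and a column `y` of observed counts; every row's predictions come from
#' member fits trained without that row's season.  Rows with any missing
#' entry are dropped listwise.  The returned weights are checked against
#' the two feasibility bounds implied by the simplex: the in-panel
#' objective never exceeds that of any single member nor of the naive
#' equal-weight ensemble.
#'
#' @param panel `data.frame` with member columns and `y`.
#' @param members character vector naming the member columns.
#' @return a named weight vector with attributes `objective`,
#'   `member_objectives`, `naive_objective` and `degenerate`.
#' @export
stack_weights <- function(panel, members = setdiff(names(panel), "y")) {
  stopifnot("y" %in% names(panel), length(members) >= 1)
  # a member with no usable prediction at all is dropped (weight 0)
  # rather than wiping out every row via listwise deletion
  usable <- members[vapply(members, function(m) any(!is.na(panel[[m]])),
                           logical(1))]
  if (length(usable) == 0)
    stop("no member has any usable panel prediction", call. = FALSE)
  keep <- stats::complete.cases(panel[, c(usable, "y")])
  panel <- panel[keep, , drop = FALSE]
  if (nrow(panel) < length(usable))
    stop(sprintf("stacking panel has %d complete rows; need at least %d",
                 nrow(panel), length(usable)), call. = FALSE)
  F <- as.matrix(panel[, usable, drop = FALSE])
  y <- panel$y
  sol <- simplex_lsq(F, y)
  member_obj <- apply(F, 2, function(col) mean((y - col)^2))
  naive_obj <- mean((y - rowMeans(F))^2)
  tol <- 1e-8 * (1 + max(member_obj))
  stopifnot(sol$objective <= min(member_obj) + tol,
            sol$objective <= naive_obj + tol)
  w <- stats::setNames(numeric(length(members)), members)
  w[usable] <- sol$w
  mo <- stats::setNames(rep(NA_real_, length(members)), members)
  mo[usable] <- member_obj
  attr(w, "objective") <- sol$objective
  attr(w, "member_objectives") <- mo
  attr(w, "naive_objective") <- naive_obj
  attr(w, "degenerate") <- sol$degenerate
  attr(w, "dropped_members") <- setdiff(members, usable)
  w
}

#' Equal weights for the naive ensemble
#'
#' @param members member names (or an integer count).
#' @return named weight vector, all entries `1/M`.
#' @export
naive_weights <- function(members) {
  if (is.numeric(members) && length(members) == 1)
    members <- paste0("m", seq_len(members))
  M <- length(members)
  stopifnot(M >= 1)
  stats::setNames(rep(1 / M, M), members)
}

#' Combine member forecasts into an ensemble forecast
#'
#' Point and every centile are the weight-averaged member values (the
#' back-of-the-envelope ensemble interval: a weighted average of member
#' forecast quantiles).
#'
#' @param w named weight vector over the members.
#' @param member_forecasts named list of [forecast_dist()] objects sharing
#'   origin and horizon.
#' @param model label for the combined forecast.
#' @return a [forecast_dist()].
#' @export
ensemble_forecast <- function(w, member_forecasts, model = "stacked") {
  stopifnot(all(names(w) %in% names(member_forecasts)))
  fcs <- member_forecasts[names(w)]
  horizons <- vapply(fcs, `[[`, integer(1), "horizon")
  if (length(unique(horizons)) != 1)
    stop("member forecasts have mismatched horizons: ",
         paste(horizons, collapse = ", "), call. = FALSE)
  point <- sum(w * vapply(fcs, `[[`, numeric(1), "point"))
  qs <- vapply(fcs, `[[`, numeric(99), "centiles")  # 99 x M
  centiles <- as.numeric(qs %*% w)
  forecast_dist(made_at_week = fcs[[1]]$made_at_week,
                horizon = horizons[1], point = point,
                centiles = centiles, model = model)
}
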