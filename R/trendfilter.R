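#' Quadratic trend filtering by ADMM
#'
#' Minimizes \eqn{\frac12 \sum_i m_i (y_i - f_i)^2 + \lambda \|D^{(3)} f\|_1}
#' where \eqn{D^{(3)}} is the third-difference operator, so the fit is a
#' piecewise-quadratic curve with adaptively chosen knots.  `m` is a 0/1
#' observation mask used by the cross-validation routine.
#'
#' @param y numeric response at equally spaced points.
#' @param lambda penalty level.
#' @param mask 0/1 observation weights.
#' @param rho ADMM step size (defaults to `lambda`).
#' @param max_iter,tol iteration cap and residual tolerance.
#' @return list with the fitted values `f`, `lambda`, iteration count and a
#'   convergence flag.
#' @keywords internal
trendfilter_admm <- function(y, lambda, mask = rep(1, length(y)),
                             rho = max(lambda, 1e-4),
                             max_iter = 2000L, tol = 1e-5,
                             relax = 1.8, init = NULL) {
  n <- length(y)
  stopifnot(n >= 5)
  D <- diff(diag(n), differences = 3)
  DtD <- crossprod(D)
  refactor <- function(rho) chol(diag(mask) + rho * DtD)
  R <- refactor(rho)
  Rt <- t(R)
  if (is.null(init)) {
    f <- y
    z <- as.vector(D %*% f)
    u <- numeric(nrow(D))
  } else {
    f <- init$f; z <- init$z; u <- init$u
  }
  iter <- 0L
  converged <- FALSE
  scale <- max(1, sqrt(sum(y^2)))
  for (iter in seq_len(max_iter)) {
    rhs <- mask * y + rho * as.vector(crossprod(D, z - u))
    f <- backsolve(R, forwardsolve(Rt, rhs))
    Df <- as.vector(D %*% f)
    z_old <- z
    v <- relax * Df + (1 - relax) * z_old + u  # over-relaxation
    z <- sign(v) * pmax(abs(v) - lambda / rho, 0)  # soft threshold
    u <- u + relax * Df + (1 - relax) * z_old - z
    r_primal <- sqrt(sum((Df - z)^2))
    r_dual <- rho * sqrt(sum((z - z_old)^2))
    if (r_primal < tol * scale && r_dual < tol * scale) {
      converged <- TRUE
      break
    }
    # residual balancing keeps the two residuals within a decade
    if (iter %% 10 == 0) {
      if (r_primal > 10 * r_dual) {
        rho <- rho * 2; u <- u / 2
        R <- refactor(rho); Rt <- t(R)
      } else if (r_dual > 10 * r_primal) {
        rho <- rho / 2; u <- u * 2
        R <- refactor(rho); Rt <- t(R)
      }
    }
  }
  list(f = f, z = z, u = u, lambda = lambda, iterations = iter,
       converged = converged)
}

# largest useful penalty: beyond it the solution is a global quadratic
trendfilter_lambda_max <- function(y) {
  n <- length(y)
  D <- diff(diag(n), differences = 3)
  u <- solve(tcrossprod(D), D %*% y)
  max(abs(u))
}

#' Cross-validated quadratic trend filtering
#'
#' Selects the penalty on a log-spaced grid by K-fold cross-validation with
#' interleaved folds (every K-th point held out; the two endpoints always
#' stay in the training set).  Held-out points are predicted by the fit at
#' their positions, obtained by refitting with those observations masked.
#'
#' @param y numeric response.
#' @param cv_folds number of folds.
#' @param n_lambda grid size.
#' @param lambda_min_ratio smallest grid value relative to the largest.
#' @return list with `f` (full-data fit at the selected penalty), `lambda`,
#'   `cv_error` per grid value and the grid itself.
#' @keywords internal
cv_trendfilter <- function(y, cv_folds = 5L, n_lambda = 12L,
                           lambda_min_ratio = 1e-4) {
  n <- length(y)
  lmax <- max(trendfilter_lambda_max(y), 1e-8)
  grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                  length.out = n_lambda))
  fold <- ((seq_len(n) - 2L) %% cv_folds) + 1L
  fold[c(1L, n)] <- 0L  # endpoints never held out
  err_mat <- matrix(0, n_lambda, cv_folds)
  warm <- vector("list", cv_folds)  # warm starts across the descending grid
  for (j in seq_along(grid)) {
    for (k in seq_len(cv_folds)) {
      mask <- as.numeric(fold != k)
      fit <- trendfilter_admm(y, grid[j], mask = mask, init = warm[[k]])
      warm[[k]] <- fit
      held <- fold == k
      err_mat[j, k] <- mean((y[held] - fit$f[held])^2)
    }
  }
  cv_err <- rowMeans(err_mat)
  cv_se <- apply(err_mat, 1, stats::sd) / sqrt(cv_folds)
  # one-standard-error rule: largest penalty within one SE of the CV optimum
  j_min <- which.min(cv_err)
  best <- grid[min(which(cv_err <= cv_err[j_min] + cv_se[j_min]))]
  fit <- trendfilter_admm(y, best, max_iter = 4000L)
  if (!fit$converged)
    warning(sprintf(
      "trend filter did not fully converge at lambda = %.4g after %d iterations",
      best, fit$iterations))
  list(f = fit$f, lambda = best, cv_error = cv_err, lambda_grid = grid)
}

#' Smooth one season's epidemic curve
#'
#' Fits a cross-validated piecewise-quadratic trend-filter curve to a
#' season of weekly counts and records the residual noise level, peak
#' height and peak week used by the empirical-Bayes forecaster.
#'
#' @param y a season's weekly ILI counts.
#' @param cv_folds CV folds for the penalty selection.
#' @param season_id optional label carried along.
#' @return an object of class `"smoothed_trajectory"`: `values`, `sigma`
#'   (residual SD, floored at 1e-6), `peak_height`, `peak_week`,
#'   `season_id`.
#' @export
smooth_season <- function(y, cv_folds = 5L, season_id = NA_character_) {
  if (length(y) < 10)
    stop("season too short to smooth (need >= 10 weeks)", call. = FALSE)
  fit <- cv_trendfilter(y, cv_folds = cv_folds)
  f <- fit$f
  structure(list(season_id = season_id,
                 values = f,
                 sigma = max(stats::sd(y - f), 1e-6),
                 peak_height = max(f),
                 peak_week = which.max(f),
                 lambda = fit$lambda),
            class = "smoothed_trajectory")
}
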