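# Independent MMWR week oracle, from the definition: weeks run
# Sunday-Saturday; week 1 of year y is the week containing January 4.
mmwr_year_start <- function(year) {
  jan4 <- as.Date(sprintf("%d-01-04", year))
  # Sunday on or before Jan 4 (POSIXlt wday: 0 = Sunday)
  jan4 - as.POSIXlt(jan4)$wday
}

mmwr_oracle <- function(date) {
  y <- as.integer(format(date, "%Y"))
  wk <- function(d, yy) as.integer(floor((d - mmwr_year_start(yy)) / 7)) + 1L
  out <- integer(length(date))
  for (i in seq_along(date)) {
    d <- date[i]; yy <- y[i]
    if (d < mmwr_year_start(yy)) yy <- yy - 1L
    else if (d >= mmwr_year_start(yy + 1L)) yy <- yy + 1L
    out[i] <- wk(d, yy)
  }
  out
}

# minimal weekly series (Sundays, contiguous) for unit tests
toy_series <- function(counts, start = as.Date("2012-08-26"),
                       temp_min = 0, temp_max = 10,
                       immunization_rate = 0.2, population = 1e6L) {
  n <- length(counts)
  data.frame(week_start = seq(start, by = "7 days", length.out = n),
             ili_count = counts,
             temp_min = rep_len(temp_min, n),
             temp_max = rep_len(temp_max, n),
             immunization_rate = rep_len(immunization_rate, n),
             population = rep_len(population, n))
}

# a smoothed_trajectory built directly, skipping the smoother
toy_trajectory <- function(values, sigma = 5, season_id = "toy") {
  structure(list(season_id = season_id, values = values, sigma = sigma,
                 peak_height = max(values), peak_week = which.max(values)),
            class = "smoothed_trajectory")
}

# Gaussian-bump season on a baseline
bump_curve <- function(L = 52, base = 135, height = 400, peak = 24,
                       width = 6) {
  t <- seq_len(L)
  base + (height - base) * exp(-(t - peak)^2 / (2 * width^2))
}

# brute-force weighted median: checks the two half-weight inequalities
# for every sample point, O(N^2)
weighted_median_bruteforce <- function(x, w) {
  w <- w / sum(w)
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  for (k in seq_along(x)) {
    below <- if (k > 1) sum(w[seq_len(k - 1)]) else 0
    above <- if (k < length(x)) sum(w[seq(k + 1, length(x))]) else 0
    if (below <= 0.5 && above <= 0.5) return(x[k])
  }
  stop("no weighted median found")
}

# brute-force simplex grid search at a given resolution (M = 3)
simplex_grid_search <- function(F, y, step = 0.01) {
  stopifnot(ncol(F) == 3)
  best_obj <- Inf; best_w <- NULL
  for (w1 in seq(0, 1, step)) for (w2 in seq(0, 1 - w1, step)) {
    w <- c(w1, w2, 1 - w1 - w2)
    obj <- mean((y - F %*% w)^2)
    if (obj < best_obj) { best_obj <- obj; best_w <- w }
  }
  list(w = best_w, objective = best_obj)
}

fast_eval_control <- function(...) {
  eval_control(eb_n_samples = 300, qrf_trees = 50, ...)
}
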