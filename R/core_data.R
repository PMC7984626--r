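#' Weekly ILI series
#'
#' The central data container is a plain `data.frame` with one row per
#' surveillance week and columns:
#' \describe{
#'   \item{week_start}{`Date`, first day (Sunday) of the week.}
#'   \item{ili_count}{non-negative integer count of ILI-positive ED visits.}
#'   \item{temp_min, temp_max}{weekly means of daily minimum / maximum
#'     temperature, degrees Celsius.}
#'   \item{immunization_rate}{fraction in \[0, 1\] of ILI visits with recent
#'     flu immunization.}
#'   \item{population}{annual mid-year city population estimate.}
#' }
#' `build_season_index()` adds `epi_week`, `epi_year`, `season_id` and
#' `week_of_season`.
#'
#' @name weekly-series
NULL

REQUIRED_WEEKLY_COLS <- c("week_start", "ili_count", "temp_min", "temp_max",
                          "immunization_rate", "population")

validate_weekly_series <- function(x) {
  missing <- setdiff(REQUIRED_WEEKLY_COLS, names(x))
  if (length(missing) > 0)
    stop("weekly series is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!inherits(x$week_start, "Date"))
    stop("week_start must be a Date", call. = FALSE)
  if (anyNA(x$ili_count) || any(x$ili_count < 0))
    stop("ili_count must be non-negative and non-missing; offending row(s): ",
         paste(utils::head(which(is.na(x$ili_count) | x$ili_count < 0), 5),
               collapse = ", "), call. = FALSE)
  bad_rate <- which(x$immunization_rate < 0 | x$immunization_rate > 1)
  if (length(bad_rate) > 0)
    stop("immunization_rate outside [0, 1] at row(s): ",
         paste(utils::head(bad_rate, 5), collapse = ", "), call. = FALSE)
  invisible(x)
}

#' Assign epi-weeks and flu seasons to a weekly series
#'
#' Weeks are numbered by the MMWR (US CDC) convention: weeks run
#' Sunday--Saturday and week 1 of a year is the week containing January 4.
#' A new flu season starts at the first week whose epi-week equals
#' `season_start_epiweek` (default 35, roughly the last week of August), so
#' seasons last 52 or 53 weeks depending on the MMWR calendar.  Seasons are
#' labelled `"2012-13"` style by the starting epi-year.  Weeks before the
#' first season start are attached to the (partial) preceding season and the
#' final season may be partial; both situations are flagged in the
#' `"partial_seasons"` attribute rather than rejected.
#'
#' @param weeks a weekly series `data.frame` (see [weekly-series]), or a
#'   `Date` vector of week start dates.
#' @param season_start_epiweek integer epi-week at which a new season begins.
#' @return the input with `epi_week`, `epi_year`, `season_id` and
#'   `week_of_season` columns added; attribute `"season_lengths"` holds the
#'   named vector of season lengths.
#' @export
build_season_index <- function(weeks, season_start_epiweek = 35L) {
  if (inherits(weeks, "Date")) {
    df <- data.frame(week_start = weeks)
  } else {
    df <- as.data.frame(weeks)
    if (!"week_start" %in% names(df))
      stop("weeks must have a week_start column", call. = FALSE)
  }
  d <- df$week_start
  if (length(d) < 1) stop("no weeks supplied", call. = FALSE)
  gaps <- diff(as.integer(d))
  if (any(gaps != 7)) {
    bad <- which(gaps != 7)[1]
    stop(sprintf(
      "weeks must be consecutive and 7 days apart; gap of %d days between %s and %s",
      gaps[bad], format(d[bad]), format(d[bad + 1])), call. = FALSE)
  }
  df$epi_week <- lubridate::epiweek(d)
  df$epi_year <- lubridate::epiyear(d)

  new_season <- df$epi_week == season_start_epiweek &
    c(TRUE, df$epi_week[-length(d)] != season_start_epiweek)
  season_no <- cumsum(new_season)
  # weeks before the first configured start form a leading partial season
  leading <- season_no == 0
  start_year <- integer(length(d))
  start_year[!leading] <- df$epi_year[which(new_season)][season_no[!leading]]
  if (any(leading)) start_year[leading] <- df$epi_year[1] - 1L
  df$season_id <- sprintf("%d-%02d", start_year, (start_year + 1L) %% 100L)
  df$week_of_season <- stats::ave(seq_along(d), df$season_id,
                                  FUN = seq_along)

  lens <- table(factor(df$season_id, levels = unique(df$season_id)))
  season_lengths <- stats::setNames(as.integer(lens), names(lens))
  partial <- names(season_lengths)[season_lengths < 52]
  attr(df, "season_lengths") <- season_lengths
  attr(df, "partial_seasons") <- partial
  df
}

#' Label high-volume weeks within each season
#'
#' Within each season, the `ceiling(0.25 * n)` weeks with the largest ILI
#' counts are labelled high-volume; ties at the 25% boundary are broken in
#' favour of the earlier week.
#'
#' @param series an indexed weekly series (from [build_season_index()]).
#' @return logical vector, `TRUE` for high-volume weeks, aligned with rows
#'   of `series`.
#' @export
label_high_volume <- function(series) {
  if (!"season_id" %in% names(series))
    stop("series must be season-indexed; run build_season_index() first",
         call. = FALSE)
  high <- logical(nrow(series))
  for (s in unique(series$season_id)) {
    idx <- which(series$season_id == s)
    n <- length(idx)
    if (n < 4)
      stop(sprintf("season %s has only %d week(s); need at least 4", s, n),
           call. = FALSE)
    k <- ceiling(0.25 * n)
    # descending count, earlier week wins ties (order() is stable)
    ord <- idx[order(-series$ili_count[idx], seq_len(n))]
    high[ord[seq_len(k)]] <- TRUE
  }
  high
}

#' Read a weekly ILI series from CSV
#'
#' Expects columns `week_start` (ISO-8601 date), `ili_count`, `temp_min`,
#' `temp_max`, `immunization_rate`, `population`; an optional `season_id`
#' column overrides season assignment downstream.
#'
#' @param path CSV file path.
#' @return a validated weekly series `data.frame`.
#' @export
read_weekly_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(REQUIRED_WEEKLY_COLS, names(x))
  if (length(missing) > 0)
    stop("CSV ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  ws <- as.Date(x$week_start)
  if (anyNA(ws))
    stop("unparseable week_start date at row(s): ",
         paste(utils::head(which(is.na(ws)), 5), collapse = ", "),
         call. = FALSE)
  x$week_start <- ws
  if (!is.numeric(x$ili_count))
    stop("ili_count must be numeric", call. = FALSE)
  validate_weekly_series(x)
  x
}

#' Write a weekly ILI series to CSV
#'
#' Round-trips through [read_weekly_csv()]: dates are written ISO-8601 and
#' floats with full precision.
#'
#' @param series weekly series `data.frame`.
#' @param path output CSV path.
#' @export
write_weekly_csv <- function(series, path) {
  out <- series[, intersect(c(REQUIRED_WEEKLY_COLS, "season_id"),
                            names(series)), drop = FALSE]
  out$week_start <- format(out$week_start, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write forecasts to CSV
#'
#' One row per (model, horizon): `made_at_week`, `horizon`, `model`,
#' `point`, `q01`..`q99`, and the central 90% interval `pi_lower_90` /
#' `pi_upper_90` (the 5th and 95th forecast centiles).
#'
#' @param forecasts a list of forecast distributions
#'   (see [forecast_dist()]).
#' @param path output CSV path.
#' @export
write_forecast_csv <- function(forecasts, path) {
  rows <- lapply(forecasts, function(f) {
    q <- as.list(f$centiles)
    names(q) <- sprintf("q%02d", 1:99)
    c(list(made_at_week = format(f$made_at_week),
           horizon = f$horizon,
           model = f$model,
           point = f$point),
      q,
      list(pi_lower_90 = f$centiles[5], pi_upper_90 = f$centiles[95]))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
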