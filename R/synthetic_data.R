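#' Simulation configuration for synthetic multi-season ILI data
#'
#' The generator emulates the marginal structure of weekly ILI-positive ED
#' visit counts at a high-volume pediatric ED: a constant off-peak baseline
#' with one Gaussian-bump epidemic wave per season (season-specific peak
#' height, week and width), negative-binomial observation noise, an annual
#' temperature sinusoid with its trough in mid-winter (so epidemic weeks are
#' cold weeks), an immunization-rate ramp to a plateau, and linear
#' population growth.  Defaults are calibrated so that a 7-season run has an
#' overall mean weekly count near 208 with high-volume (top-25%) weeks
#' averaging near 333.
#'
#' @param n_seasons number of complete flu seasons.
#' @param start_year calendar year in which the first season starts.
#' @param season_start_epiweek epi-week at which seasons begin.
#' @param baseline_rate mean off-peak visits/week.
#' @param peak_height_range interval from which each season's peak mean
#'   count is drawn uniformly.
#' @param peak_week_range interval (weeks of season) for the peak location.
#' @param peak_width_range interval (weeks) for the Gaussian bump SD.
#' @param dispersion negative-binomial size parameter; `Inf` gives
#'   noise-free rounded counts.
#' @param final_season_weeks if non-`NULL`, truncate the last season to this
#'   many weeks (a partial final season).
#' @param temp_min_mean,temp_amplitude,temp_offset,temp_noise_sd annual
#'   minimum-temperature cycle: mean, seasonal amplitude, constant
#'   max-minus-min offset, and weekly noise SD, all degrees Celsius.
#' @param immunization_plateau mid-season immunization-rate plateau.
#' @param immunization_noise_sd weekly noise SD on the immunization rate.
#' @param population_start,population_growth mid-year population for the
#'   first season and per-season increment.
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_seasons = 7L,
                       start_year = 2012L,
                       season_start_epiweek = 35L,
                       baseline_rate = 135,
                       peak_height_range = c(300, 420),
                       peak_week_range = c(18, 30),
                       peak_width_range = c(5, 8),
                       dispersion = 35,
                       final_season_weeks = NULL,
                       temp_min_mean = -5.5,
                       temp_amplitude = 13,
                       temp_offset = 23,
                       temp_noise_sd = 3,
                       immunization_plateau = 0.23,
                       immunization_noise_sd = 0.02,
                       population_start = 1200000,
                       population_growth = 15000,
                       seed = 1L) {
  cfg <- list(n_seasons = as.integer(n_seasons), start_year = as.integer(start_year),
              season_start_epiweek = as.integer(season_start_epiweek),
              baseline_rate = baseline_rate,
              peak_height_range = peak_height_range,
              peak_week_range = peak_week_range,
              peak_width_range = peak_width_range,
              dispersion = dispersion,
              final_season_weeks = final_season_weeks,
              temp_min_mean = temp_min_mean, temp_amplitude = temp_amplitude,
              temp_offset = temp_offset, temp_noise_sd = temp_noise_sd,
              immunization_plateau = immunization_plateau,
              immunization_noise_sd = immunization_noise_sd,
              population_start = population_start,
              population_growth = population_growth,
              seed = as.integer(seed))
  stopifnot(cfg$n_seasons >= 1, cfg$baseline_rate > 0, cfg$dispersion > 0,
            diff(cfg$peak_height_range) >= 0, diff(cfg$peak_week_range) >= 0,
            diff(cfg$peak_width_range) >= 0)
  class(cfg) <- "sim_config"
  cfg
}

# first Sunday-start week whose MMWR epi-week equals `epiweek` in `year`
first_week_of_epiweek <- function(year, epiweek) {
  d <- seq(as.Date(sprintf("%d-01-01", year)),
           as.Date(sprintf("%d-12-31", year)), by = "1 day")
  d <- d[lubridate::wday(d) == 1]  # Sundays
  d[lubridate::epiweek(d) == epiweek & lubridate::epiyear(d) == year][1]
}

#' Simulate a multi-season weekly ILI dataset
#'
#' Seasons follow the real MMWR calendar (52 or 53 weeks each, starting at
#' the configured epi-week).  Same seed, same config: bit-identical output.
#'
#' @param config a [sim_config()].
#' @return a season-indexed weekly series (see [weekly-series]) with the
#'   latent epidemic mean in column `latent_mean`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  start <- first_week_of_epiweek(config$start_year, config$season_start_epiweek)
  # over-generate, then keep the first n_seasons complete seasons
  dates <- seq(start, by = "7 days",
               length.out = config$n_seasons * 53L + 5L)
  idx <- build_season_index(data.frame(week_start = dates),
                            config$season_start_epiweek)
  keep_ids <- unique(idx$season_id)[seq_len(config$n_seasons)]
  idx <- idx[idx$season_id %in% keep_ids, , drop = FALSE]
  if (!is.null(config$final_season_weeks)) {
    last <- keep_ids[config$n_seasons]
    idx <- idx[idx$season_id != last |
                 idx$week_of_season <= config$final_season_weeks, ,
               drop = FALSE]
  }
  n <- nrow(idx)
  season_no <- match(idx$season_id, keep_ids)

  # per-season epidemic wave parameters
  hs <- stats::runif(config$n_seasons, config$peak_height_range[1],
                     config$peak_height_range[2])
  ps <- stats::runif(config$n_seasons, config$peak_week_range[1],
                     config$peak_week_range[2])
  wsd <- stats::runif(config$n_seasons, config$peak_width_range[1],
                      config$peak_width_range[2])
  mu <- config$baseline_rate +
    (hs[season_no] - config$baseline_rate) *
    exp(-((idx$week_of_season - ps[season_no])^2) / (2 * wsd[season_no]^2))

  if (is.infinite(config$dispersion)) {
    counts <- round(mu)
  } else {
    counts <- stats::rnbinom(n, size = config$dispersion, mu = mu)
  }

  doy <- as.integer(format(idx$week_start, "%j"))
  cycle <- -cos(2 * pi * (doy - 15) / 365.25)  # trough mid-January
  tmin <- config$temp_min_mean + config$temp_amplitude * cycle +
    stats::rnorm(n, 0, config$temp_noise_sd)
  # daily maxima swing less than minima over the year (continental winters)
  tmax <- config$temp_min_mean + config$temp_offset +
    0.8 * config$temp_amplitude * cycle +
    stats::rnorm(n, 0, config$temp_noise_sd)

  imm <- config$immunization_plateau * pmin(1, idx$week_of_season / 20) +
    stats::rnorm(n, 0, config$immunization_noise_sd)
  imm <- pmin(pmax(imm, 0), 1)

  # annual estimates drift around the nominal growth line
  growth <- stats::rnorm(config$n_seasons, config$population_growth,
                         0.2 * abs(config$population_growth))
  pop_by_season <- round(config$population_start +
                           c(0, cumsum(growth))[seq_len(config$n_seasons)])

  out <- data.frame(
    week_start = idx$week_start,
    ili_count = as.integer(counts),
    temp_min = tmin,
    temp_max = tmax,
    immunization_rate = imm,
    population = pop_by_season[season_no],
    epi_week = idx$epi_week,
    epi_year = idx$epi_year,
    season_id = idx$season_id,
    week_of_season = idx$week_of_season,
    latent_mean = mu
  )
  attr(out, "season_lengths") <-
    table(factor(out$season_id, levels = keep_ids))
  attr(out, "sim_config") <- config
  rownames(out) <- NULL
  out
}

#' Descriptive statistics by visit-volume stratum
#'
#' For each numeric variable: overall, high-volume and low-volume mean and
#' SD, plus the Welch (unequal-variance) two-sample t statistic for the
#' high-minus-low mean difference.
#'
#' @param series a weekly series.
#' @param high logical high-volume labels (from [label_high_volume()]).
#' @param vars variables to summarize.
#' @return a `data.frame`, one row per variable.
#' @export
summarize_weekly <- function(series, high,
                             vars = c("ili_count", "temp_min", "temp_max",
                                      "immunization_rate")) {
  stopifnot(length(high) == nrow(series))
  if (sum(high) < 2 || sum(!high) < 2)
    stop("each volume stratum needs at least 2 weeks", call. = FALSE)
  rows <- lapply(vars, function(v) {
    x <- series[[v]]
    tt <- stats::t.test(x[high], x[!high], var.equal = FALSE)
    data.frame(variable = v,
               mean_all = mean(x), sd_all = stats::sd(x),
               mean_high = mean(x[high]), sd_high = stats::sd(x[high]),
               mean_low = mean(x[!high]), sd_low = stats::sd(x[!high]),
               t_high_low = unname(tt$statistic))
  })
  out <- do.call(rbind, rows)
  attr(out, "t_variant") <- "Welch two-sample t, unequal variances"
  out
}
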