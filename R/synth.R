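#' Configuration of a synthetic monitoring campaign
#'
#' Defines the environment (temperature, geomagnetic Kp), the growth model,
#' and the sampling design of a simulated multi-season moss growth-monitoring
#' campaign. The growth model couples daily shoot elongation to the previous
#' day's temperature anomaly with a slope that is boosted by a factor
#' `1 + kappa` whenever the previous day's daily Kp falls inside `kp_window`
#' — the ground truth that the gradient analysis is expected to recover.
#'
#' @param seed Integer seed; all campaign randomness derives from it.
#' @param n_seasons Number of growing seasons (consecutive years).
#' @param season_doy Day-of-year bounds of the season (thaw to freeze).
#' @param sampling_interval_days Days between consecutive sampling events.
#' @param n_plots Number of sample plots.
#' @param shoots_per_sample Shoots measured per plot and sampling event.
#' @param temp_mean Annual mean air temperature, degC.
#' @param temp_annual_amplitude Amplitude of the annual harmonic, degC.
#' @param temp_period_days Period of the annual harmonic, days.
#' @param temp_ar_rho Lag-1 autocorrelation of the daily weather noise (also
#'   used for the day-to-day persistence of hour-specific anomalies).
#' @param temp_noise_sd Marginal SD of the daily weather noise, degC.
#' @param diurnal_amplitude Amplitude of the within-day temperature cycle, degC.
#' @param hour_noise_sd Marginal SD of hour-specific temperature anomalies
#'   around the daily mean + diurnal cycle, degC. AR(1) across days within
#'   each hour, independent across hours.
#' @param kp_ar_rho Lag-1 autocorrelation of the latent Gaussian process
#'   behind the 3-hourly Kp series.
#' @param kp_skew Gamma shape of the right-skewed Kp marginal (smaller =
#'   more skewed; the degenerate limit collapses to a constant).
#' @param kp_level Marginal mean of the Kp series before clipping/snapping.
#' @param beta0 Baseline growth–temperature slope, mm/day per degC.
#' @param kp_window Kp interval `c(lo, hi)` inside which the slope is boosted.
#' @param kappa Fractional slope boost inside `kp_window` (>= -1); `kappa = 0`
#'   gives a Kp-independent coupling.
#' @param hour_weights Eight non-negative weights giving the relative
#'   contribution of each synoptic hour's temperature anomaly to growth.
#' @param season_peak_rate Peak of the seasonal growth hump, mm/day.
#' @param shoot_noise_sd Per-shoot daily measurement/biology noise, mm/day.
#' @param process_noise_sd Daily mire-level process noise on the true rate,
#'   mm/day (shared across plots).
#' @param start_year First calendar year of the campaign.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_seasons = 8L,
                         season_doy = c(110L, 290L),
                         sampling_interval_days = 2L,
                         n_plots = 6L,
                         shoots_per_sample = 40L,
                         temp_mean = 4,
                         temp_annual_amplitude = 12,
                         temp_period_days = 365.3,
                         temp_ar_rho = 0.7,
                         temp_noise_sd = 3,
                         diurnal_amplitude = 4,
                         hour_noise_sd = 2.5,
                         kp_ar_rho = 0.8,
                         kp_skew = 1.0,
                         kp_level = 1.5,
                         beta0 = 0.15,
                         kp_window = c(0.9, 1.6),
                         kappa = 1.0,
                         hour_weights = rep(1, 8),
                         season_peak_rate = 4,
                         shoot_noise_sd = 1.5,
                         process_noise_sd = 0.3,
                         start_year = 2015L) {
  cfg <- list(
    seed = as.integer(seed), n_seasons = as.integer(n_seasons),
    season_doy = as.integer(season_doy),
    sampling_interval_days = as.integer(sampling_interval_days),
    n_plots = as.integer(n_plots),
    shoots_per_sample = as.integer(shoots_per_sample),
    temp_mean = temp_mean, temp_annual_amplitude = temp_annual_amplitude,
    temp_period_days = temp_period_days, temp_ar_rho = temp_ar_rho,
    temp_noise_sd = temp_noise_sd, diurnal_amplitude = diurnal_amplitude,
    hour_noise_sd = hour_noise_sd, kp_ar_rho = kp_ar_rho,
    kp_skew = kp_skew, kp_level = kp_level, beta0 = beta0,
    kp_window = as.numeric(kp_window), kappa = kappa,
    hour_weights = as.numeric(hour_weights),
    season_peak_rate = season_peak_rate, shoot_noise_sd = shoot_noise_sd,
    process_noise_sd = process_noise_sd, start_year = as.integer(start_year)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  with(cfg, {
    if (n_seasons < 1) stop("n_seasons must be >= 1")
    if (length(season_doy) != 2 || season_doy[1] >= season_doy[2]) {
      stop("season_doy must be increasing bounds c(lo, hi)")
    }
    if (any(season_doy < 1) || any(season_doy > 366)) {
      stop("season_doy must lie in [1, 366]")
    }
    if (sampling_interval_days < 1) stop("sampling_interval_days must be >= 1")
    if (n_plots < 1 || shoots_per_sample < 1) {
      stop("n_plots and shoots_per_sample must be >= 1")
    }
    if (temp_annual_amplitude < 0) stop("temp_annual_amplitude must be >= 0")
    if (temp_period_days <= 0) stop("temp_period_days must be > 0")
    if (temp_ar_rho < 0 || temp_ar_rho >= 1) stop("temp_ar_rho must lie in [0, 1)")
    if (kp_ar_rho < 0 || kp_ar_rho >= 1) stop("kp_ar_rho must lie in [0, 1)")
    for (nm in c("temp_noise_sd", "diurnal_amplitude", "hour_noise_sd",
                 "shoot_noise_sd", "process_noise_sd")) {
      if (cfg[[nm]] < 0) stop(sprintf("%s must be >= 0", nm))
    }
    if (kp_skew <= 0) stop("kp_skew must be > 0")
    if (kp_level < 0) stop("kp_level must be >= 0")
    if (length(kp_window) != 2 || kp_window[1] >= kp_window[2]) {
      stop("kp_window must be increasing bounds c(k_lo, k_hi)")
    }
    if (kappa < -1) stop("kappa must be >= -1")
    if (length(hour_weights) != 8 || any(hour_weights < 0) ||
        sum(hour_weights) <= 0) {
      stop("hour_weights must be 8 non-negative weights with positive sum")
    }
    if (season_peak_rate < 0) stop("season_peak_rate must be >= 0")
  })
  invisible(cfg)
}

#' Synoptic hours of the diurnal grid
#' @export
synoptic_hours <- function() c(0L, 3L, 6L, 9L, 12L, 15L, 18L, 21L)

season_bounds <- function(config, year) {
  origin <- as.Date(sprintf("%d-01-01", year))
  c(origin + config$season_doy[1] - 1, origin + config$season_doy[2] - 1)
}

#' Calendar span of a synthetic campaign
#'
#' All days from one day before the first season's start (so day-prior
#' alignment never truncates the first season day) to the last season's end.
#'
#' @param config A `synth_config`.
#' @return Vector of `Date`s.
#' @export
campaign_dates <- function(config) {
  first <- season_bounds(config, config$start_year)[1]
  last <- season_bounds(config, config$start_year + config$n_seasons - 1)[2]
  seq(first - 1, last, by = "day")
}

# Snap to the published Kp granularity: thirds, ties rounded up.
snap_to_thirds <- function(x) pmin(floor(x * 3 + 0.5) / 3, 9)

#' Simulate a three-hourly Kp series
#'
#' A stationary Gaussian AR(1) latent process on the 3-h grid is mapped
#' through its probability transform to a right-skewed gamma marginal
#' (shape `kp_skew`, mean `kp_level`), clipped to `[0, 9]`, and snapped to
#' the nearest third (ties up), matching the granularity of the published
#' planetary Kp scale.
#'
#' @param config A `synth_config`.
#' @param dates Days to cover (default: the full campaign span).
#' @return Data frame with `datetime_utc` (8 slots per day, labelled by
#'   interval start hour UTC) and `kp`.
#' @export
simulate_kp <- function(config, dates = campaign_dates(config)) {
  dates <- as.Date(dates)
  if (length(dates) < 1) stop("Kp simulation needs a positive date span")
  set.seed(config$seed + 1L)
  n <- length(dates) * 8L
  z <- ar1_series(n, config$kp_ar_rho)
  u <- stats::pnorm(z)
  raw <- stats::qgamma(u, shape = config$kp_skew,
                       scale = config$kp_level / config$kp_skew)
  kp <- snap_to_thirds(pmin(pmax(raw, 0), 9))
  slot <- rep(synoptic_hours(), times = length(dates))
  day <- rep(dates, each = 8L)
  data.frame(
    datetime_utc = as.POSIXct(day, tz = "UTC") + slot * 3600,
    kp = kp
  )
}

#' Simulate daily and diurnal temperature
#'
#' Daily mean = `temp_mean` + annual sinusoid (period `temp_period_days`,
#' peak in late July of the first year) + stationary AR(1) weather noise.
#' The diurnal value at synoptic hour h adds a deterministic within-day
#' sinusoid `diurnal_amplitude * sin(2*pi*(h - 9)/24)` plus an hour-specific
#' anomaly that is AR(1) across days within each hour.
#'
#' @param config A `synth_config`.
#' @param dates Days to cover (default: the full campaign span).
#' @return List with `daily` (columns `date`, `temp`, `seasonal`) and
#'   `diurnal` (columns `date`, `hour`, `temp`, `seasonal`). `seasonal` is
#'   the deterministic component, kept as generator ground truth.
#' @export
simulate_temperature <- function(config, dates = campaign_dates(config)) {
  dates <- as.Date(dates)
  if (length(dates) < 1) stop("temperature simulation needs a positive date span")
  if (config$temp_annual_amplitude < 0) stop("temp_annual_amplitude must be >= 0")
  set.seed(config$seed + 2L)
  n <- length(dates)
  t_num <- as.numeric(dates)
  t_peak <- as.numeric(as.Date(sprintf("%d-07-20", config$start_year)))
  seasonal <- config$temp_mean + config$temp_annual_amplitude *
    sin(2 * pi * (t_num - t_peak) / config$temp_period_days + pi / 2)
  ar <- ar1_series(n, config$temp_ar_rho, config$temp_noise_sd)
  daily <- data.frame(date = dates, temp = seasonal + ar, seasonal = seasonal)

  hours <- synoptic_hours()
  cyc <- config$diurnal_amplitude * sin(2 * pi * (hours - 9) / 24)
  eta <- vapply(
    seq_along(hours),
    function(i) ar1_series(n, config$temp_ar_rho, config$hour_noise_sd),
    numeric(n)
  )
  diurnal <- data.frame(
    date = rep(dates, times = 8L),
    hour = rep(hours, each = n),
    temp = rep(daily$temp, times = 8L) + rep(cyc, each = n) + as.numeric(eta),
    seasonal = rep(seasonal, times = 8L) + rep(cyc, each = n)
  )
  diurnal <- diurnal[order(diurnal$date, diurnal$hour), , drop = FALSE]
  row.names(diurnal) <- NULL
  list(daily = daily, diurnal = diurnal)
}

# Quadratic seasonal hump, zero at the season edges, peaking mid-season.
season_hump <- function(config, doy) {
  lo <- config$season_doy[1]
  hi <- config$season_doy[2]
  half <- (hi - lo) / 2
  mid <- (lo + hi) / 2
  pmax(0, config$season_peak_rate * (1 - ((doy - mid) / half)^2))
}

#' Simulate growth from the environmental drivers
#'
#' The true mire-level rate on day d is
#' `max(0, hump(d) + beta(Kp_{d-1}) * anom_{d-1} + process noise)` where
#' `anom` is the hour-weighted mean temperature anomaly (observed minus
#' deterministic seasonal component) over the eight synoptic hours and
#' `beta(Kp) = beta0 * (1 + kappa)` when the daily Kp lies inside
#' `kp_window`, `beta0` otherwise. Plot-level interval records are means of
#' `shoots_per_sample` noisy per-shoot increments over each sampling
#' interval; intervals tile each season, the last truncated at season end.
#'
#' @param kp_daily Daily Kp values: a `daily_pattern` or data frame with
#'   columns `date` and `value`/`kp`, covering every season day and the day
#'   before each.
#' @param temp Output of [simulate_temperature()] covering the same days.
#' @param config A `synth_config`.
#' @return List with `intervals` (plot-level growth-interval table) and
#'   `truth` (per-day `hump`, `beta`, `anomaly`, `kp_prev`, `true_rate`,
#'   with the injected `kp_window`, `hour_weights`, `beta0`, `kappa` as
#'   attributes).
#' @export
simulate_growth <- function(kp_daily, temp, config) {
  set.seed(config$seed + 3L)
  kp_val <- if (!is.null(kp_daily$value)) kp_daily$value else kp_daily$kp
  kp_dates <- as.Date(kp_daily$date)

  years <- config$start_year + seq_len(config$n_seasons) - 1L
  season_days <- lapply(years, function(y) {
    b <- season_bounds(config, y)
    seq(b[1], b[2], by = "day")
  })
  all_days <- as.Date(unlist(season_days), origin = "1970-01-01")
  need <- sort(unique(c(all_days, all_days - 1)))
  miss <- need[!(need %in% temp$daily$date)]
  if (length(miss)) stop(sprintf("missing temperature driver day: %s", miss[1]))
  miss <- need[!(need %in% kp_dates)]
  if (length(miss)) stop(sprintf("missing Kp driver day: %s", miss[1]))

  # hour-weighted anomaly per day
  w <- config$hour_weights / sum(config$hour_weights)
  di <- temp$diurnal
  # diurnal is sorted by (date, hour): reshape into days x hours
  anom_mat <- matrix(di$temp - di$seasonal, ncol = 8, byrow = TRUE)
  anom_by_day <- as.numeric(anom_mat %*% w)
  anom_dates <- unique(di$date)

  prev <- all_days - 1
  anom_prev <- anom_by_day[match(prev, anom_dates)]
  kp_prev <- kp_val[match(prev, kp_dates)]
  inside <- kp_prev >= config$kp_window[1] & kp_prev <= config$kp_window[2]
  beta <- config$beta0 * (1 + config$kappa * inside)
  doy <- as.integer(format(all_days, "%j"))
  hump <- season_hump(config, doy)
  noise <- stats::rnorm(length(all_days), 0, config$process_noise_sd)
  true_rate <- pmax(0, hump + beta * anom_prev + noise)

  truth <- data.frame(
    date = all_days,
    season = as.integer(format(all_days, "%Y")),
    hump = hump, beta = beta, kp_prev = kp_prev,
    anomaly = anom_prev, true_rate = true_rate
  )
  attr(truth, "kp_window") <- config$kp_window
  attr(truth, "hour_weights") <- config$hour_weights
  attr(truth, "beta0") <- config$beta0
  attr(truth, "kappa") <- config$kappa

  # interval tiling per season
  iv <- do.call(rbind, lapply(seq_along(years), function(i) {
    b <- season_bounds(config, years[i])
    starts <- seq(b[1], b[2] - 1, by = config$sampling_interval_days)
    ends <- pmin(starts + config$sampling_interval_days, b[2])
    data.frame(start_date = starts, end_date = ends)
  }))
  # sums of true rates over (start, end] via cumulative sums on integer days
  day_int <- as.integer(truth$date)
  cum <- cumsum(truth$true_rate)
  idx_of <- function(d) match(as.integer(d), day_int)
  len <- as.integer(iv$end_date - iv$start_date)
  i_end <- idx_of(iv$end_date)
  i_start <- idx_of(iv$start_date)  # NA for the first interval of a season
  true_sum <- cum[i_end] - ifelse(is.na(i_start), 0, cum[i_start])

  n_iv <- nrow(iv)
  n_rec <- n_iv * config$n_plots
  plot_ids <- sprintf("P%02d", seq_len(config$n_plots))
  # per-shoot increment = true growth over interval + N(0, sd * sqrt(len))
  shoot_noise <- matrix(
    stats::rnorm(n_rec * config$shoots_per_sample, 0, config$shoot_noise_sd),
    nrow = n_rec
  )
  len_rep <- rep(len, times = config$n_plots)
  sum_rep <- rep(true_sum, times = config$n_plots)
  increments <- sum_rep + rowMeans(shoot_noise) * sqrt(len_rep)
  rates <- pmax(0, increments / len_rep)

  intervals <- data.frame(
    plot_id = rep(plot_ids, each = n_iv),
    start_date = rep(iv$start_date, times = config$n_plots),
    end_date = rep(iv$end_date, times = config$n_plots),
    n_shoots = config$shoots_per_sample,
    rate = rates,
    stringsAsFactors = FALSE
  )
  list(intervals = intervals, truth = truth)
}

#' Simulate a full monitoring campaign
#'
#' Runs [simulate_kp()], [simulate_temperature()] and [simulate_growth()] in
#' sequence with seeds derived from `config$seed`; identical configurations
#' produce bit-identical campaigns.
#'
#' @param config A `synth_config`.
#' @return A `kp_campaign` list: `config`, `kp` (3-hourly), `kp_daily`
#'   (daily-mean `daily_pattern`), `temp`, `growth_intervals`, `truth`.
#' @export
simulate_campaign <- function(config) {
  kp <- simulate_kp(config)
  temp <- simulate_temperature(config)
  kp_daily <- daily_kp(kp, "mean")
  g <- simulate_growth(kp_daily, temp, config)
  structure(
    list(config = config, kp = kp, kp_daily = kp_daily, temp = temp,
         growth_intervals = g$intervals, truth = g$truth),
    class = "kp_campaign"
  )
}

#' Write a campaign to the standard input CSVs
#'
#' Emits `growth_intervals.csv`, `temperature.csv` (diurnal rows plus daily
#' rows with `hour = NA`), `kp.csv`, and the ground truth
#' (`ground_truth.csv` + `ground_truth.json` with the injected parameters).
#'
#' @param campaign A `kp_campaign`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths.
#' @export
write_campaign <- function(campaign, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    growth = file.path(dir, "growth_intervals.csv"),
    temperature = file.path(dir, "temperature.csv"),
    kp = file.path(dir, "kp.csv"),
    truth = file.path(dir, "ground_truth.csv"),
    truth_meta = file.path(dir, "ground_truth.json")
  )
  write_growth_intervals(campaign$growth_intervals, paths[["growth"]])
  tt <- rbind(
    data.frame(date = campaign$temp$diurnal$date,
               hour = campaign$temp$diurnal$hour,
               temp_c = campaign$temp$diurnal$temp),
    data.frame(date = campaign$temp$daily$date, hour = NA_integer_,
               temp_c = campaign$temp$daily$temp)
  )
  write_temperature_table(tt, paths[["temperature"]])
  write_kp_table(campaign$kp, paths[["kp"]])
  truth <- campaign$truth
  utils::write.csv(
    data.frame(date = format(truth$date), season = truth$season,
               hump = truth$hump, beta = truth$beta, kp_prev = truth$kp_prev,
               anomaly = truth$anomaly, true_rate = truth$true_rate),
    paths[["truth"]], row.names = FALSE, quote = FALSE
  )
  jsonlite::write_json(
    list(kp_window = attr(truth, "kp_window"),
         hour_weights = attr(truth, "hour_weights"),
         beta0 = attr(truth, "beta0"), kappa = attr(truth, "kappa"),
         seed = campaign$config$seed),
    paths[["truth_meta"]], auto_unbox = TRUE, digits = NA
  )
  paths
}
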