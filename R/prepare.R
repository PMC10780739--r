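#' Extrapolate interval rates to a daily growth pattern
#'
#' Each sampling interval's mean elongation rate is carried to every calendar
#' day in `(start_date, end_date]` — growth accrues up to and including the
#' sampling day. Days covered by no interval are absent from the pattern.
#'
#' @param intervals Interval table for a single plot (columns `plot_id`,
#'   `start_date`, `end_date`, `n_shoots`, `rate`).
#' @return A `daily_pattern` in mm/day.
#' @export
intervals_to_daily <- function(intervals) {
  if (nrow(intervals) == 0) {
    return(daily_pattern(as.Date(character()), numeric(), "mm/day"))
  }
  if (!is.null(intervals$plot_id) && length(unique(intervals$plot_id)) > 1) {
    stop("intervals_to_daily expects intervals for a single plot")
  }
  validate_growth_intervals(intervals)
  len <- as.integer(intervals$end_date - intervals$start_date)
  days <- rep(intervals$start_date, times = len) + sequence(len)
  vals <- rep(intervals$rate, times = len)
  dup <- unique(days[duplicated(days)])
  if (length(dup)) {
    stop(sprintf(
      "overlapping intervals within a plot/season: day(s) %s covered more than once",
      paste(utils::head(format(dup), 5), collapse = ", ")
    ))
  }
  daily_pattern(days, vals, "mm/day")
}

#' Average per-plot patterns into a mire-area pattern
#'
#' Per date, the unweighted mean over the plots that carry a value on that
#' date (no imputation); a date absent from every plot stays absent.
#'
#' @param patterns List of `daily_pattern`s with identical units.
#' @return A `daily_pattern`.
#' @export
average_plots <- function(patterns) {
  if (length(patterns) < 1) stop("average_plots needs at least one pattern")
  units <- unique(vapply(patterns, pattern_units, character(1)))
  if (length(units) != 1) {
    stop(sprintf("unit mismatch across plots: %s", paste(units, collapse = " vs ")))
  }
  if (length(patterns) == 1) return(patterns[[1]])
  all <- do.call(rbind, lapply(patterns, function(p) p[, c("date", "value")]))
  agg <- stats::aggregate(value ~ date, data = all, FUN = mean)
  daily_pattern(agg$date, agg$value, units)
}

#' Centered moving average within seasons
#'
#' Smooths a daily pattern with a centered moving average of odd width,
#' applied within each season independently (never across the winter gap).
#' At season edges the window shrinks to the available days, so output dates
#' equal input dates.
#'
#' @param pattern A `daily_pattern`.
#' @param width Odd window width in days (default 3).
#' @return A `daily_pattern` with the same dates and units.
#' @export
moving_average <- function(pattern, width = 3) {
  if (width < 1 || width %% 2 == 0) {
    stop("moving-average width must be odd and >= 1")
  }
  if (nrow(pattern) == 0 || width == 1) return(pattern)
  out <- pattern$value
  for (s in unique(pattern$season)) {
    idx <- which(pattern$season == s)
    out[idx] <- zoo::rollapply(pattern$value[idx], width, mean,
                               partial = TRUE, align = "center")
  }
  new_pattern_like(pattern, out)
}

#' Aggregate a three-hourly Kp series to daily values
#'
#' Only UTC days with all 8 synoptic slots present are kept; incomplete days
#' are dropped with a warning.
#'
#' @param kp Data frame with `datetime_utc` (POSIXct, UTC) and `kp`.
#' @param aggregator `"mean"` (default) or `"max"` of the 8 slots. How the
#'   3-hourly index should be reduced to a daily value is not standardized;
#'   the mean is the package default and the choice is exposed here.
#' @return A `daily_pattern` in Kp units.
#' @export
daily_kp <- function(kp, aggregator = c("mean", "max")) {
  aggregator <- match.arg(aggregator)
  day <- as.Date(kp$datetime_utc, tz = "UTC")
  counts <- table(day)
  complete <- names(counts)[counts == 8]
  incomplete <- names(counts)[counts != 8]
  if (length(incomplete)) {
    warning(sprintf(
      "dropping %d incomplete Kp day(s): %s",
      length(incomplete), paste(utils::head(incomplete, 5), collapse = ", ")
    ))
  }
  keep <- day %in% as.Date(complete)
  if (!any(keep)) stop("no complete Kp days after filtering")
  f <- if (aggregator == "mean") mean else max
  agg <- tapply(kp$kp[keep], as.character(day[keep]), f)
  daily_pattern(as.Date(names(agg)), as.numeric(agg), "Kp")
}

#' Lag-align growth with day-prior drivers
#'
#' Builds one paired record per growth day d for which both drivers exist at
#' day d - lag; records failing this are dropped (count reported via
#' `message`).
#'
#' @param growth,temp,kp `daily_pattern`s of growth rate, temperature, Kp.
#' @param lag Non-negative lag in days (default 1: day-prior drivers).
#' @return Data frame of paired records: `date`, `growth` (day d), `temp`
#'   and `kp` (day d - lag), `season`.
#' @export
lag_align <- function(growth, temp, kp, lag = 1L) {
  if (lag < 0) stop("lag must be >= 0")
  target <- growth$date - lag
  ti <- match(target, temp$date)
  ki <- match(target, kp$date)
  ok <- !is.na(ti) & !is.na(ki) &
    is.finite(growth$value) & is.finite(temp$value[ti]) & is.finite(kp$value[ki])
  ok[is.na(ok)] <- FALSE
  dropped <- sum(!ok)
  if (dropped > 0) {
    message(sprintf("lag_align: dropped %d of %d growth days lacking drivers at lag %d",
                    dropped, nrow(growth), lag))
  }
  data.frame(
    date = growth$date[ok],
    growth = growth$value[ok],
    temp = temp$value[ti][ok],
    kp = kp$value[ki][ok],
    season = growth$season[ok]
  )
}

#' Monitoring bookkeeping summary
#'
#' Summarizes a multi-year campaign the way long-term growth-monitoring
#' campaigns are reported: one row per year plus a pooled row in which the
#' counts are sums over years and the mean sample size / mean sampling
#' interval are unweighted means of the yearly means, rounded half-up to one
#' decimal.
#'
#' @param yearly Either a data frame of yearly rows (columns `year`,
#'   `sampling_events`, `shoots_measured`, `plot_growth_rates`,
#'   `mire_growth_rates`, `mean_sample_size`, `mean_interval_days`, and
#'   optionally `plots`) or a named list of growth-interval tables, one per
#'   year, from which the yearly rows are computed.
#' @return A `monitoring_summary` data frame: the yearly rows plus a final
#'   `"pooled"` row.
#' @export
monitoring_summary <- function(yearly) {
  if (is.data.frame(yearly)) {
    rows <- yearly
  } else {
    if (length(yearly) < 1) stop("monitoring_summary needs at least one year")
    rows <- do.call(rbind, lapply(names(yearly), function(y) {
      yearly_monitoring_row(yearly[[y]], y)
    }))
  }
  need <- c("year", "sampling_events", "shoots_measured", "plot_growth_rates",
            "mire_growth_rates", "mean_sample_size", "mean_interval_days")
  miss <- setdiff(need, names(rows))
  if (length(miss)) stop(sprintf("yearly rows missing column(s): %s",
                                 paste(miss, collapse = ", ")))
  if (any(rows$sampling_events == 0)) {
    stop(sprintf("year %s has zero sampling events",
                 rows$year[which(rows$sampling_events == 0)[1]]))
  }
  pooled <- data.frame(
    year = "pooled",
    sampling_events = sum(rows$sampling_events),
    shoots_measured = sum(rows$shoots_measured),
    plot_growth_rates = sum(rows$plot_growth_rates),
    mire_growth_rates = sum(rows$mire_growth_rates),
    mean_sample_size = round_half_up(mean(rows$mean_sample_size), 1),
    mean_interval_days = round_half_up(mean(rows$mean_interval_days), 1),
    stringsAsFactors = FALSE
  )
  if ("plots" %in% names(rows)) {
    pooled$plots <- sprintf("%d-%d", min(rows$plots), max(rows$plots))
    rows$plots <- as.character(rows$plots)
  }
  rows$year <- as.character(rows$year)
  out <- rbind(rows[, names(pooled)], pooled)
  row.names(out) <- NULL
  structure(out, class = c("monitoring_summary", "data.frame"))
}

#' @rdname monitoring_summary
#' @param intervals Growth-interval table for one year.
#' @param year Year label.
#' @export
yearly_monitoring_row <- function(intervals, year) {
  if (nrow(intervals) == 0) {
    stop(sprintf("year %s has zero sampling events", year))
  }
  periods <- unique(intervals[, c("start_date", "end_date")])
  data.frame(
    year = as.character(year),
    sampling_events = length(unique(intervals$end_date)),
    plots = length(unique(intervals$plot_id)),
    shoots_measured = sum(intervals$n_shoots),
    plot_growth_rates = nrow(intervals),
    mire_growth_rates = nrow(periods),
    mean_sample_size = round_half_up(mean(intervals$n_shoots), 1),
    mean_interval_days = round_half_up(
      mean(as.numeric(intervals$end_date - intervals$start_date)), 1),
    stringsAsFactors = FALSE
  )
}
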