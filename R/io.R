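# CSV schemas shared by the generator and the pipeline.
#
#   growth:      plot_id,start_date,end_date,n_shoots,rate_mm_day
#   temperature: date,hour,temp_c      (hour in {0,3,...,21}; daily rows NA)
#   kp:          datetime_utc,kp       (one row per 3-h UTC slot)
#
# Dates are ISO-8601; datetimes "YYYY-MM-DD HH:MM:SS" in UTC.

#' Read a growth-interval table
#'
#' @param path CSV file with header `plot_id,start_date,end_date,n_shoots,rate_mm_day`.
#' @return Data frame with columns `plot_id`, `start_date`, `end_date`
#'   (`Date`), `n_shoots`, `rate` (mm/day).
#' @export
read_growth_intervals <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "start_date", "end_date", "n_shoots", "rate_mm_day")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop(sprintf("growth file missing column(s): %s",
                                 paste(miss, collapse = ", ")))
  out <- data.frame(
    plot_id = as.character(x$plot_id),
    start_date = as.Date(x$start_date),
    end_date = as.Date(x$end_date),
    n_shoots = as.integer(x$n_shoots),
    rate = as.numeric(x$rate_mm_day),
    stringsAsFactors = FALSE
  )
  validate_growth_intervals(out)
  out
}

validate_growth_intervals <- function(x) {
  if (any(x$end_date <= x$start_date)) {
    stop("growth intervals must satisfy end_date > start_date")
  }
  if (any(x$n_shoots < 1)) stop("growth intervals must have n_shoots >= 1")
  if (any(x$rate < 0)) stop("growth rates must be >= 0")
  invisible(x)
}

#' @rdname read_growth_intervals
#' @param x Interval table as returned by [read_growth_intervals()].
#' @param path Output CSV path.
#' @export
write_growth_intervals <- function(x, path) {
  out <- data.frame(
    plot_id = x$plot_id,
    start_date = format(x$start_date),
    end_date = format(x$end_date),
    n_shoots = x$n_shoots,
    rate_mm_day = x$rate
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a temperature table
#'
#' Mixed daily/diurnal schema: rows with `hour` set carry the temperature at
#' that 3-hourly synoptic time; rows with `hour` empty/NA carry the daily
#' mean.
#'
#' @param path CSV file with header `date,hour,temp_c`.
#' @return Data frame with columns `date` (`Date`), `hour` (integer or NA),
#'   `temp_c`.
#' @export
read_temperature_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "hour", "temp_c")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop(sprintf("temperature file missing column(s): %s",
                                 paste(miss, collapse = ", ")))
  data.frame(
    date = as.Date(x$date),
    hour = suppressWarnings(as.integer(x$hour)),
    temp_c = as.numeric(x$temp_c),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_temperature_table
#' @param x Temperature table (columns `date`, `hour`, `temp_c`).
#' @export
write_temperature_table <- function(x, path) {
  out <- data.frame(
    date = format(as.Date(x$date)),
    hour = x$hour,
    temp_c = x$temp_c
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract the daily-mean temperature pattern from a temperature table
#'
#' @param x Temperature table (see [read_temperature_table()]).
#' @return A `daily_pattern` in degC built from the `hour = NA` rows.
#' @export
temperature_daily_pattern <- function(x) {
  d <- x[is.na(x$hour), , drop = FALSE]
  if (nrow(d) == 0) stop("temperature table has no daily-mean (hour = NA) rows")
  daily_pattern(d$date, d$temp_c, "degC")
}

#' Extract a single synoptic hour from a temperature table
#'
#' @param x Temperature table.
#' @param hour One of 0, 3, ..., 21.
#' @return A `daily_pattern` in degC of the temperatures at that hour.
#' @export
temperature_hour_pattern <- function(x, hour) {
  d <- x[!is.na(x$hour) & x$hour == hour, , drop = FALSE]
  if (nrow(d) == 0) stop(sprintf("temperature table has no rows for hour %d", hour))
  daily_pattern(d$date, d$temp_c, "degC")
}

#' Read a three-hourly Kp table
#'
#' @param path CSV file with header `datetime_utc,kp`.
#' @return Data frame with columns `datetime_utc` (`POSIXct`, UTC) and `kp`.
#' @export
read_kp_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("datetime_utc", "kp")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop(sprintf("kp file missing column(s): %s",
                                 paste(miss, collapse = ", ")))
  dt <- as.POSIXct(x$datetime_utc, tz = "UTC")
  if (anyNA(dt)) stop("kp file has unparseable datetime_utc entries")
  data.frame(datetime_utc = dt, kp = as.numeric(x$kp))
}

#' @rdname read_kp_table
#' @param x Kp table (columns `datetime_utc`, `kp`).
#' @export
write_kp_table <- function(x, path) {
  out <- data.frame(
    datetime_utc = format(x$datetime_utc, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    kp = x$kp
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
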