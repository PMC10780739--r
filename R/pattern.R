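#' Date-indexed daily pattern
#'
#' The basic container of the analysis: an ordered series of one value per
#' calendar date with a units tag and a season identifier. Growth-rate
#' patterns exist only inside growing seasons (one season per calendar year);
#' temperature and Kp patterns may be continuous across winters.
#'
#' @param date Vector coercible to `Date`; duplicates are an error.
#' @param value Numeric values, one per date.
#' @param units Units tag, one of `"mm/day"`, `"degC"`, `"Kp"`, `"residual"`.
#' @param season Optional season identifier per date; defaults to the
#'   calendar year.
#' @return A `daily_pattern`: a data frame with columns `date`, `value`,
#'   `season`, sorted by date, carrying a `units` attribute.
#' @export
daily_pattern <- function(date, value, units, season = NULL) {
  date <- as.Date(date)
  units <- match.arg(units, c("mm/day", "degC", "Kp", "residual"))
  if (length(value) != length(date)) {
    stop("`date` and `value` must have equal length")
  }
  if (anyDuplicated(date)) stop("duplicate dates in daily pattern")
  if (is.null(season)) season <- as.integer(format(date, "%Y"))
  if (length(season) != length(date)) {
    stop("`season` must have one entry per date")
  }
  ord <- order(date)
  out <- data.frame(
    date = date[ord], value = as.numeric(value)[ord], season = season[ord],
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(out, units = units, class = c("daily_pattern", "data.frame"))
}

#' @rdname daily_pattern
#' @param x A `daily_pattern`.
#' @export
pattern_units <- function(x) attr(x, "units")

new_pattern_like <- function(template, value, units = pattern_units(template)) {
  daily_pattern(template$date, value, units, season = template$season)
}

#' @export
print.daily_pattern <- function(x, ...) {
  cat(sprintf(
    "<daily_pattern> %d days, units = %s, %d season(s)\n",
    nrow(x), pattern_units(x), length(unique(x$season))
  ))
  if (nrow(x) > 0) {
    cat(sprintf("  %s .. %s\n", min(x$date), max(x$date)))
  }
  invisible(x)
}
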