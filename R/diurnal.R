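#' Sliding-window response matrix across the diurnal hours
#'
#' Repeats the Kp-gradient analysis once per synoptic hour: growth of day d
#' is paired with the temperature at that hour of day d - lag (day-prior
#' convention retained per hour) and the day-prior Kp, records are sorted by
#' Kp, and the sliding-window correlation profile is computed. Only days on
#' which all eight hours are available enter, so every row shares the same
#' records and the same window Kp means.
#'
#' @param growth A `daily_pattern` of growth rates.
#' @param diurnal_temp Diurnal temperature table: columns `date`, `hour`,
#'   and `temp` or `temp_c`; all eight synoptic hours must be present.
#' @param kp_daily A `daily_pattern` of daily Kp.
#' @param window Sliding-window size (default 200).
#' @param lag Driver lag in days (default 1).
#' @return A `diurnal_matrix` list: `hours`, `r` (8 x n-windows matrix of
#'   windowed correlations), `kp_mean` (per window), `full_profile` (named
#'   per-hour whole-data r), `n_records`, `window`.
#' @export
diurnal_response_matrix <- function(growth, diurnal_temp, kp_daily,
                                    window = 200, lag = 1L) {
  hours <- synoptic_hours()
  tcol <- if ("temp" %in% names(diurnal_temp)) "temp" else "temp_c"
  have <- unique(diurnal_temp$hour)
  miss <- setdiff(hours, have)
  if (length(miss)) {
    stop(sprintf("diurnal temperature table is missing hour(s): %s",
                 paste(miss, collapse = ", ")))
  }
  # keep only dates carrying all eight hours so rows stay comparable
  cnt <- table(diurnal_temp$date[diurnal_temp$hour %in% hours])
  full_dates <- as.Date(names(cnt)[cnt == 8])
  keep <- diurnal_temp$date %in% full_dates
  dt <- diurnal_temp[keep, , drop = FALSE]

  profiles <- vector("list", 8)
  full_r <- numeric(8)
  kp_mean <- NULL
  n_rec <- NA_integer_
  for (i in seq_along(hours)) {
    h <- hours[i]
    sel <- dt$hour == h
    temp_h <- daily_pattern(dt$date[sel], dt[[tcol]][sel], "degC")
    rec <- suppressMessages(lag_align(growth, temp_h, kp_daily, lag))
    rec <- sort_by_kp(rec)
    ws <- sliding_window_correlation(rec, window)
    profiles[[i]] <- ws$r
    full_r[i] <- pearson(rec$growth, rec$temp)$r
    if (is.null(kp_mean)) {
      kp_mean <- ws$kp_mean
      n_rec <- nrow(rec)
    }
  }
  r <- do.call(rbind, profiles)
  rownames(r) <- as.character(hours)
  names(full_r) <- as.character(hours)
  structure(
    list(hours = hours, r = r, kp_mean = kp_mean, full_profile = full_r,
         n_records = n_rec, window = window),
    class = "diurnal_matrix"
  )
}

#' @export
print.diurnal_matrix <- function(x, ...) {
  cat(sprintf(
    "<diurnal_matrix> 8 hours x %d windows (window = %d, n = %d records)\n",
    ncol(x$r), x$window, x$n_records
  ))
  cat("full-data per-hour r:\n")
  print(round(x$full_profile, 3))
  invisible(x)
}

#' Bimodality score of the diurnal response profile
#'
#' Quantifies the morning/evening double peak of the growth response to
#' diurnal temperature: `score = mean(morning peak, evening peak) - midday
#' trough`, where the peaks are the maxima of the per-hour correlation over
#' hours 6-9 and 18-21 and the trough is the minimum over hours 12-15. The
#' score is positive exactly when the bimodal shape holds.
#'
#' @param x A `diurnal_matrix` or a named numeric per-hour profile (names
#'   "0", "3", ..., "21").
#' @param morning,evening,midday Hour groups defining the two peaks and the
#'   trough.
#' @return A `bimodality_score` list: `morning_peak`, `evening_peak`,
#'   `midday_trough`, `score`.
#' @export
bimodality_score <- function(x, morning = c(6, 9), evening = c(18, 21),
                             midday = c(12, 15)) {
  profile <- if (inherits(x, "diurnal_matrix")) x$full_profile else x
  if (is.null(names(profile))) {
    stop("per-hour profile must be named by hour")
  }
  pick <- function(hs) profile[as.character(hs)]
  m <- max(pick(morning))
  e <- max(pick(evening))
  tr <- min(pick(midday))
  structure(
    list(morning_peak = m, evening_peak = e, midday_trough = tr,
         score = mean(c(m, e)) - tr),
    class = "bimodality_score"
  )
}

#' @export
print.bimodality_score <- function(x, ...) {
  cat(sprintf(
    "bimodality score %.4f (morning %.4f, evening %.4f, midday %.4f)\n",
    x$score, x$morning_peak, x$evening_peak, x$midday_trough
  ))
  invisible(x)
}
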