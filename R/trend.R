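r_squared <- function(y, fitted) {
  tss <- sum((y - mean(y))^2)
  rss <- sum((y - fitted)^2)
  if (tss <= 0) 1 else 1 - rss / tss
}

#' Remove the per-season quadratic trend from a growth pattern
#'
#' Fits an ordinary least-squares second-order polynomial in day-of-season
#' to each season independently (growth exists only within seasons) and
#' returns the fitted coefficients plus the residual pattern.
#'
#' @param pattern A `daily_pattern` of growth rates.
#' @return List of class `quadratic_season_trend`: `trend` (one row per
#'   season: `c0`, `c1`, `c2` over day-of-season, `r_squared`, `n`) and
#'   `residuals` (a `daily_pattern` with units `"residual"`).
#' @export
fit_quadratic_per_season <- function(pattern) {
  if (nrow(pattern) == 0) stop("empty pattern")
  seasons <- unique(pattern$season)
  resid <- pattern$value
  rows <- vector("list", length(seasons))
  for (i in seq_along(seasons)) {
    idx <- which(pattern$season == seasons[i])
    if (length(idx) < 4) {
      stop(sprintf("season %s has %d day(s); at least 4 are required",
                   seasons[i], length(idx)))
    }
    x <- as.numeric(pattern$date[idx] - min(pattern$date[idx]))
    y <- pattern$value[idx]
    fit <- stats::lm(y ~ x + I(x^2))
    resid[idx] <- stats::residuals(fit)
    co <- stats::coef(fit)
    co[is.na(co)] <- 0
    rows[[i]] <- data.frame(
      season = seasons[i], c0 = co[[1]], c1 = co[[2]], c2 = co[[3]],
      r_squared = r_squared(y, stats::fitted(fit)), n = length(idx)
    )
  }
  structure(
    list(trend = do.call(rbind, rows),
         residuals = new_pattern_like(pattern, resid, "residual")),
    class = "quadratic_season_trend"
  )
}

#' Fit and remove a single annual sinusoid
#'
#' Linear least squares on the basis `{1, sin(2*pi*t/P), cos(2*pi*t/P)}`
#' with `t` in days since the first date. The fitted curve is reported as
#' offset + amplitude * sin at a phase expressed as the day (since the first
#' date) at which the sinusoid peaks.
#'
#' @param pattern A `daily_pattern` (typically daily temperature).
#' @param period Period in days (default 365.3, the annual cycle).
#' @return List of class `harmonic_trend`: `period`, `offset`, `amplitude`,
#'   `phase_days` (peak day in `[0, period)`), `coef_sin`, `coef_cos`,
#'   `r_squared`, `n`, and `residuals` (a `daily_pattern`).
#' @export
fit_harmonic <- function(pattern, period = 365.3) {
  if (period <= 0) stop("period must be > 0")
  if (nrow(pattern) < 3) stop("harmonic fit needs at least 3 points")
  t <- as.numeric(pattern$date - pattern$date[1])
  if (diff(range(t)) < period) {
    warning("pattern spans less than one period; the fit may be poorly constrained")
  }
  omega <- 2 * pi / period
  s <- sin(omega * t)
  co <- cos(omega * t)
  y <- pattern$value
  fit <- stats::lm(y ~ s + co)
  b <- stats::coef(fit)
  b[is.na(b)] <- 0
  bs <- b[["s"]]
  bc <- b[["co"]]
  amplitude <- sqrt(bs^2 + bc^2)
  # y = offset + amplitude * sin(omega * t + psi); peak at omega*t + psi = pi/2
  psi <- atan2(bc, bs)
  phase_days <- if (amplitude > 0) ((pi / 2 - psi) / omega) %% period else 0
  structure(
    list(period = period, offset = b[[1]], amplitude = amplitude,
         phase_days = phase_days, coef_sin = bs, coef_cos = bc,
         r_squared = r_squared(y, stats::fitted(fit)), n = nrow(pattern),
         residuals = new_pattern_like(pattern, y - stats::fitted(fit),
                                      "residual")),
    class = "harmonic_trend"
  )
}

#' @export
print.harmonic_trend <- function(x, ...) {
  cat(sprintf(
    "<harmonic_trend> period %.1f d, amplitude %.3f, offset %.3f, peak day %.1f, R^2 = %.4f (n = %d)\n",
    x$period, x$amplitude, x$offset, x$phase_days, x$r_squared, x$n
  ))
  invisible(x)
}

#' Select the best-fitting period over a grid
#'
#' Fits [fit_harmonic()] at each candidate period and returns the one that
#' maximizes R-squared (ties broken towards the smaller period).
#'
#' @param pattern A `daily_pattern`.
#' @param periods Non-empty numeric grid of candidate periods in days.
#' @return List: `best_period`, `best_fit` (the `harmonic_trend` at it), and
#'   `table` (data frame of `period`, `r_squared`).
#' @export
scan_period <- function(pattern, periods) {
  if (length(periods) < 1) stop("period grid must be non-empty")
  fits <- suppressWarnings(lapply(periods, function(p) fit_harmonic(pattern, p)))
  r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
  ord <- order(-r2, periods)
  best <- ord[1]
  list(
    best_period = periods[best],
    best_fit = fits[[best]],
    table = data.frame(period = periods, r_squared = r2)
  )
}
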