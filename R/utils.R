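# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Decimal rounding with the half-up convention used for the monitoring
#' bookkeeping (base `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded to `digits` decimals, ties rounded up.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Stationary AR(1) series with marginal standard deviation `sd`.
# x_t = rho * x_{t-1} + e_t, e_t ~ N(0, sd^2 * (1 - rho^2)), x_0 ~ N(0, sd^2).
ar1_series <- function(n, rho, sd = 1) {
  stopifnot(n >= 1)
  if (rho < 0 || rho >= 1) stop("AR(1) coefficient must lie in [0, 1)")
  if (sd == 0) return(rep(0, n))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  init <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(innov, rho, method = "recursive", init = init))
}

stop_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
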