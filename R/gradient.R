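#' Pearson correlation with log-space p-value
#'
#' Standard product-moment correlation with a two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom,
#' computed and stored in log10 space so extremely small p-values (|t| far
#' beyond 25) do not underflow.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, both non-constant.
#' @return A `cor_result` list: `r`, `n`, `log10_p`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("Pearson correlation needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined")
  }
  r <- stats::cor(x, y)
  structure(list(r = r, n = n, log10_p = log10_p_from_r(r, n)),
            class = "cor_result")
}

log10_p_from_r <- function(r, n) {
  denom <- 1 - r^2
  if (denom <= 0) return(-Inf)
  t <- abs(r) * sqrt((n - 2) / denom)
  (log(2) + stats::pt(t, df = n - 2, lower.tail = FALSE, log.p = TRUE)) / log(10)
}

#' @export
print.cor_result <- function(x, ...) {
  if (is.finite(x$log10_p)) {
    e <- floor(x$log10_p)
    m <- 10^(x$log10_p - e)
    cat(sprintf("r = %.4f; n = %d; P = %.1f x 10^%d\n", x$r, x$n, m, e))
  } else {
    cat(sprintf("r = %.4f; n = %d; P = 0 (exact linearity)\n", x$r, x$n))
  }
  invisible(x)
}

#' Sort paired records along the Kp gradient
#'
#' Stable ascending sort on the Kp value, ties broken by date ascending.
#'
#' @param records Paired records (columns `date`, `growth`, `temp`, `kp`).
#' @return The records reordered.
#' @export
sort_by_kp <- function(records) {
  if (nrow(records) == 0) stop("no records to sort")
  out <- records[order(records$kp, records$date), , drop = FALSE]
  row.names(out) <- NULL
  out
}

# Rolling Pearson r and rolling mean over contiguous windows, by centered
# cumulative sums (values are globally centered first for precision).
roll_r <- function(g, t, w) {
  g <- g - mean(g)
  t <- t - mean(t)
  cs <- function(x) cumsum(c(0, x))
  n <- length(g)
  i <- seq_len(n - w + 1)
  j <- i + w
  Sg <- cs(g)[j] - cs(g)[i]
  St <- cs(t)[j] - cs(t)[i]
  Sgg <- cs(g * g)[j] - cs(g * g)[i]
  Stt <- cs(t * t)[j] - cs(t * t)[i]
  Sgt <- cs(g * t)[j] - cs(g * t)[i]
  num <- w * Sgt - Sg * St
  den <- (w * Sgg - Sg^2) * (w * Stt - St^2)
  num / sqrt(pmax(den, 0))
}

roll_mean <- function(x, w) {
  cs <- cumsum(c(0, x))
  n <- length(x)
  i <- seq_len(n - w + 1)
  (cs[i + w] - cs[i]) / w
}

#' Sliding-window correlation along the Kp gradient
#'
#' On records sorted by increasing Kp, computes the Pearson correlation of
#' (growth, temperature) and the mean (or median) Kp in every contiguous
#' window of `window` records, stepping one record at a time: window i
#' covers ranks i..i+window-1, giving n - window + 1 window statistics.
#'
#' @param records Kp-sorted paired records (see [sort_by_kp()]).
#' @param window Window size in records (default 200).
#' @param kp_stat Window Kp summary: `"mean"` (default) or `"median"`.
#' @return A `window_stats` data frame: `window`, `kp_mean`, `r`, `n`.
#' @export
sliding_window_correlation <- function(records, window = 200,
                                       kp_stat = c("mean", "median")) {
  kp_stat <- match.arg(kp_stat)
  n <- nrow(records)
  if (window < 3) stop("window must be >= 3")
  if (n < window) {
    stop(sprintf(
      "only %d records but window = %d; use a smaller window", n, window))
  }
  if (is.unsorted(records$kp)) {
    stop("records must be sorted by Kp; see sort_by_kp()")
  }
  r <- roll_r(records$growth, records$temp, window)
  kp_mean <- if (kp_stat == "mean") {
    roll_mean(records$kp, window)
  } else {
    zoo::rollapply(records$kp, window, stats::median, align = "left")
  }
  structure(
    data.frame(window = seq_along(r), kp_mean = kp_mean, r = r, n = window),
    class = c("window_stats", "data.frame")
  )
}

#' Correlation within a closed Kp subrange
#'
#' @param records Paired records.
#' @param lo,hi Closed Kp bounds; records with `lo <= kp <= hi` are used.
#' @return A `cor_result` with attributes `lo`, `hi`.
#' @export
subrange_summary <- function(records, lo, hi) {
  sel <- records$kp >= lo & records$kp <= hi
  if (sum(sel) < 3) {
    stop(sprintf("fewer than 3 records with Kp in [%g, %g]", lo, hi))
  }
  out <- pearson(records$growth[sel], records$temp[sel])
  attr(out, "lo") <- lo
  attr(out, "hi") <- hi
  out
}

#' Detect the favorable Kp interval from a window profile
#'
#' Windows whose correlation reaches the reference level (normally the
#' whole-data correlation) are flagged; if none is, no interval is detected.
#' The interval is grown around the maximum-r window and reported as the Kp
#' span `[min kp_mean, max kp_mean]` of its windows. Two boundary rules are
#' provided:
#'
#' * `"half_rise"` (default): the contiguous region around the peak where
#'   the profile stays above the level halfway between the reference and
#'   the typical elevated level, the latter estimated robustly as the
#'   median correlation of the flagged windows. The profile crosses this
#'   level on its steep flanks, so the boundary is far better localized
#'   than a crossing at the reference level itself, which sits in the flat
#'   foot of the rise; using the median rather than the maximum avoids the
#'   inward bias a noisy peak would induce.
#' * `"run"`: the maximal contiguous run of flagged (`r >= reference`)
#'   windows containing the peak.
#'
#' @param stats A `window_stats` data frame.
#' @param reference Reference correlation level (e.g. the global r).
#' @param records Optional Kp-sorted records; if given, the correlation over
#'   all records inside the detected span is attached.
#' @param rule Boundary rule, `"half_rise"` or `"run"`.
#' @return A `kp_interval` list (`lo`, `hi`, `windows`, `peak_kp`, `peak_r`,
#'   and if `records` given `r_inside`, `n_inside`), or `NULL`.
#' @export
detect_favorable_interval <- function(stats, reference, records = NULL,
                                      rule = c("half_rise", "run")) {
  rule <- match.arg(rule)
  if (nrow(stats) < 1) stop("empty window profile")
  flag <- stats$r >= reference
  if (!any(flag)) return(NULL)
  peak <- which.max(stats$r)
  level <- if (rule == "half_rise") {
    reference + 0.5 * (stats::median(stats$r[flag]) - reference)
  } else {
    reference
  }
  above <- stats$r >= level
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  k <- which(starts <= peak & ends >= peak)
  idx <- starts[k]:ends[k]
  out <- list(
    lo = min(stats$kp_mean[idx]), hi = max(stats$kp_mean[idx]),
    windows = idx, peak_kp = stats$kp_mean[peak], peak_r = stats$r[peak]
  )
  if (!is.null(records)) {
    inside <- subrange_summary(records, out$lo, out$hi)
    out$r_inside <- inside$r
    out$n_inside <- inside$n
  }
  structure(out, class = "kp_interval")
}

#' Share of monitoring days with favorable Kp
#'
#' @param kp Day-prior Kp values over the monitoring days (a `daily_pattern`,
#'   a paired-record `kp` column, or a bare numeric vector).
#' @param interval A `kp_interval` or numeric `c(lo, hi)`.
#' @return Percentage of days with `lo <= kp <= hi`, rounded half-up to one
#'   decimal.
#' @export
fraction_days_in_interval <- function(kp, interval) {
  v <- if (is.data.frame(kp)) kp$value %||% kp$kp else kp
  if (length(v) == 0) stop("empty day set")
  bounds <- if (is.list(interval)) c(interval$lo, interval$hi) else interval
  round_half_up(100 * mean(v >= bounds[1] & v <= bounds[2]), 1)
}

#' Permutation null envelope for the window profile
#'
#' Re-randomizes the Kp column against the fixed (growth, temperature)
#' pairs `n_perm` times, recomputes the sliding-window correlation profile
#' for each replicate, and returns the pointwise 2.5/50/97.5% envelope.
#' Under the null of no Kp modulation the observed profile should lie
#' within the envelope at close to 95% of windows.
#'
#' Two randomization schemes are available. `"permute"` draws a fresh
#' random permutation of the Kp values, which treats the records as
#' exchangeable; because Kp is strongly autocorrelated in time, days of
#' similar Kp cluster in calendar time, so the observed profile carries
#' more low-frequency variation than this exchangeable null and the
#' envelope is somewhat anti-conservative. `"shift"` rotates the
#' date-ordered Kp column by a random circular offset, which preserves the
#' Kp series' own autocorrelation and is the better-calibrated null for
#' autocorrelated covariates; see the package vignette.
#'
#' @param records Paired records in date order (need not be Kp-sorted).
#' @param window Window size.
#' @param n_perm Number of replicates (>= 100).
#' @param seed Integer seed for the randomization.
#' @param probs Envelope quantiles.
#' @param method `"permute"` (default) or `"shift"`.
#' @return Data frame `window`, `lower`, `median`, `upper` with attributes
#'   `n_perm`, `probs` and `method`.
#' @export
permutation_envelope <- function(records, window, n_perm = 200, seed = 1,
                                 probs = c(0.025, 0.5, 0.975),
                                 method = c("permute", "shift")) {
  method <- match.arg(method)
  if (n_perm < 100) stop("n_perm must be >= 100")
  n <- nrow(records)
  if (n < window) stop("fewer records than the window size")
  records <- records[order(records$date), , drop = FALSE]
  set.seed(seed)
  m <- n - window + 1
  prof <- matrix(NA_real_, nrow = n_perm, ncol = m)
  for (b in seq_len(n_perm)) {
    # assign re-randomized kp values to the fixed pairs, then re-sort by the
    # usual (kp, date) order so tie handling matches the observed profile
    kp_new <- if (method == "permute") {
      records$kp[sample.int(n)]
    } else {
      sh <- sample.int(n - 1, 1)
      records$kp[((seq_len(n) - 1 + sh) %% n) + 1]
    }
    ord <- order(kp_new, records$date)
    prof[b, ] <- roll_r(records$growth[ord], records$temp[ord], window)
  }
  qs <- apply(prof, 2, stats::quantile, probs = probs, names = FALSE)
  structure(
    data.frame(window = seq_len(m), lower = qs[1, ], median = qs[2, ],
               upper = qs[3, ]),
    n_perm = n_perm, probs = probs, method = method
  )
}

#' Fraction of windows inside a permutation envelope
#'
#' @param stats Observed `window_stats`.
#' @param envelope Output of [permutation_envelope()] on the same records
#'   and window size.
#' @return Proportion of windows with `lower <= r <= upper`.
#' @export
envelope_coverage <- function(stats, envelope) {
  if (nrow(stats) != nrow(envelope)) {
    stop("profile and envelope have different window counts")
  }
  mean(stats$r >= envelope$lower & stats$r <= envelope$upper)
}
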