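mk_intervals <- function(starts, ends, rates, plot = "P01", shoots = 30) {
  data.frame(plot_id = plot, start_date = as.Date(starts),
             end_date = as.Date(ends), n_shoots = shoots, rate = rates,
             stringsAsFactors = FALSE)
}

test_that("interval rates extrapolate to the days after each sampling start", {
  p <- intervals_to_daily(mk_intervals("2020-05-01", "2020-05-03", 2.0))
  expect_equal(format(p$date), c("2020-05-02", "2020-05-03"))
  expect_equal(p$value, c(2.0, 2.0))
  # abutting intervals: step change at the boundary day, no gap
  p2 <- intervals_to_daily(mk_intervals(
    c("2020-05-01", "2020-05-03"), c("2020-05-03", "2020-05-05"), c(1, 3)))
  expect_equal(p2$value, c(1, 1, 3, 3))
  expect_equal(as.numeric(diff(p2$date)), rep(1, 3))
  # empty input -> empty pattern
  empty <- data.frame(plot_id = character(), start_date = as.Date(character()),
                      end_date = as.Date(character()), n_shoots = integer(),
                      rate = numeric())
  expect_equal(nrow(intervals_to_daily(empty)), 0)
  expect_error(intervals_to_daily(mk_intervals(
    c("2020-05-01", "2020-05-02"), c("2020-05-04", "2020-05-05"), c(1, 2))),
    "overlap")
})

test_that("extrapolation conserves total growth over each interval", {
  set.seed(42)
  for (i in 1:20) {
    len <- sample(1:6, 1)
    start <- as.Date("2021-06-01") + sample(0:50, 1)
    rate <- runif(1, 0, 5)
    p <- intervals_to_daily(mk_intervals(format(start), format(start + len), rate))
    expect_equal(sum(p$value), rate * len, tolerance = 1e-12)
  }
})

test_that("plot averaging is an unweighted mean over available plots", {
  a <- daily_pattern(c("2020-05-01", "2020-05-02"), c(2, 1), "mm/day")
  b <- daily_pattern(c("2020-05-01", "2020-05-03"), c(4, 5), "mm/day")
  m <- average_plots(list(a, b))
  expect_equal(m$value[m$date == as.Date("2020-05-01")], 3)  # {2, 4} -> 3
  # a date covered by one plot only: no imputation, just that plot
  expect_equal(m$value[m$date == as.Date("2020-05-02")], 1)
  expect_equal(m$value[m$date == as.Date("2020-05-03")], 5)
  expect_identical(average_plots(list(a)), a)
  cc <- daily_pattern("2020-05-01", 1, "degC")
  expect_error(average_plots(list(a, cc)), "unit mismatch")
})

test_that("moving average shrinks at season edges and stays within seasons", {
  p <- daily_pattern(as.Date("2020-05-01") + 0:4, c(1, 2, 3, 4, 5), "mm/day")
  expect_equal(moving_average(p, 3)$value, c(1.5, 2, 3, 4, 4.5))
  expect_equal(moving_average(p, 1)$value, p$value)
  const <- daily_pattern(as.Date("2020-05-01") + 0:4, rep(2, 5), "mm/day")
  expect_equal(moving_average(const, 3)$value, rep(2, 5))
  expect_error(moving_average(p, 2), "odd")
  # two seasons: smoothing never crosses the winter gap
  two <- daily_pattern(c(as.Date("2020-05-01") + 0:2, as.Date("2021-05-01") + 0:2),
                       c(0, 0, 0, 9, 9, 9), "mm/day")
  expect_equal(moving_average(two, 3)$value, c(0, 0, 0, 9, 9, 9))
})

test_that("moving average never widens the value range", {
  set.seed(7)
  for (i in 1:10) {
    v <- rnorm(30)
    p <- daily_pattern(as.Date("2020-05-01") + 0:29, v, "mm/day")
    sm <- moving_average(p, 3)$value
    expect_gte(min(sm), min(v))
    expect_lte(max(sm), max(v))
  }
})

test_that("daily Kp uses complete UTC days and the requested aggregator", {
  mk_kp <- function(days, values) {
    data.frame(
      datetime_utc = as.POSIXct(rep(as.Date(days), each = 8), tz = "UTC") +
        rep(synoptic_hours() * 3600, times = length(days)),
      kp = values
    )
  }
  kp <- mk_kp("2020-05-01", c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_equal(daily_kp(kp, "mean")$value, 0.5)
  expect_equal(daily_kp(kp, "max")$value, 1.0)
  const <- mk_kp("2020-05-02", rep(2, 8))
  expect_equal(daily_kp(const, "mean")$value, 2)
  expect_equal(daily_kp(const, "max")$value, 2)
  # an incomplete day is excluded with a warning
  both <- rbind(kp[1:7, ], const)
  expect_warning(dk <- daily_kp(both, "mean"), "incomplete")
  expect_equal(format(dk$date), "2020-05-02")
  expect_error(daily_kp(kp, "median"))
})

test_that("day-prior alignment pairs growth with lagged drivers", {
  g <- daily_pattern(c("2020-05-02", "2020-05-03", "2020-05-04"), 1:3, "mm/day")
  tp <- daily_pattern(c("2020-05-01", "2020-05-02", "2020-05-03"), c(10, 11, 12), "degC")
  kp <- daily_pattern(c("2020-05-01", "2020-05-02", "2020-05-03"), c(1, 2, 3), "Kp")
  rec <- lag_align(g, tp, kp, 1)
  # growth of May 2 pairs with the May 1 temperature and Kp
  expect_equal(rec$temp[rec$date == as.Date("2020-05-02")], 10)
  expect_equal(rec$kp[rec$date == as.Date("2020-05-02")], 1)
  expect_equal(nrow(rec), 3)
  rec0 <- lag_align(g, tp, kp, 0)
  expect_equal(rec0$temp[rec0$date == as.Date("2020-05-02")], 11)
  # a missing driver day drops exactly that record
  tp2 <- tp[tp$date != as.Date("2020-05-01"), ]
  expect_message(rec2 <- lag_align(g, tp2, kp, 1), "dropped 1")
  expect_equal(nrow(rec2), 2)
  expect_error(lag_align(g, tp, kp, -1), ">= 0")
})

test_that("alignment matches a brute-force date intersection and ignores order", {
  set.seed(11)
  for (i in 1:10) {
    gd <- as.Date("2020-05-01") + sample(0:40, 25)
    td <- as.Date("2020-05-01") + sample(0:40, 30)
    kd <- as.Date("2020-05-01") + sample(0:40, 30)
    g <- daily_pattern(gd, rnorm(25), "mm/day")
    tp <- daily_pattern(td, rnorm(30), "degC")
    kp <- daily_pattern(kd, runif(30, 0, 9), "Kp")
    rec <- suppressMessages(lag_align(g, tp, kp, 1))
    expected <- intersect(intersect(gd, td + 1), kd + 1)
    expect_equal(sort(as.numeric(rec$date)), sort(expected))
    # shuffled inputs give the same records
    shuf <- function(p) daily_pattern(rev(p$date), rev(p$value), pattern_units(p))
    rec2 <- suppressMessages(lag_align(shuf(g), shuf(tp), shuf(kp), 1))
    expect_equal(rec, rec2)
  }
})

test_that("monitoring summary pools counts as sums and means as means", {
  ms <- monitoring_summary(published_yearly_rows())
  pooled <- ms[ms$year == "pooled", ]
  expect_equal(pooled$shoots_measured, 209490)
  expect_equal(pooled$mean_sample_size, 52.1)
  # single year: pooled row equals that year's row
  one <- published_yearly_rows()[3, ]
  ms1 <- monitoring_summary(one)
  p1 <- ms1[ms1$year == "pooled", ]
  for (col in c("sampling_events", "shoots_measured", "plot_growth_rates",
                "mire_growth_rates", "mean_sample_size", "mean_interval_days")) {
    expect_equal(p1[[col]], one[[col]])
  }
  # randomized yearly tables: pooled counts equal brute-force sums
  set.seed(5)
  for (i in 1:5) {
    k <- sample(2:6, 1)
    rows <- data.frame(
      year = as.character(2000 + seq_len(k)),
      sampling_events = sample(10:100, k),
      shoots_measured = sample(1000:50000, k),
      plot_growth_rates = sample(100:2000, k),
      mire_growth_rates = sample(50:300, k),
      mean_sample_size = round(runif(k, 20, 100), 1),
      mean_interval_days = round(runif(k, 1.5, 6), 1)
    )
    p <- monitoring_summary(rows)
    p <- p[p$year == "pooled", ]
    expect_equal(p$sampling_events, sum(rows$sampling_events))
    expect_equal(p$mire_growth_rates, sum(rows$mire_growth_rates))
    expect_equal(p$mean_sample_size, round_half_up(mean(rows$mean_sample_size), 1))
  }
  bad <- published_yearly_rows()
  bad$sampling_events[2] <- 0
  expect_error(monitoring_summary(bad), "zero sampling events")
})

test_that("yearly rows are computed correctly from an interval table", {
  iv <- rbind(
    mk_intervals(c("2020-05-01", "2020-05-03"), c("2020-05-03", "2020-05-05"),
                 c(1, 2), plot = "A", shoots = 20),
    mk_intervals(c("2020-05-01", "2020-05-03"), c("2020-05-03", "2020-05-05"),
                 c(3, 4), plot = "B", shoots = 40)
  )
  row <- yearly_monitoring_row(iv, 2020)
  expect_equal(row$sampling_events, 2)
  expect_equal(row$plots, 2)
  expect_equal(row$shoots_measured, 120)
  expect_equal(row$plot_growth_rates, 4)
  expect_equal(row$mire_growth_rates, 2)
  expect_equal(row$mean_sample_size, 30.0)
  expect_equal(row$mean_interval_days, 2.0)
})
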