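test_that("pearson matches hand-computed values and guards its domain", {
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson(c(1, 2, 3), c(6, 4, 2))$r, -1)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)  # cov 4 / (sqrt5*sqrt5)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson(1:2, 1:2), "n >= 3")
  expect_error(pearson(1:4, 1:5), "equal length")
})

test_that("log-space p-values agree with cor.test and never underflow", {
  set.seed(2)
  x <- rnorm(50)
  y <- x + rnorm(50, 0, 1.5)
  res <- pearson(x, y)
  ct <- cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(10^res$log10_p, ct$p.value, tolerance = 1e-8)
  # a correlation whose p-value underflows double precision stays finite in log space
  n <- 2000
  xx <- rnorm(n)
  yy <- xx + rnorm(n, 0, 0.1)
  big <- pearson(xx, yy)
  expect_true(is.finite(big$log10_p))
  expect_lt(big$log10_p, -300)
  # p monotone decreasing in |r| at fixed n
  p_at <- function(r) kpgrowth:::log10_p_from_r(r, 100)
  rs <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(sapply(rs, p_at)) < 0))
})

test_that("records sort stably by Kp with date tie-break", {
  rec <- data.frame(
    date = as.Date(c("2020-05-03", "2020-05-01", "2020-05-02")),
    growth = 1:3, temp = 1:3, kp = c(2, 1, 3)
  )
  expect_equal(sort_by_kp(rec)$kp, c(1, 2, 3))
  tie <- data.frame(date = as.Date(c("2020-05-03", "2020-05-01")),
                    growth = 1:2, temp = 1:2, kp = c(1, 1))
  expect_equal(format(sort_by_kp(tie)$date[1]), "2020-05-01")
  sorted <- sort_by_kp(rec)
  expect_equal(sort_by_kp(sorted), sorted)
})

test_that("sliding windows reproduce hand-computed profiles", {
  rec <- data.frame(date = as.Date("2020-05-01") + 0:4,
                    growth = c(1, 2, 3, 2, 1), temp = 1:5,
                    kp = c(.1, .2, .3, .4, .5))
  ws <- sliding_window_correlation(rec, 3)
  expect_equal(ws$r, c(1, 0, -1), tolerance = 1e-12)
  expect_equal(ws$kp_mean, c(0.2, 0.3, 0.4), tolerance = 1e-12)
  expect_equal(ws$n, rep(3, 3))
  # degenerate window covering everything equals the global correlation
  rec2 <- data.frame(date = as.Date("2020-05-01") + 0:9,
                     growth = rnorm(10), temp = rnorm(10), kp = sort(runif(10)))
  ws2 <- sliding_window_correlation(rec2, 10)
  expect_equal(nrow(ws2), 1)
  expect_equal(ws2$r, pearson(rec2$growth, rec2$temp)$r, tolerance = 1e-12)
  expect_error(sliding_window_correlation(rec, 6), "smaller window")
  expect_error(sliding_window_correlation(rec, 2), ">= 3")
  unsorted <- rec
  unsorted$kp <- rev(unsorted$kp)
  expect_error(sliding_window_correlation(unsorted, 3), "sorted")
})

test_that("every window matches the direct Pearson oracle", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(30:80, 1)
    w <- sample(5:20, 1)
    rec <- sort_by_kp(data.frame(
      date = as.Date("2020-05-01") + seq_len(n),
      growth = rnorm(n, 2, 1), temp = rnorm(n, 10, 5), kp = runif(n, 0, 9)
    ))
    ws <- sliding_window_correlation(rec, w)
    expect_equal(ws$r, direct_window_r(rec, w), tolerance = 1e-12)
    expect_true(all(diff(ws$kp_mean) >= -1e-12))
  }
})

test_that("global correlation is invariant under Kp sorting", {
  camp <- simulate_campaign(small_config(seed = 8))
  rec <- campaign_records(camp)
  expect_equal(pearson(rec$growth, rec$temp)$r,
               with(sort_by_kp(rec), pearson(growth, temp)$r),
               tolerance = 1e-12)
})

test_that("subrange summaries use closed bounds", {
  rec <- data.frame(date = as.Date("2020-05-01") + 0:5,
                    growth = c(1, 2, 3, 4, 5, 6), temp = c(2, 1, 3, 5, 4, 6),
                    kp = c(0.5, 0.87, 1.0, 1.61, 2.0, 3.0))
  all_r <- subrange_summary(rec, 0, 9)
  expect_equal(all_r$r, pearson(rec$growth, rec$temp)$r)
  inside <- subrange_summary(rec, 0.87, 1.61)
  expect_equal(inside$n, 3)  # both boundary records included
  expect_error(subrange_summary(rec, 7, 8), "fewer than 3")
})

test_that("interval detection flags elevated runs and handles null profiles", {
  ws <- structure(data.frame(window = 1:5, kp_mean = seq(0.5, 2.5, by = 0.5),
                             r = c(0.1, 0.1, 0.1, 0.1, 0.1), n = 10),
                  class = c("window_stats", "data.frame"))
  expect_null(detect_favorable_interval(ws, reference = 0.5))
  ws$r <- c(0.1, 0.6, 0.7, 0.6, 0.1)
  iv <- detect_favorable_interval(ws, reference = 0.5)
  expect_equal(iv$lo, 1.0)
  expect_equal(iv$hi, 2.0)
  expect_equal(iv$peak_kp, 1.5)
  # the run rule returns the same span here (single flagged run)
  iv2 <- detect_favorable_interval(ws, reference = 0.5, rule = "run")
  expect_equal(c(iv2$lo, iv2$hi), c(iv$lo, iv$hi))
})

test_that("the share of favorable days is a closed-interval percentage", {
  expect_equal(fraction_days_in_interval(c(0.5, 1.0, 1.2, 2.0),
                                         c(0.87, 1.61)), 50.0)
  expect_equal(fraction_days_in_interval(c(0.5, 1.0, 1.2, 2.0), c(0, 9)), 100.0)
  expect_equal(fraction_days_in_interval(c(0.5, 1.0), c(5, 6)), 0.0)
  expect_error(fraction_days_in_interval(numeric(), c(0, 1)), "empty")
})

test_that("growth does not respond to Kp directly when coupling runs through temperature", {
  # the modulation acts on the temperature slope, not on the Kp level itself
  rs <- sapply(1:3, function(s) {
    camp <- cached_campaign(s)
    rec <- campaign_records(camp)
    pearson(rec$growth, rec$kp)$r
  })
  expect_true(all(abs(rs) < 0.1))
})

test_that("permutation envelopes are reproducible and reject only with modulation", {
  camp <- simulate_campaign(small_config(seed = 13))
  rec <- campaign_records(camp)
  sorted <- sort_by_kp(rec)
  env1 <- permutation_envelope(rec, 100, n_perm = 100, seed = 5)
  env2 <- permutation_envelope(rec, 100, n_perm = 100, seed = 5)
  expect_identical(env1, env2)
  expect_true(all(env1$lower <= env1$median & env1$median <= env1$upper))
  expect_error(permutation_envelope(rec, 100, n_perm = 50, seed = 1), ">= 100")
  prof <- sliding_window_correlation(sorted, 100)
  expect_equal(nrow(env1), nrow(prof))
  # at the full campaign scale the injected boost escapes the null envelope
  # inside the injected Kp window
  camp_full <- cached_campaign(1)
  rec_full <- campaign_records(camp_full)
  prof_full <- sliding_window_correlation(sort_by_kp(rec_full), 200)
  env_full <- permutation_envelope(rec_full, 200, n_perm = 100, seed = 1)
  escape <- prof_full$r > env_full$upper &
    prof_full$kp_mean >= 0.9 & prof_full$kp_mean <= 1.6
  expect_true(any(escape))
})
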