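test_that("ACF basics: lag 0 is 1, band is 1.96/sqrt(n)", {
  ts <- ar1_ts(500, 0.5)
  a <- acf_fn(ts, 20)
  expect_identical(a$values[1], 1)
  expect_equal(a$ci, 1.96 / sqrt(500))
  expect_true(all(abs(a$values) <= 1 + 1e-12))
  expect_error(acf_fn(ts, 300), "max_lag")
})

test_that("AR(1) autocorrelation follows phi^k", {
  phi <- 0.8
  ts <- ar1_ts(4000, phi, seed = 10)
  a <- acf_fn(ts, 10)
  for (k in 1:5)
    expect_lt(abs(a$values[k + 1] - phi^k), 0.06)
})

test_that("PACF agrees with ACF at lag 1 and with the stats oracle", {
  ts <- make_ts(withr::with_seed(4, rnorm(300, 20, 5)))
  a <- acf_fn(ts, 25)
  p <- pacf_fn(ts, 25)
  expect_equal(p$values[1], a$values[2], tolerance = 1e-12)
  # independent route: stats::pacf on the same data
  oracle <- as.numeric(stats::pacf(ts$values, lag.max = 25,
                                   plot = FALSE)$acf)
  expect_equal(p$values, oracle, tolerance = 1e-8)
})

test_that("PACF isolates direct dependence in AR processes", {
  # AR(1): partial correlations vanish beyond lag 1
  ts1 <- ar1_ts(4000, 0.8, seed = 12)
  p1 <- pacf_fn(ts1, 10)
  expect_gt(p1$values[1], 0.7)
  expect_true(all(abs(p1$values[2:10]) < 2 * p1$ci))

  # AR(2): lag-2 partial correlation recovers the second coefficient
  phi <- c(0.5, 0.3)
  ts2 <- withr::with_seed(13, make_ts(as.numeric(
    stats::arima.sim(list(ar = phi), 6000))))
  p2 <- pacf_fn(ts2, 10)
  expect_lt(abs(p2$values[2] - phi[2]), 0.05)
  expect_true(all(abs(p2$values[3:10]) < 2 * p2$ci))
})

test_that("white-noise correlograms exceed the band at the nominal rate", {
  hits <- 0; total <- 0
  for (s in 1:20) {
    x <- withr::with_seed(100 + s, rnorm(500))
    a <- acf_fn(make_ts(x), 40)
    hits <- hits + sum(abs(a$values[-1]) > a$ci)
    total <- total + 40
  }
  rate <- hits / total
  se <- sqrt(0.05 * 0.95 / total)
  expect_lt(abs(rate - 0.05), 4 * se)
})

test_that("weekly_subsample partitions the daily record", {
  daily <- make_ts(1:28)
  subs <- weekly_subsample(daily)
  expect_length(subs, 7)
  expect_true(all(vapply(subs, function(s) s$delta_t == 7, logical(1))))
  expect_true(all(vapply(subs, length, numeric(1)) == 4))
  # the union of subsamples is the original multiset of values
  expect_setequal(unlist(lapply(subs, function(s) s$values)), 1:28)
  # labelled by the weekday actually sampled
  expect_equal(names(subs)[1], weekdays(daily$dates[1]))
  expect_error(weekly_subsample(subs[[1]]), "daily")
  expect_error(weekly_subsample(make_ts(1:10)), "14")
})

test_that("significant_positive_run measures initial memory in days", {
  fake_cf <- function(values, ci, delta_t = 1)
    structure(list(lags = seq_along(values), lag_days =
                     seq_along(values) * delta_t, values = values,
                   ci = ci, kind = "ACF", n = 100, delta_t = delta_t),
              class = "mosq_cf")
  expect_equal(significant_positive_run(fake_cf(rep(0.5, 8), 0.2)), 8)
  expect_equal(significant_positive_run(fake_cf(c(0.1, 0.5), 0.2)), 0)
  expect_equal(significant_positive_run(
    fake_cf(c(0.5, 0.4, 0.1, 0.5), 0.2)), 2)
  # reported in days: weekly series scale by delta_t
  expect_equal(significant_positive_run(
    fake_cf(c(0.5, 0.4, 0.1), 0.2, delta_t = 7)), 14)

  # brute-force scan oracle on a real ACF
  a <- acf_fn(ar1_ts(3000, 0.9, seed = 21), 60)
  v <- a$values[-1]
  scan <- 0
  for (k in seq_along(v)) {
    if (v[k] > a$ci) scan <- k else break
  }
  expect_equal(significant_positive_run(a), scan)
})

test_that("weekly subsampling hides sub-biweekly ACF structure", {
  # a 10-day cycle produces ACF peaks at lags 10, 20, ... in daily data;
  # none of the weekly subsamples can represent a 10-day periodicity
  n <- 700
  x <- withr::with_seed(31,
    200 + 80 * sin(2 * pi * seq_len(n) / 10) + rnorm(n, 0, 10))
  daily <- make_ts(x)
  a_daily <- acf_fn(daily, 30)
  expect_gt(a_daily$values[11], 0.5)    # strong peak at the 10-day lag
  for (s in weekly_subsample(daily)) {
    a_w <- acf_fn(s, 10)
    # the cycle cannot appear at its true time scale: the weekly lags
    # bracketing 10 days (7 and 14 d) show no positive peak -- the
    # sub-Nyquist periodicity aliases elsewhere instead
    expect_lt(a_w$values[2], 0.2)
    expect_lt(a_w$values[3], 0.2)
  }
})
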