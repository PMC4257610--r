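# independent oracle: iterate a density-dependent map with dependence at
# an arbitrary lag (the package generator only covers lag 0)
iterate_lagged <- function(model, r_m, K, n, lag, N0) {
  N <- numeric(n)
  N[seq_len(lag + 1)] <- N0 * (1 + 0.05 * seq_len(lag + 1))
  for (t in (lag + 1):(n - 1)) {
    D <- if (model == "ricker") N[t - lag] / K else
      log(N[t - lag]) / log(K)
    N[t + 1] <- N[t] * exp(r_m * (1 - D))
  }
  make_ts(N)
}

test_that("noise-free series give exact parameter recovery", {
  for (model in c("ricker", "gompertz")) {
    for (lag in c(0L, 2L, 5L)) {
      ts <- iterate_lagged(model, r_m = 0.4, K = 120, n = 150,
                           lag = lag, N0 = 12)
      fit <- fit_density_model(ts, model, lag = lag)
      expect_equal(fit$r_m, 0.4, tolerance = 1e-6)
      expect_equal(fit$K, 120, tolerance = 1e-6)
      expect_lt(fit$residual_sd, 1e-7)
      expect_equal(fit$n_dropped_zero, 0)
    }
  }
})

test_that("recovery bias shrinks with series length under noise", {
  est <- function(n) {
    ts <- generate_density_series("ricker", r_m = 0.4, K = 100, n = n,
                                  N0 = 50, noise_sd = 0.1, seed = 77)
    fit <- fit_density_model(ts, "ricker", lag = 0)
    abs(fit$K - 100)
  }
  expect_lt(est(2000), est(200))
})

test_that("zero-abundance transitions are dropped and counted", {
  v <- c(10, 20, 0, 0, 15, 30, 25, 40, 18, 22, rep(c(30, 45, 20, 35), 20))
  ts <- make_ts(v)
  fit <- fit_density_model(ts, "ricker", lag = 0)
  # transitions touching the two zeros: (20->0), (0->0), (0->15)
  expect_equal(fit$n_dropped_zero, 3)
  expect_equal(fit$n_used, length(v) - 1 - 3)
})

test_that("the fitted-covariate interface is honoured", {
  n <- 400
  temp <- make_ts(withr::with_seed(3, rnorm(n, 20, 4)), label = "temp")
  ts <- generate_density_series("ricker", 0.5, 200, n = n, N0 = 100,
                                noise_sd = 0.05, seed = 5)
  fit <- fit_density_model(ts, "ricker", lag = 0,
                           covariates = list(temp = temp))
  expect_named(fit$covariate_coeffs, "temp")
  # an unrelated covariate gets a near-zero coefficient
  expect_lt(abs(fit$covariate_coeffs[["temp"]]), 0.01)
  expect_error(simulate_density_model(fit, 50), "covariates")
  expect_error(fit_density_model(ts, "ricker", 0,
                                 covariates = list(temp = make_ts(1:10))),
               "aligned")
})

test_that("simulation from a fit reproduces its stationary regime", {
  fit <- structure(list(model = "ricker", lag = 0L, r_m = 0.5, K = 100,
                        b = -0.5 / 100, covariate_coeffs = numeric(),
                        residual_sd = 0), class = "density_fit")
  s <- simulate_density_model(fit, 50, N0 = 100)
  expect_equal(s$values, rep(100, 50), tolerance = 1e-10)
  expect_error(simulate_density_model(fit, 50, N0 = 0), "N0")

  # with noise, the long-run mean stays near the carrying capacity
  fit$residual_sd <- 0.15
  s2 <- simulate_density_model(fit, 4000, N0 = 100, seed = 8)
  expect_lt(abs(mean(s2$values) - 100) / 100, 0.10)
})

test_that("multi-lag fits identify the true feedback lag", {
  f1 <- fit_density_model(
    iterate_lagged("ricker", 0.4, 120, 150, 0, 12), "ricker", 0)
  m1 <- multi_lag_fit(
    iterate_lagged("ricker", 0.4, 120, 150, 0, 12), "ricker", lags = 0)
  expect_equal(m1$r_m, f1$r_m, tolerance = 1e-9)
  expect_equal(m1$b, f1$b, tolerance = 1e-9)

  # data generated with dependence only at lag 2: that coefficient
  # dominates in standardised magnitude
  ts2 <- generate_density_series("ricker", 0.6, 150, n = 600, N0 = 40,
                                 noise_sd = 0.08, seed = 21)
  # rebuild with true lag-2 dependence via the oracle + noise
  ts2 <- withr::with_seed(22, {
    N <- numeric(600); N[1:3] <- c(40, 44, 48)
    for (t in 3:599)
      N[t + 1] <- N[t] * exp(0.6 * (1 - N[t - 2] / 150) +
                               rnorm(1, 0, 0.08))
    make_ts(N)
  })
  mfit <- multi_lag_fit(ts2, "ricker", lags = 0:4)
  expect_equal(unname(which.max(abs(mfit$std_coeffs))), 3L)  # lag 2
  expect_error(multi_lag_fit(ts2, "ricker", lags = c(0, 0, 1)),
               "duplicated")
})

test_that("lag-0 fitted models cannot reproduce persistent memory", {
  # fit on overdispersed trap-like counts, then simulate: the model's
  # short-lag partial autocorrelations are non-positive, unlike the
  # long positive memory of the observations it was fitted to
  obs <- generate_abundance(365 * 5, seed = 31)
  pos <- fill_gaps(obs, 0)
  fit <- fit_density_model(pos, "ricker", lag = 0)
  sim <- simulate_density_model(fit, 1500, N0 = max(fit$K, 10), seed = 32)
  p <- pacf_fn(sim, 20)
  expect_true(all(p$values[1:5] < p$ci))
  expect_lt(min(p$values[1:3]), 0)
})
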