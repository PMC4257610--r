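#' Generate synthetic daily weather forcing
#'
#' Emulates the structural features of mid-latitude station weather
#' that the downstream analyses rely on: an annual temperature sinusoid
#' (period 365.25 d) with AR(1) day-to-day noise, intermittent rainfall
#' as a wet/dry Bernoulli process with exponential wet-day depths, and
#' relative humidity elevated on wet days. No attempt is made to match
#' any particular station's climatology.
#'
#' @param n_days number of days, `>= 2`.
#' @param mean_temp annual mean temperature, degrees C.
#' @param annual_amplitude half-range of the annual cycle, degrees C.
#' @param temp_noise_sd marginal sd of the AR(1) temperature noise.
#' @param temp_noise_ar1 AR(1) coefficient, in `[0, 1)`.
#' @param rain_prob daily wet-day probability, in `[0, 1]`.
#' @param rain_mean mean wet-day depth, mm/day, `> 0`.
#' @param rh_base dry-day mean relative humidity, percent.
#' @param rh_rain_boost added humidity on wet days, percent.
#' @param start first calendar day.
#' @param seed integer seed; all randomness flows from it.
#' @return A [mosq_weather].
#' @export
generate_weather <- function(n_days,
                             mean_temp = 17, annual_amplitude = 9,
                             temp_noise_sd = 2.5, temp_noise_ar1 = 0.7,
                             rain_prob = 0.3, rain_mean = 8,
                             rh_base = 70, rh_rain_boost = 15,
                             start = as.Date("2004-01-01"),
                             seed = 1L) {
  if (n_days < 2) stop("n_days must be >= 2")
  if (rain_prob < 0 || rain_prob > 1) stop("rain_prob must lie in [0, 1]")
  if (rain_mean <= 0) stop("rain_mean must be > 0")
  if (temp_noise_ar1 < 0 || temp_noise_ar1 >= 1)
    stop("temp_noise_ar1 must lie in [0, 1)")
  withr::with_seed(seed, {
    t <- seq_len(n_days)
    # coldest around Jan 15, warmest mid-July
    doy0 <- as.numeric(start - as.Date("2004-01-15"))
    seasonal <- mean_temp -
      annual_amplitude * cos(2 * pi * (t - 1 + doy0) / 365.25)
    noise <- if (temp_noise_sd > 0) {
      as.numeric(stats::arima.sim(list(ar = temp_noise_ar1), n_days,
                                  sd = temp_noise_sd *
                                    sqrt(1 - temp_noise_ar1^2)))
    } else rep(0, n_days)
    temp <- seasonal + noise
    wet <- stats::rbinom(n_days, 1L, rain_prob)
    prcp <- wet * stats::rexp(n_days, rate = 1 / rain_mean)
    rh <- pmin(100, pmax(0,
      rh_base + rh_rain_boost * wet + stats::rnorm(n_days, 0, 5)))
    mosq_weather(start + t - 1, temp, prcp, rh)
  })
}

#' Generate a synthetic daily abundance series
#'
#' Emulates the statistical structure of daily adult trap counts: a
#' non-negative expectation built from a baseline plus superposed
#' sinusoidal components (annual and sub-annual periodicities), zeroed
#' inside a winter window, with strongly overdispersed day-to-day count
#' noise. Overdispersion is negative-binomial (mean/dispersion
#' parameterisation) because observed records show order-of-magnitude
#' swings between consecutive days that Poisson noise cannot produce.
#'
#' @param n_days number of days, `>= 2`.
#' @param periods numeric vector of component periods in days, all
#'   `>= 2` (shorter would be unresolvable at daily sampling).
#' @param amplitudes matching non-negative amplitudes (counts).
#' @param baseline mean count, `>= 0`.
#' @param dispersion negative-binomial size parameter, `> 0`; smaller
#'   means noisier. `Inf` gives Poisson noise.
#' @param winter_window integer day-of-year range `c(first, last)` with
#'   zero expectation (wraps over new year if first > last), or `NULL`.
#' @param start first calendar day.
#' @param seed integer seed.
#' @return A daily [mosq_ts] of counts.
#' @export
generate_abundance <- function(n_days,
                               periods = c(365.25, 70, 30),
                               amplitudes = c(40, 15, 10),
                               baseline = 30, dispersion = 0.8,
                               winter_window = c(335, 60),
                               start = as.Date("2004-01-01"),
                               seed = 1L) {
  if (n_days < 2) stop("n_days must be >= 2")
  if (length(periods) != length(amplitudes))
    stop("'periods' and 'amplitudes' must match")
  if (any(periods < 2))
    stop("all periods must be >= 2 days (daily Nyquist limit)")
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0")
  if (baseline < 0) stop("baseline must be >= 0")
  if (dispersion <= 0) stop("dispersion must be > 0")
  withr::with_seed(seed, {
    t <- seq_len(n_days)
    mu <- rep(baseline, n_days)
    for (k in seq_along(periods))
      mu <- mu + amplitudes[k] * sin(2 * pi * t / periods[k])
    mu <- pmax(mu, 0)
    if (!is.null(winter_window)) {
      doy <- as.integer(format(start + t - 1, "%j"))
      inwin <- if (winter_window[1] <= winter_window[2])
        doy >= winter_window[1] & doy <= winter_window[2]
      else
        doy >= winter_window[1] | doy <= winter_window[2]
      mu[inwin] <- 0
    }
    counts <- if (is.finite(dispersion))
      stats::rnbinom(n_days, size = dispersion, mu = mu)
    else stats::rpois(n_days, mu)
    counts[mu == 0] <- 0
    mosq_ts(start + t - 1, counts, 1, "synthetic")
  })
}

#' Iterate a density-dependent population recursion
#'
#' Generates a series from the Ricker map
#' `N[t+1] = N[t] * exp(r_m * (1 - N[t]/K))` or the Gompertz-logistic
#' map `N[t+1] = N[t] * exp(r_m * (1 - log(N[t]) / log(K)))`, with
#' optional multiplicative log-normal process noise. With
#' `noise_sd = 0` the recursion is exact, which is what the
#' parameter-recovery tests of [fit_density_model()] rely on.
#'
#' @param model `"ricker"` or `"gompertz"`.
#' @param r_m maximum per-capita growth rate (1/step).
#' @param K carrying capacity, `> 0`.
#' @param n series length.
#' @param N0 initial abundance, `> 0`.
#' @param noise_sd sd of Gaussian noise added to the log growth rate.
#' @param start first calendar day.
#' @param seed integer seed (ignored when `noise_sd = 0`).
#' @return A daily [mosq_ts].
#' @export
generate_density_series <- function(model = c("ricker", "gompertz"),
                                    r_m, K, n, N0 = K / 10,
                                    noise_sd = 0,
                                    start = as.Date("2004-01-01"),
                                    seed = 1L) {
  model <- match.arg(model)
  if (K <= 0) stop("K must be > 0")
  if (N0 <= 0) stop("N0 must be > 0")
  if (n < 2) stop("n must be >= 2")
  withr::with_seed(seed, {
    eps <- if (noise_sd > 0) stats::rnorm(n - 1, 0, noise_sd) else
      rep(0, n - 1)
    N <- numeric(n)
    N[1] <- N0
    for (t in seq_len(n - 1)) {
      g <- if (model == "ricker")
        r_m * (1 - N[t] / K)
      else
        r_m * (1 - log(N[t]) / log(K))
      N[t + 1] <- N[t] * exp(g + eps[t])
    }
    mosq_ts(start + seq_len(n) - 1, N, 1, paste0(model, "_synth"))
  })
}
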