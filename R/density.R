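#' Calibrate a density-dependent population model
#'
#' Fits the Ricker model `N[t+1] = N[t] exp(r_m (1 - N[t-lag]/K))` or
#' the Gompertz-logistic model
#' `N[t+1] = N[t] exp(r_m (1 - log(N[t-lag]) / log(K)))` by ordinary
#' least squares on the linearisation
#' `log(N[t+1]/N[t]) = a + b * D[t-lag] + sum_j c_j E_j[t]`,
#' where `D = N` (Ricker) or `D = log N` (Gompertz) and the `E_j` are
#' optional additive environmental covariates (modelling environmental
#' control of `r_m` and `K`). Back-transformation: `r_m = a`,
#' `K = -a/b` (Ricker) or `log K = -a/b` (Gompertz).
#'
#' Transitions involving a zero abundance (in `N[t]`, `N[t+1]`, or the
#' lagged density term) are excluded -- the linearisation needs logs of
#' positive counts -- and the number dropped is reported.
#'
#' @param ts a daily abundance [mosq_ts].
#' @param model `"ricker"` or `"gompertz"`.
#' @param lag density-dependence lag in days, 0 to 5.
#' @param covariates optional named list of aligned [mosq_ts]
#'   covariates (e.g. temperature, rainfall).
#' @return An object of class `"density_fit"`: list with `model`,
#'   `lag`, `r_m`, `K`, `covariate_coeffs`, `residual_sd` (log scale),
#'   `n_used`, `n_dropped_zero`, and the underlying `lm` fit in `$lm`.
#' @export
fit_density_model <- function(ts, model = c("ricker", "gompertz"),
                              lag = 0, covariates = NULL) {
  model <- match.arg(model)
  stopifnot_mosq_ts(ts)
  if (!lag %in% 0:5) stop("lag must lie in 0..5")
  X <- density_design(ts, model, lags = lag, covariates)
  if (X$n_used < 10 * (2 + length(covariates)))
    stop("only ", X$n_used, " usable transitions; need at least ",
         10 * (2 + length(covariates)))
  fit <- stats::lm(dlog ~ ., data = X$df)
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  K <- if (model == "ricker") -a / b else exp(-a / b)
  cov_coef <- stats::coef(fit)[-(1:2)]
  structure(list(model = model, lag = lag, r_m = a, K = K, b = b,
                 covariate_coeffs = cov_coef,
                 residual_sd = stats::sigma(fit),
                 n_used = X$n_used, n_dropped_zero = X$n_dropped,
                 lm = fit),
            class = "density_fit")
}

# shared design-matrix builder; lags may be a set for multi-lag fits
density_design <- function(ts, model, lags, covariates) {
  N <- ts$values
  if (anyNA(N)) stop("series has gaps; fill or split it first")
  n <- length(N)
  maxlag <- max(lags)
  t_idx <- (maxlag + 1):(n - 1)          # growth from t to t+1
  dlog <- suppressWarnings(log(N[t_idx + 1] / N[t_idx]))
  df <- data.frame(dlog = dlog)
  for (L in lags) {
    D <- N[t_idx - L]
    df[[paste0("density_lag", L)]] <-
      if (model == "ricker") D else suppressWarnings(log(D))
  }
  if (!is.null(covariates)) {
    if (is.null(names(covariates)) || any(!nzchar(names(covariates))))
      stop("covariates must be a named list")
    for (nm in names(covariates)) {
      cv <- covariates[[nm]]
      stopifnot_mosq_ts(cv)
      if (length(cv$values) != n)
        stop("covariate '", nm, "' is not aligned with the series")
      df[[nm]] <- cv$values[t_idx]
    }
  }
  ok <- stats::complete.cases(df) &
    apply(is.finite(as.matrix(df)), 1, all)
  n_dropped <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  dd <- df[, grep("^density_lag", names(df)), drop = FALSE]
  if (ncol(dd) > 1 && qr(as.matrix(dd))$rank < ncol(dd))
    stop("collinear density lag terms")
  list(df = df, n_used = nrow(df), n_dropped = n_dropped)
}

#' @export
print.density_fit <- function(x, ...) {
  cat("<density_fit> ", x$model, ", lag ",
      paste(x$lag, collapse = ","), ": r_m = ", signif(x$r_m, 4),
      ", K = ", signif(x$K, 4), ", residual sd = ",
      signif(x$residual_sd, 3), "\n", sep = "")
  cat("  transitions used: ", x$n_used, " (", x$n_dropped_zero,
      " dropped at zero abundance)\n", sep = "")
  if (length(x$covariate_coeffs)) {
    cat("  covariates:\n")
    print(signif(x$covariate_coeffs, 4))
  }
  invisible(x)
}

#' Simulate from a calibrated density-dependent model
#'
#' Iterates the fitted recursion forward with Gaussian process noise
#' of sd `residual_sd` added to the log growth rate (optionally with
#' covariate forcing). Used to compare the correlation structure of
#' canonical population models against observations.
#'
#' @param fit a `"density_fit"`.
#' @param n length of the simulated series.
#' @param N0 initial abundance, `> 0`.
#' @param covariates optional named list of [mosq_ts], names matching
#'   the fitted covariates, each of length `>= n`.
#' @param seed integer seed.
#' @param start first calendar day.
#' @return A daily [mosq_ts].
#' @export
simulate_density_model <- function(fit, n, N0 = fit$K,
                                   covariates = NULL, seed = 1L,
                                   start = as.Date("2004-01-01")) {
  if (N0 <= 0) stop("N0 must be > 0")
  lag <- max(fit$lag)
  cn <- names(fit$covariate_coeffs)
  if (length(cn) && (is.null(covariates) || !all(cn %in% names(covariates))))
    stop("fit uses covariates (", paste(cn, collapse = ", "),
         "); supply them")
  withr::with_seed(seed, {
    eps <- if (fit$residual_sd > 0) stats::rnorm(n, 0, fit$residual_sd)
      else rep(0, n)
    N <- numeric(n)
    N[seq_len(lag + 1)] <- N0
    for (t in (lag + 1):(n - 1)) {
      D <- if (fit$model == "ricker") N[t - fit$lag] else
        log(N[t - fit$lag])
      g <- fit$r_m + sum(fit$b * D)
      if (length(cn))
        for (nm in cn)
          g <- g + fit$covariate_coeffs[[nm]] *
            covariates[[nm]]$values[t]
      N[t + 1] <- N[t] * exp(g + eps[t])
    }
    mosq_ts(start + seq_len(n) - 1, N, 1,
            paste0(fit$model, "_lag", paste(fit$lag, collapse = "_"),
                   "_sim"))
  })
}

#' Multi-lag density-dependence fit
#'
#' Least squares with one density term per requested lag,
#' `log(N[t+1]/N[t]) = a + sum_L b_L D[t-L] + covariates`, reporting
#' per-lag coefficients and their standardised magnitudes. With a
#' single lag this reduces exactly to [fit_density_model()].
#'
#' @inheritParams fit_density_model
#' @param lags integer set within 0..5 (duplicates rejected).
#' @return A `"density_fit"` whose `lag` is the vector of lags, `b`
#'   the per-lag coefficient vector, and with an extra element
#'   `std_coeffs` (coefficients scaled by the sd of their regressor).
#' @export
multi_lag_fit <- function(ts, model = c("ricker", "gompertz"),
                          lags = 0:5, covariates = NULL) {
  model <- match.arg(model)
  if (anyDuplicated(lags)) stop("duplicated density lags")
  if (!all(lags %in% 0:5)) stop("lags must lie in 0..5")
  X <- density_design(ts, model, lags, covariates)
  if (X$n_used < 10 * (1 + length(lags) + length(covariates)))
    stop("only ", X$n_used, " usable transitions")
  fit <- stats::lm(dlog ~ ., data = X$df)
  co <- stats::coef(fit)
  a <- unname(co[1])
  bidx <- grep("^density_lag", names(co))
  b <- co[bidx]
  sds <- vapply(names(co)[bidx], function(nm) stats::sd(X$df[[nm]]),
                numeric(1))
  b_main <- b[which.max(abs(b * sds))]
  K <- if (model == "ricker") -a / sum(b) else exp(-a / sum(b))
  structure(list(model = model, lag = lags, r_m = a, K = K,
                 b = unname(b), std_coeffs = b * sds,
                 covariate_coeffs = co[-c(1, bidx)],
                 residual_sd = stats::sigma(fit),
                 n_used = X$n_used, n_dropped_zero = X$n_dropped,
                 lm = fit),
            class = "density_fit")
}
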