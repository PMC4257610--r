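#' Sample autocorrelation function
#'
#' Biased (1/n) sample autocorrelations of a gapless series, with the
#' large-sample white-noise 95% band `1.96 / sqrt(n)`. The biased
#' normalisation guarantees a positive-semidefinite ACF, which the
#' Durbin-Levinson recursion used by [pacf_fn()] requires.
#'
#' @param ts a gapless [mosq_ts] (or numeric vector).
#' @param max_lag largest lag in sampling steps; must be `< n/2`.
#' @return An object of class `"mosq_cf"`: list with `lags` (steps),
#'   `lag_days` (`lags * delta_t`), `values`, `ci` (band half-width),
#'   `kind = "ACF"`, `n`, `delta_t`.
#' @export
acf_fn <- function(ts, max_lag = 120) {
  v <- if (inherits(ts, "mosq_ts")) ts$values else as.numeric(ts)
  dt <- if (inherits(ts, "mosq_ts")) ts$delta_t else 1
  if (anyNA(v)) stop("series has gaps; fill or split it first")
  n <- length(v)
  if (max_lag >= n / 2)
    stop("max_lag = ", max_lag, " too large for n = ", n,
         " (must be < n/2)")
  a <- stats::acf(v, lag.max = max_lag, plot = FALSE, demean = TRUE)
  vals <- as.numeric(a$acf)
  vals[1] <- 1   # exact by definition; the C routine leaves an ulp
  structure(list(lags = 0:max_lag, lag_days = (0:max_lag) * dt,
                 values = vals, ci = 1.96 / sqrt(n),
                 kind = "ACF", n = n, delta_t = dt),
            class = "mosq_cf")
}

#' Sample partial autocorrelation function
#'
#' Partial autocorrelations obtained from the biased sample ACF via the
#' Durbin-Levinson recursion: the lag-k value is the correlation
#' between x_t and x_{t-k} after the indirect correlation carried by
#' the intermediate terms x_{t-1} .. x_{t-k+1} has been removed. Lag 1
#' equals the lag-1 autocorrelation by construction.
#'
#' @inheritParams acf_fn
#' @return A `"mosq_cf"` with `kind = "PACF"` and lags 1 .. `max_lag`.
#' @export
pacf_fn <- function(ts, max_lag = 120) {
  a <- acf_fn(ts, max_lag)
  rho <- a$values[-1]                    # rho[k], k = 1..max_lag
  phi <- durbin_levinson(rho)
  structure(list(lags = 1:max_lag, lag_days = (1:max_lag) * a$delta_t,
                 values = phi, ci = a$ci, kind = "PACF",
                 n = a$n, delta_t = a$delta_t),
            class = "mosq_cf")
}

# Durbin-Levinson: partial autocorrelations phi[k,k] from rho[1..L]
durbin_levinson <- function(rho) {
  L <- length(rho)
  pacf <- numeric(L)
  phi_prev <- numeric(0)
  for (k in seq_len(L)) {
    if (k == 1) {
      phi_kk <- rho[1]
      phi_prev <- phi_kk
    } else {
      num <- rho[k] - sum(phi_prev * rho[(k - 1):1])
      den <- 1 - sum(phi_prev * rho[1:(k - 1)])
      phi_kk <- num / den
      phi_prev <- c(phi_prev - phi_kk * rev(phi_prev), phi_kk)
    }
    pacf[k] <- phi_kk
  }
  pacf
}

#' @export
print.mosq_cf <- function(x, ...) {
  cat("<mosq_cf> ", x$kind, ", ", length(x$lags), " lags (delta_t = ",
      x$delta_t, " d), n = ", x$n,
      ", 95% band +/- ", signif(x$ci, 3), "\n", sep = "")
  cat("  positive-significance run: ",
      significant_positive_run(x), " days\n", sep = "")
  invisible(x)
}

#' Plot a correlogram with its confidence band
#' @param x a `"mosq_cf"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mosq_cf <- function(x, ...) {
  graphics::plot(x$lag_days, x$values, type = "h",
                 xlab = "lag (days)", ylab = x$kind,
                 ylim = range(c(x$values, x$ci, -x$ci)), ...)
  graphics::abline(h = c(-x$ci, 0, x$ci), lty = c(2, 1, 2),
                   col = c("blue", "black", "blue"))
  invisible(x)
}

#' Split a daily series into the 7 weekly subsampling designs
#'
#' Degrades a daily record to the weekly sampling common in trap
#' studies: returns the 7 series "collected" on each day of the week,
#' each with `delta_t = 7` days and labelled by its weekday. Together
#' the subsamples partition the original values.
#'
#' @param ts a daily [mosq_ts] of length `>= 14`.
#' @return A named list of 7 [mosq_ts] (names are weekdays).
#' @export
weekly_subsample <- function(ts) {
  stopifnot_mosq_ts(ts)
  if (ts$delta_t != 1) stop("weekly_subsample needs a daily series")
  n <- length(ts$values)
  if (n < 14) stop("need at least 14 days")
  out <- vector("list", 7)
  nms <- character(7)
  for (off in 0:6) {
    idx <- seq(1 + off, n, by = 7)
    day <- weekdays(ts$dates[1 + off])
    nms[off + 1] <- day
    out[[off + 1]] <- mosq_ts(ts$dates[idx], ts$values[idx],
                              delta_t = 7,
                              label = paste0(ts$label, " [", day, "]"))
  }
  names(out) <- nms
  out
}

#' Length of the initial run of significant positive correlation
#'
#' The largest lag L such that the correlation at every lag 1 .. L
#' exceeds the +95% band; 0 if lag 1 is already not significant.
#' Reported in days (`L * delta_t`), which makes daily and weekly
#' correlograms directly comparable ("memory" in calendar time).
#'
#' @param cf a `"mosq_cf"`.
#' @return Run length in days.
#' @export
significant_positive_run <- function(cf) {
  pos <- seq_along(cf$lags)[cf$lags >= 1]
  above <- cf$values[pos] > cf$ci
  if (!length(above) || !above[1]) return(0)
  first_break <- which(!above)
  L <- if (length(first_break)) first_break[1] - 1 else length(above)
  L * cf$delta_t
}

#' Export a correlogram as delimited text
#' @param cf a `"mosq_cf"`.
#' @param path output path.
#' @export
write_correlogram <- function(cf, path) {
  utils::write.csv(data.frame(lag_days = cf$lag_days,
                              value = cf$values, ci = cf$ci),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
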