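#' Shortest resolvable period at a given sampling interval
#'
#' By the Nyquist sampling theorem a process sampled every `delta_t`
#' days can only resolve oscillations of period `2 * delta_t` or
#' longer: weekly trapping (delta_t = 7) cannot see anything faster
#' than 2 weeks, daily trapping resolves down to 2 days.
#'
#' @param delta_t sampling interval in days, `> 0`.
#' @return `2 * delta_t`, in days.
#' @examples
#' nyquist_period(7)  # 14
#' @export
nyquist_period <- function(delta_t) {
  if (!is.numeric(delta_t) || delta_t <= 0)
    stop("delta_t must be > 0")
  2 * delta_t
}

#' Discrete Fourier power spectrum on the period grid
#'
#' Decomposes a uniformly sampled series of length N into sinusoids of
#' period `T_i = N * delta_t / i`, i = 1 .. N/2, and reports the
#' squared oscillation amplitude of each component. The normalisation
#' is chosen so that a sinusoid of amplitude A occupying a single
#' frequency bin has power exactly A^2 at that bin (power =
#' `(2/N)^2 |X_i|^2`). Under this convention the biased sample
#' variance of the series equals `sum(power)/2`, with the Nyquist bin
#' (even N) contributing `power/4` — see [spectrum_variance()].
#'
#' @param ts a gapless [mosq_ts] of length `>= 4` (or numeric vector).
#' @param detrend `"mean"` (default) removes the series mean so the
#'   zero-frequency component carries no power; `"none"` leaves the
#'   series untouched (the i = 0 bin is excluded either way).
#' @param log1p_transform analyse `log(1 + N)` instead of raw counts.
#'   Off by default; when on, the output is flagged in `$transform`.
#' @param taper `"none"` (default, plain DFT) or `"hann"`.
#' @return An object of class `"mosq_spectrum"`: list with `periods`
#'   (days, strictly decreasing from `N*delta_t` to `2*delta_t`),
#'   `power` (amplitude^2), `n`, `delta_t`, `transform`, `taper`.
#' @examples
#' x <- sin(2 * pi * (1:120) / 30)
#' sp <- power_spectrum(mosq_ts(as.Date("2004-01-01") + 0:119, x))
#' sp$periods[which.max(sp$power)]  # 30
#' @export
power_spectrum <- function(ts, detrend = c("mean", "none"),
                           log1p_transform = FALSE,
                           taper = c("none", "hann")) {
  detrend <- match.arg(detrend)
  taper <- match.arg(taper)
  if (inherits(ts, "mosq_ts")) {
    x <- ts$values
    delta_t <- ts$delta_t
  } else {
    x <- as.numeric(ts)
    delta_t <- 1
  }
  if (anyNA(x))
    stop("series has gaps; fill_gaps() short holes or split the series")
  n <- length(x)
  if (n < 4) stop("need at least 4 observations")
  if (log1p_transform) x <- log1p(x)
  if (detrend == "mean") x <- x - mean(x)
  if (taper == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
    x <- x * w / sqrt(mean(w^2))   # preserve average power
  }
  X <- stats::fft(x)
  i <- seq_len(floor(n / 2))
  power <- (2 / n)^2 * Mod(X[i + 1])^2
  structure(list(periods = n * delta_t / i, power = power,
                 n = n, delta_t = delta_t,
                 transform = if (log1p_transform) "log1p" else "none",
                 taper = taper),
            class = "mosq_spectrum")
}

#' @export
print.mosq_spectrum <- function(x, ...) {
  cat("<mosq_spectrum> n = ", x$n, ", delta_t = ", x$delta_t,
      " d, periods ", format(max(x$periods)), " .. ",
      format(min(x$periods)), " d\n", sep = "")
  pk <- find_peaks(x, k = 3)
  if (nrow(pk)) {
    cat("  top peaks (period d, power):\n")
    for (j in seq_len(nrow(pk)))
      cat(sprintf("   %8.1f  %12.4g\n", pk$period[j], pk$power[j]))
  }
  invisible(x)
}

#' Series variance implied by a spectrum
#'
#' Sums component powers under the package normalisation back to the
#' biased (1/n) sample variance of the mean-removed series; used as a
#' Parseval consistency check.
#'
#' @param spec a `mosq_spectrum` computed with `detrend = "mean"`.
#' @return The implied variance.
#' @export
spectrum_variance <- function(spec) {
  w <- rep(0.5, length(spec$power))
  if (spec$n %% 2 == 0) w[length(w)] <- 0.25   # Nyquist bin, even n
  sum(spec$power * w)
}

#' Locate dominant spectral peaks
#'
#' Finds local maxima of the (optionally smoothed) power spectrum,
#' ranked by power. Raw periodograms of noisy series are jagged, so a
#' 3-bin moving-average smoothing is applied before the local-maximum
#' search by default; the width is configurable. The zero-frequency
#' (infinite period) component is never a candidate. Ties are broken
#' toward the longer period.
#'
#' @param spec a `mosq_spectrum`.
#' @param k number of peaks to return, `>= 1`.
#' @param band period interval `c(min, max)` in days to search within
#'   (default the full resolvable range `[2*delta_t, n*delta_t]`).
#' @param smooth odd smoothing width in bins; 1 disables smoothing.
#' @return A data frame of class `"mosq_peaks"` with columns `period`
#'   (days), `power` (of the smoothed spectrum), `rank`.
#' @export
find_peaks <- function(spec, k = 3, band = NULL, smooth = 3) {
  if (k < 1) stop("k must be >= 1")
  if (smooth < 1 || smooth %% 2 != 1)
    stop("smooth must be an odd positive width")
  p <- spec$power
  np <- length(p)
  if (smooth > 1) {
    half <- (smooth - 1) / 2
    p <- as.numeric(stats::filter(p, rep(1 / smooth, smooth),
                                  sides = 2))
    # partial windows at the ends instead of NA
    for (j in seq_len(half)) {
      p[j] <- mean(spec$power[1:(j + half)])
      p[np - j + 1] <- mean(spec$power[(np - j + 1 - half):np])
    }
  }
  if (is.null(band)) band <- c(2 * spec$delta_t, spec$n * spec$delta_t)
  sel <- spec$periods >= band[1] & spec$periods <= band[2]
  if (!any(sel)) stop("empty period band [", band[1], ", ", band[2], "]")
  idx <- which(sel)
  is_peak <- vapply(idx, function(j) {
    left <- if (j > 1) p[j - 1] else -Inf
    right <- if (j < np) p[j + 1] else -Inf
    p[j] > left && p[j] > right
  }, logical(1))
  cand <- idx[is_peak]
  if (!length(cand)) {
    # a monotone band has no interior maximum; fall back to the largest bin
    cand <- idx[which.max(p[idx])]
  }
  # rank by power; ties toward longer period (smaller index i)
  cand <- cand[order(-p[cand], cand)]
  cand <- cand[seq_len(min(k, length(cand)))]
  out <- data.frame(period = spec$periods[cand], power = p[cand],
                    rank = seq_along(cand))
  class(out) <- c("mosq_peaks", "data.frame")
  out
}

#' Dominant period within a band
#'
#' Convenience wrapper: the period of the rank-1 peak of
#' [find_peaks()] restricted to `band`.
#' @inheritParams find_peaks
#' @return Period in days.
#' @export
dominant_period <- function(spec, band = NULL, smooth = 3) {
  find_peaks(spec, k = 1, band = band, smooth = smooth)$period[1]
}

#' Export a spectrum as delimited text
#' @param spec a `mosq_spectrum`.
#' @param path output path.
#' @export
write_spectrum <- function(spec, path) {
  utils::write.csv(data.frame(period_days = spec$periods,
                              power = spec$power),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot a power spectrum on a log period axis
#' @param x a `mosq_spectrum`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mosq_spectrum <- function(x, ...) {
  graphics::plot(x$periods, x$power, type = "l", log = "x",
                 xlab = "period (days)",
                 ylab = expression(S(T) ~ (amplitude^2)), ...)
  invisible(x)
}
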