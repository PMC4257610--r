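#' Activity ratio of an abundance series
#'
#' The ratio of the day's count to the maximum count in a moving
#' 31-day window around it. The window maximum proxies the fraction of
#' the underlying population that is trappable under the most
#' favourable conditions of a relatively homogeneous period, so the
#' ratio estimates the day's active fraction. Windows whose maximum is
#' 0 (deep winter) give an undefined ratio (`NA`), excluded from
#' binning downstream.
#'
#' @param abundance a daily [mosq_ts].
#' @param window window length in days; odd, `>= 3` (default 31).
#' @param align `"center"` (default) or `"right"` (trailing window).
#' @return A daily [mosq_ts] of ratios in `[0, 1]` (with `NA` where
#'   undefined, including the partial windows at the series edges for
#'   the centered alignment).
#' @export
activity_ratio_series <- function(abundance, window = 31,
                                  align = c("center", "right")) {
  align <- match.arg(align)
  stopifnot_mosq_ts(abundance)
  if (abundance$delta_t != 1)
    stop("activity_ratio_series needs a daily series")
  if (window < 3 || window %% 2 != 1)
    stop("window must be odd and >= 3")
  v <- abundance$values
  mx <- zoo::rollapply(v, window, max, fill = NA, align = align,
                       na.rm = TRUE)
  ratio <- ifelse(is.na(mx) | mx == 0, NA_real_, v / mx)
  mosq_ts(abundance$dates, ratio, 1,
          paste(abundance$label, "activity ratio"))
}

#' Median activity ratio by rainfall intensity
#'
#' Bins days by current-day rainfall intensity and reports the median
#' activity ratio per bin -- the empirical rainfall-activity curve.
#' Undefined ratios are excluded; empty bins are flagged by
#' `n_days = 0` and `NA` medians.
#'
#' @param ratios activity-ratio [mosq_ts] from
#'   [activity_ratio_series()].
#' @param precipitation daily precipitation [mosq_ts] (mm/day) on the
#'   same calendar.
#' @param bin_edges increasing vector of interior bin edges in mm/day;
#'   bins partition `[0, Inf)` as `[0, e1), [e1, e2), ..., [ek, Inf)`.
#' @return A data frame of class `"activity_curve"` with columns
#'   `bin_low`, `bin_high`, `median_ratio`, `n_days`.
#' @export
bin_by_rainfall <- function(ratios, precipitation,
                            bin_edges = c(0.5, 1, 2, 5, 10, 20)) {
  stopifnot_mosq_ts(ratios)
  stopifnot_mosq_ts(precipitation)
  if (!identical(ratios$dates, precipitation$dates))
    stop("ratio and precipitation series are not aligned")
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  edges <- c(0, bin_edges, Inf)
  ok <- !is.na(ratios$values)
  bin <- cut(precipitation$values[ok], edges, right = FALSE,
             include.lowest = TRUE)
  med <- tapply(ratios$values[ok], bin, stats::median)
  n <- tapply(ratios$values[ok], bin, length)
  out <- data.frame(bin_low = edges[-length(edges)],
                    bin_high = edges[-1],
                    median_ratio = as.numeric(med),
                    n_days = ifelse(is.na(n), 0L, as.integer(n)))
  class(out) <- c("activity_curve", "data.frame")
  out
}

#' Parametric rainfall-activity function
#'
#' A unimodal (hump-shaped) response of the active adult fraction to
#' current-day rainfall: activity rises with rainfall at low
#' intensities (humid air, oviposition opportunity) and falls steeply
#' above an optimum (heavy rain suppresses flight). The form is
#' piecewise log-linear,
#' `a(p) = floor + (1 - floor) * exp(-rise * (opt - p))` below the
#' optimum and `... * exp(-fall * (p - opt))` above it, bounded in
#' `[floor, 1]` with its maximum 1 at `opt`.
#'
#' @param precip precipitation, mm/day, `>= 0` (vectorised).
#' @param rise rate of increase below the optimum (1/(mm/day)), `> 0`.
#' @param opt optimum rainfall intensity, mm/day.
#' @param fall rate of decrease above the optimum, `> 0`; steep by
#'   default.
#' @param floor lower bound of the activity fraction, in `[0, 1)`.
#' @return Activity fractions in `[floor, 1]`.
#' @examples
#' parametric_activity(c(0, 2, 6, 20))
#' @export
parametric_activity <- function(precip, rise = 0.35, opt = 2,
                                fall = 0.25, floor = 0.05) {
  if (any(precip < 0)) stop("precip must be >= 0")
  if (rise <= 0 || fall <= 0) stop("rise and fall rates must be > 0")
  if (floor < 0 || floor >= 1) stop("floor must lie in [0, 1)")
  g <- ifelse(precip <= opt,
              exp(-rise * (opt - precip)),
              exp(-fall * (precip - opt)))
  floor + (1 - floor) * g
}

#' Export an activity curve as delimited text
#' @param curve an `"activity_curve"` from [bin_by_rainfall()].
#' @param path output path.
#' @export
write_activity_curve <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot an empirical rainfall-activity curve
#' @param x an `"activity_curve"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.activity_curve <- function(x, ...) {
  mid <- ifelse(is.finite(x$bin_high), (x$bin_low + x$bin_high) / 2,
                x$bin_low * 1.5)
  graphics::plot(mid, x$median_ratio, type = "b",
                 xlab = "rainfall intensity (mm/day)",
                 ylab = "median activity ratio", ylim = c(0, 1), ...)
  invisible(x)
}
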