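#' Daily (or subsampled) time series
#'
#' The common currency of all analyses in \pkg{mosquitodyn}: a uniformly
#' sampled series of values on a calendar of days. The sampling interval
#' `delta_t` is 1 day for raw trap records and 7 days for weekly
#' subsamples; it sets the Nyquist period `2 * delta_t` of any spectral
#' or correlation analysis of the series.
#'
#' @param dates vector of `Date`s, strictly increasing and equally
#'   spaced by `delta_t` days.
#' @param values numeric vector, same length as `dates`. `NA` marks a
#'   missing observation (a gap); see [fill_gaps()].
#' @param delta_t sampling interval in days (default 1).
#' @param label free-text label (species or variable name).
#'
#' @return An object of class `"mosq_ts"`: a list with elements
#'   `dates`, `values`, `delta_t`, `label`.
#' @examples
#' ts <- mosq_ts(as.Date("2010-01-01") + 0:9, rpois(10, 5), label = "demo")
#' length(ts$values)
#' @export
mosq_ts <- function(dates, values, delta_t = 1, label = "") {
  dates <- as.Date(dates)
  values <- as.numeric(values)
  if (length(dates) != length(values))
    stop("'dates' and 'values' must have the same length")
  if (length(dates) < 2)
    stop("a mosq_ts needs at least 2 observations")
  if (anyDuplicated(dates))
    stop("duplicated dates in series")
  d <- as.numeric(diff(dates))
  if (any(d != delta_t))
    stop("dates must be equally spaced by delta_t = ", delta_t,
         " days (first violation at position ",
         which(d != delta_t)[1] + 1L, ")")
  structure(list(dates = dates, values = values,
                 delta_t = delta_t, label = as.character(label)),
            class = "mosq_ts")
}

#' @export
print.mosq_ts <- function(x, ...) {
  cat("<mosq_ts> ", if (nzchar(x$label)) paste0("'", x$label, "' ") else "",
      length(x$values), " obs, delta_t = ", x$delta_t, " d, ",
      format(x$dates[1]), " .. ", format(x$dates[length(x$dates)]), "\n",
      sep = "")
  n_na <- sum(is.na(x$values))
  if (n_na > 0) cat("  ", n_na, " missing value(s)\n", sep = "")
  invisible(x)
}

#' @export
length.mosq_ts <- function(x) length(x$values)

#' @export
as.data.frame.mosq_ts <- function(x, ...) {
  data.frame(date = x$dates, value = x$values)
}

is_daily <- function(ts) inherits(ts, "mosq_ts") && ts$delta_t == 1

stopifnot_mosq_ts <- function(ts) {
  if (!inherits(ts, "mosq_ts"))
    stop("expected a 'mosq_ts' object; got ", class(ts)[1])
  invisible(ts)
}

#' Aligned daily weather forcing
#'
#' Bundles the daily meteorological drivers of the life-cycle simulator:
#' mean temperature, precipitation depth, relative humidity, and
#' (optionally) dew point and wind speed, all on one contiguous daily
#' calendar.
#'
#' @param dates contiguous daily `Date` vector.
#' @param temperature daily mean air temperature, degrees C.
#' @param precipitation daily precipitation depth, mm/day, `>= 0`.
#' @param relative_humidity daily mean relative humidity, percent in
#'   `[0, 100]`. Optional (`NULL`).
#' @param dew_point,wind_speed optional, degrees C and m/s.
#'
#' @return An object of class `"mosq_weather"`.
#' @export
mosq_weather <- function(dates, temperature, precipitation,
                         relative_humidity = NULL,
                         dew_point = NULL, wind_speed = NULL) {
  dates <- as.Date(dates)
  n <- length(dates)
  if (n < 2) stop("weather series needs at least 2 days")
  if (any(as.numeric(diff(dates)) != 1))
    stop("weather dates must form a contiguous daily calendar")
  chk_len <- function(v, nm) {
    if (!is.null(v) && length(v) != n)
      stop("'", nm, "' must have length ", n)
    if (is.null(v)) NULL else as.numeric(v)
  }
  temperature <- chk_len(temperature, "temperature")
  precipitation <- chk_len(precipitation, "precipitation")
  relative_humidity <- chk_len(relative_humidity, "relative_humidity")
  if (any(precipitation < 0, na.rm = TRUE))
    stop("precipitation must be >= 0 mm/day")
  if (!is.null(relative_humidity) &&
      any(relative_humidity < 0 | relative_humidity > 100, na.rm = TRUE))
    stop("relative_humidity must lie in [0, 100]")
  structure(list(dates = dates,
                 temperature = temperature,
                 precipitation = precipitation,
                 relative_humidity = relative_humidity,
                 dew_point = chk_len(dew_point, "dew_point"),
                 wind_speed = chk_len(wind_speed, "wind_speed")),
            class = "mosq_weather")
}

#' @export
print.mosq_weather <- function(x, ...) {
  cat("<mosq_weather> ", length(x$dates), " days, ",
      format(x$dates[1]), " .. ", format(x$dates[length(x$dates)]), "\n",
      sep = "")
  opt <- c("relative_humidity", "dew_point", "wind_speed")
  have <- opt[!vapply(x[opt], is.null, logical(1))]
  cat("  fields: temperature, precipitation",
      if (length(have)) paste0(", ", paste(have, collapse = ", ")), "\n",
      sep = "")
  invisible(x)
}

#' @export
length.mosq_weather <- function(x) length(x$dates)
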