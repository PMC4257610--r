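#' Read a daily abundance table
#'
#' Reads trap-count tables laid out as one row per day with an ISO-8601
#' date column and one integer column per species, and extracts a single
#' species as a [mosq_ts]. Missing days inside the record are kept as
#' `NA` (flagged, never silently filled); use [fill_gaps()] or split the
#' series before spectral analysis.
#'
#' @param path path to a delimited text file.
#' @param species name of the species column to extract.
#' @param date_col name of the date column (default `"date"`).
#' @param sep field separator (default `","`).
#' @return A daily [mosq_ts] of non-negative counts (possibly with `NA`
#'   for days absent from the file).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(date = as.Date("2010-06-01") + 0:4,
#'                      Ae.vexans = c(3, 10, 2, 0, 5)), f, row.names = FALSE)
#' read_abundance(f, "Ae.vexans")
#' @export
read_abundance <- function(path, species, date_col = "date", sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!date_col %in% names(df))
    stop("date column '", date_col, "' not found in ", path)
  avail <- setdiff(names(df), date_col)
  if (!species %in% avail)
    stop("unknown species '", species, "'; available: ",
         paste(avail, collapse = ", "))
  dates <- as.Date(df[[date_col]])
  if (anyNA(dates)) stop("unparseable dates in ", path)
  if (anyDuplicated(dates)) stop("duplicated dates in ", path)
  o <- order(dates)
  dates <- dates[o]
  vals <- as.numeric(df[[species]])[o]
  if (any(vals < 0, na.rm = TRUE)) stop("negative counts for ", species)
  # expand to the full daily calendar; absent days become NA gaps
  full <- seq(dates[1], dates[length(dates)], by = "day")
  out <- rep(NA_real_, length(full))
  out[match(dates, full)] <- vals
  n_gap <- sum(is.na(out))
  if (n_gap > 0)
    message("read_abundance: ", n_gap, " missing day(s) flagged as NA")
  mosq_ts(full, out, delta_t = 1, label = species)
}

#' Write an abundance table
#'
#' Inverse of [read_abundance()]: writes one or more aligned daily
#' series as a date + one-column-per-species CSV, the same dialect
#' [read_abundance()] reads, so synthetic fixtures exercise the real
#' I/O path.
#'
#' @param ts_list a [mosq_ts] or a list of them sharing one calendar.
#' @param path output file path.
#' @export
write_abundance <- function(ts_list, path) {
  if (inherits(ts_list, "mosq_ts")) ts_list <- list(ts_list)
  dates <- ts_list[[1]]$dates
  df <- data.frame(date = format(dates, "%Y-%m-%d"))
  for (ts in ts_list) {
    stopifnot_mosq_ts(ts)
    if (!identical(ts$dates, dates))
      stop("all series must share the same calendar")
    nm <- if (nzchar(ts$label)) ts$label else
      paste0("V", length(df))
    df[[nm]] <- ts$values
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a daily weather export
#'
#' Reads NCDC-style daily station exports. Column names and unit codes
#' vary between exports, so the mapping is declared through a dialect
#' list rather than guessed. Gaps in any field are linearly interpolated
#' up to `max_gap` days (weather is smooth at that scale); longer gaps
#' are an error. A gap report is emitted via `message()`.
#'
#' @param path delimited text file with at least date, temperature and
#'   precipitation columns.
#' @param dialect named list mapping internal names to file columns and
#'   declaring units: elements `date`, `temperature`, `precipitation`
#'   (mandatory), `relative_humidity`, `dew_point`, `wind_speed`
#'   (optional), `temp_unit` (`"C"` or `"tenths_C"`), `precip_unit`
#'   (`"mm"` or `"tenths_mm"`), `sep`.
#' @param max_gap longest run of missing days to interpolate (default 7).
#' @return A [mosq_weather] on a contiguous daily calendar, with an
#'   attribute `"gap_report"`: a data frame of the gaps found
#'   (field, start, end, length).
#' @export
read_weather <- function(path, dialect = list(), max_gap = 7) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::modifyList(list(
    date = "date", temperature = "temperature",
    precipitation = "precipitation",
    relative_humidity = "relative_humidity",
    dew_point = "dew_point", wind_speed = "wind_speed",
    temp_unit = "C", precip_unit = "mm", sep = ","), dialect)
  df <- utils::read.table(path, header = TRUE, sep = d$sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  for (mand in c("date", "temperature", "precipitation"))
    if (!d[[mand]] %in% names(df))
      stop("mandatory column '", d[[mand]], "' (", mand,
           ") missing from ", path)
  dates <- as.Date(df[[d$date]])
  o <- order(dates)
  dates <- dates[o]
  if (anyDuplicated(dates)) stop("duplicated dates in ", path)
  full <- seq(dates[1], dates[length(dates)], by = "day")
  idx <- match(dates, full)

  get_field <- function(nm) {
    col <- d[[nm]]
    if (!col %in% names(df)) return(NULL)
    v <- rep(NA_real_, length(full))
    v[idx] <- as.numeric(df[[col]])[o]
    v
  }
  temp <- get_field("temperature")
  prcp <- get_field("precipitation")
  if (d$temp_unit == "tenths_C") temp <- temp / 10
  if (d$precip_unit == "tenths_mm") prcp <- prcp / 10
  rh <- get_field("relative_humidity")
  dew <- get_field("dew_point")
  wind <- get_field("wind_speed")

  gaps <- list()
  fill_field <- function(v, nm) {
    if (is.null(v) || !anyNA(v)) return(v)
    r <- rle(is.na(v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      gaps[[length(gaps) + 1L]] <<- data.frame(
        field = nm, start = full[starts[j]], end = full[ends[j]],
        length = r$lengths[j])
      if (r$lengths[j] > max_gap)
        stop("gap of ", r$lengths[j], " days in '", nm, "' (",
             format(full[starts[j]]), " .. ", format(full[ends[j]]),
             ") exceeds max_gap = ", max_gap)
    }
    zoo::na.approx(v, na.rm = FALSE, rule = 2)
  }
  temp <- fill_field(temp, "temperature")
  prcp <- pmax(fill_field(prcp, "precipitation"), 0)
  rh <- fill_field(rh, "relative_humidity")
  dew <- fill_field(dew, "dew_point")
  wind <- fill_field(wind, "wind_speed")

  report <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(field = character(), start = as.Date(character()),
               end = as.Date(character()), length = integer())
  if (nrow(report))
    message("read_weather: interpolated ", nrow(report),
            " gap(s), longest ", max(report$length), " day(s)")
  w <- mosq_weather(full, temp, prcp, rh, dew, wind)
  attr(w, "gap_report") <- report
  w
}

#' Write a weather table in the dialect read_weather() reads
#' @param weather a [mosq_weather].
#' @param path output file path.
#' @export
write_weather <- function(weather, path) {
  df <- data.frame(date = format(weather$dates, "%Y-%m-%d"),
                   temperature = weather$temperature,
                   precipitation = weather$precipitation)
  for (nm in c("relative_humidity", "dew_point", "wind_speed"))
    if (!is.null(weather[[nm]])) df[[nm]] <- weather[[nm]]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Interpolate short gaps in a series
#'
#' Fills runs of `NA` of length at most `max_gap` by linear
#' interpolation between the flanking observations. Longer gaps are an
#' error: they should split the series rather than be bridged, because
#' interpolation over long spans injects spurious low-frequency power
#' into spectra. Observed values are never altered.
#'
#' @param ts a [mosq_ts].
#' @param max_gap longest gap (days) to interpolate; `>= 0`.
#' @return A gapless [mosq_ts].
#' @export
fill_gaps <- function(ts, max_gap) {
  stopifnot_mosq_ts(ts)
  if (max_gap < 0) stop("max_gap must be >= 0")
  v <- ts$values
  if (!anyNA(v)) return(ts)
  if (is.na(v[1]) || is.na(v[length(v)]))
    stop("series starts or ends with a gap; trim it first")
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bad <- which(r$values & r$lengths > max_gap)
  if (length(bad))
    stop("gap of ", r$lengths[bad[1]], " days (",
         format(ts$dates[starts[bad[1]]]), " .. ",
         format(ts$dates[ends[bad[1]]]),
         ") exceeds max_gap = ", max_gap)
  out <- zoo::na.approx(v)
  mosq_ts(ts$dates, out, ts$delta_t, ts$label)
}

#' Trailing moving average
#'
#' Causal mean over the `window` days ending at each day: the value at
#' day t averages days t-window+1 .. t, so that development or survival
#' on day t never depends on future weather. The first `window - 1` days
#' use the partial window available, so a simulation can start on day 1.
#'
#' @param x a [mosq_ts] or plain numeric vector.
#' @param window averaging window in observations, `>= 1`.
#' @return Same type as `x`.
#' @examples
#' moving_average(1:10, 10)[10]  # mean(1:10) = 5.5
#' @export
moving_average <- function(x, window) {
  if (window < 1) stop("window must be >= 1")
  window <- as.integer(window)
  vals <- if (inherits(x, "mosq_ts")) x$values else as.numeric(x)
  if (anyNA(vals)) stop("moving_average needs a gapless series")
  cs <- cumsum(vals)
  n <- length(vals)
  out <- numeric(n)
  head_n <- seq_len(min(window, n))
  out[head_n] <- cs[head_n] / head_n          # partial start-up window
  if (n > window) {
    i <- (window + 1L):n
    out[i] <- (cs[i] - cs[i - window]) / window
  }
  if (inherits(x, "mosq_ts"))
    mosq_ts(x$dates, out, x$delta_t, x$label)
  else out
}
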