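# Core domain types and deterministic covariate engineering.
#
# AdmissionSeries and CovariateSeries are plain data.frames carrying a class
# attribute, one row per calendar day on a gap-free daily grid (days with no
# observation carry NA counts, never silently dropped).

#' Population-normalised admission rate
#'
#' Converts a raw daily admission count to the rate per 100,000 population,
#' the response scale used throughout the package.
#'
#' @param count non-negative integer vector of daily admissions
#'   (00:00--23:59).
#' @param population positive population denominator (recycled).
#' @return numeric vector, admissions per 100,000 population.
#' @export
#' @examples
#' normalise_admissions(543, 100e6)  # 0.543
normalise_admissions <- function(count, population) {
  if (!is_count(count)) stopf("'count' must be non-negative integers")
  if (!is.numeric(population) || any(!is.finite(population)) ||
      any(population <= 0))
    stopf("'population' must be positive")
  count / population * 1e5
}

#' Daily admission series
#'
#' Builds an admission series on a strictly daily grid. Missing days inside
#' the date range are inserted with `NA` count (explicit gap markers).
#'
#' @param date `Date` vector, strictly increasing.
#' @param count non-negative integer admissions per day.
#' @param population positive population per day (scalar or vector).
#' @return a data.frame of class `"admission_series"` with columns `date`,
#'   `count`, `population` and `rate` (per 100,000).
#' @export
admission_series <- function(date, count, population) {
  stopifnot(inherits(date, "Date"))
  if (any(diff(as.integer(date)) <= 0)) stopf("dates must be strictly increasing")
  ok <- !is.na(count)
  if (!is_count(count[ok])) stopf("'count' must be non-negative integers")
  if (any(!is.finite(population) | population <= 0))
    stopf("'population' must be positive")
  population <- rep_len(population, length(date))
  grid <- seq(min(date), max(date), by = "day")
  i <- match(grid, date)
  out <- data.frame(date = grid, count = count[i], population = population[i])
  # carry population across gap days so the grid stays usable
  if (anyNA(out$population)) {
    filled <- out$population
    for (j in seq_along(filled)) if (is.na(filled[j]) && j > 1) filled[j] <- filled[j - 1]
    out$population <- filled
  }
  out$rate <- ifelse(is.na(out$count), NA_real_,
                     out$count / out$population * 1e5)
  class(out) <- c("admission_series", "data.frame")
  out
}

#' Decompose wind speed and direction into east-west / north-south components
#'
#' Uses the meteorological "direction the wind blows from" convention:
#' `EW = -WS * sin(WD)`, `NS = -WS * cos(WD)` with `WD` in degrees clockwise
#' from North. Positive `EW` means winds from the west; positive `NS` means
#' winds from the south.
#'
#' @param ws wind speed (km/h), non-negative.
#' @param wd wind direction in degrees, in `[0, 360]`.
#' @return data.frame with columns `EW` and `NS` (km/h).
#' @export
#' @examples
#' decompose_wind(28, 360)  # calm northerly: EW 0, NS -28
decompose_wind <- function(ws, wd) {
  if (any(!is.finite(ws)) || any(ws < 0)) stopf("'ws' must be non-negative")
  if (any(!is.finite(wd)) || any(wd < 0 | wd > 360))
    stopf("'wd' must lie in [0, 360] degrees")
  th <- wd * pi / 180
  data.frame(EW = -ws * sin(th), NS = -ws * cos(th))
}

#' Backward-looking rolling mean and deviation
#'
#' For each day i the rolling mean is taken over the `window` days
#' i-window+1, ..., i (the current day included), and the deviation is the
#' same-day departure from it, so that mean + deviation reproduces the
#' original value exactly wherever both are defined. Windows reaching before
#' the start of the series treat the unavailable days as missing; any window
#' with more than `max_missing` missing values yields `NA`, otherwise the
#' mean of the available values is used.
#'
#' @param x numeric vector of daily values (may contain `NA`).
#' @param window window length in days (default 14).
#' @param max_missing maximum tolerated fraction of missing values in a
#'   window before the output is `NA` (default 0.5, exclusive bound:
#'   strictly more than half missing gives `NA`).
#' @return data.frame with columns `mean` (the rolling mean, `Y_rl`) and
#'   `dev` (the daily deviation, `Y_dv = Y - Y_rl`).
#' @export
rolling_backward_mean <- function(x, window = 14L, max_missing = 0.5) {
  stopifnot(is.numeric(x), window >= 1)
  n <- length(x)
  rl <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- i - window + 1L
    vals <- if (lo >= 1L) x[lo:i] else c(rep(NA_real_, 1L - lo), x[1:i])
    n_miss <- sum(is.na(vals))
    if (n_miss / window <= max_missing && n_miss < window)
      rl[i] <- mean(vals, na.rm = TRUE)
  }
  data.frame(mean = rl, dev = x - rl)
}

#' Lagged mean excluding the current day
#'
#' The mean of the `lag` days strictly preceding day i; the value on day i
#' itself is never used. The first `lag` positions, for which fewer than
#' `lag` prior days exist, are `NA`. Within a fully available lag window,
#' windows with more than half of the values missing yield `NA`, otherwise
#' the mean of the available values.
#'
#' @param x numeric vector of daily values.
#' @param lag number of preceding days to average (default 3).
#' @return numeric vector `Y_lg` of the same length as `x`.
#' @export
#' @examples
#' lagged_mean(c(1, 2, 3, 4))  # NA NA NA 2
lagged_mean <- function(x, lag = 3L) {
  stopifnot(is.numeric(x), lag >= 1)
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i <= lag) next
    vals <- x[(i - lag):(i - 1L)]
    n_miss <- sum(is.na(vals))
    if (n_miss / lag <= 0.5 && n_miss < lag) out[i] <- mean(vals, na.rm = TRUE)
  }
  out
}

#' Derive engineered covariate columns
#'
#' Adds the derived columns used by the regression models to a covariate
#' data.frame: wind components `EW`/`NS` (from `WS`/`WD`, if absent),
#' 14-day backward rolling means and deviations for temperature and
#' relative humidity (`TM_rl`, `TM_dv`, `RH_rl`, `RH_dv`) and 3-day lagged
#' pollen means (`GR_lg`, `NG_lg`).
#'
#' @param cov data.frame with columns `date`, `WS`, `WD`, `TM`, `RH` and
#'   optionally `GR`, `NG`.
#' @param window rolling window length in days (default 14).
#' @param lag pollen lag in days (default 3).
#' @return `cov` with the derived columns appended.
#' @export
derive_covariates <- function(cov, window = 14L, lag = 3L) {
  stopifnot(is.data.frame(cov), "date" %in% names(cov))
  if (!all(c("EW", "NS") %in% names(cov)) &&
      all(c("WS", "WD") %in% names(cov))) {
    w <- decompose_wind(cov$WS, cov$WD)
    cov$EW <- w$EW
    cov$NS <- w$NS
  }
  for (v in c("TM", "RH")) {
    if (!v %in% names(cov)) next
    r <- rolling_backward_mean(cov[[v]], window = window)
    cov[[paste0(v, "_rl")]] <- r$mean
    cov[[paste0(v, "_dv")]] <- r$dev
  }
  for (v in c("GR", "NG")) {
    if (!v %in% names(cov)) next
    cov[[paste0(v, "_lg")]] <- lagged_mean(cov[[v]], lag = lag)
  }
  cov
}

# md5 of the packaged HAAD table, frozen at packaging time
.haad_table_md5 <- "1b695aeda22fa408b5c21c4fe0c4238c"

#' Load the packaged table of high asthma admissions days
#'
#' Returns the 16 recorded HAADs for Melbourne (1993--2013) with their
#' admission counts and same-day environmental covariates: weekday `WK`,
#' raw admissions `RA`, normalised admissions per 100,000 `NAdm`, midday
#' wind speed/direction and components (`WS`, `WD`, `EW`, `NS`), daily
#' precipitation `PR` (mm), midday temperature `TM` (deg C) and relative
#' humidity `RH` (%), airport thunderstorm report `TS` (logical), daily
#' grass/non-grass pollen concentrations `GR`, `NG` (grains/m^3) with their
#' 3-day lagged means `GR_lg`, `NG_lg`, and daily mean `O3` (ppb) and
#' `PM25` (ug/m^3). Cells unavailable in the source are `NA` (pollen was
#' only measured October--December; air quality only from 2003).
#'
#' @param check integrity-check the packaged file against its recorded
#'   checksum (default `TRUE`).
#' @return data.frame of class `"haad_table"` with 16 rows.
#' @export
load_haad_table <- function(check = TRUE) {
  path <- system.file("extdata", "haad_table.csv", package = "stormasthma",
                      mustWork = TRUE)
  if (check && !identical(unname(tools::md5sum(path)), .haad_table_md5))
    stopf("packaged HAAD table is corrupt (checksum mismatch)")
  d <- read.csv(path, na.strings = c("NA", ""), stringsAsFactors = FALSE)
  if (nrow(d) != 16L) stopf("packaged HAAD table must have 16 rows")
  d$date <- as.Date(d$date)
  d$TS <- d$TS == "Y"
  class(d) <- c("haad_table", "data.frame")
  d
}

#' Read / write the daily series CSV schema
#'
#' One row per day; ISO-8601 `date` column; `"NA"` and empty cells both
#' parse as missing. All other columns are passed through unchanged.
#'
#' @param path file path.
#' @param x data.frame with a `date` column.
#' @return `read_daily_csv` returns a data.frame with `date` parsed as
#'   `Date`; `write_daily_csv` returns `path` invisibly.
#' @export
read_daily_csv <- function(path) {
  d <- read.csv(path, na.strings = c("NA", ""), stringsAsFactors = FALSE)
  if (!"date" %in% names(d)) stopf("daily CSV must have a 'date' column")
  d$date <- as.Date(d$date)
  if (anyNA(d$date)) stopf("unparseable dates in %s", path)
  d
}

#' @rdname read_daily_csv
#' @export
write_daily_csv <- function(x, path) {
  stopifnot(is.data.frame(x), "date" %in% names(x))
  x$date <- format(x$date, "%Y-%m-%d")
  write.csv(x, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Flag thunderstorm days from METAR/SPECI report lines
#'
#' Scans aviation weather report strings for the thunderstorm weather group.
#' A report counts as a thunderstorm report when any whitespace-delimited
#' token is `TS` or a weather group beginning with `TS` with optional
#' intensity prefix (for example `TSRA`, `+TSRA`). Vicinity reports
#' (`VCTS`) are excluded by default.
#'
#' @param dates `Date` vector, one per report line (repeats allowed).
#' @param reports character vector of raw METAR/SPECI report bodies.
#' @param include_vicinity also count `VCTS` (thunderstorm in the vicinity)
#'   as a thunderstorm report (default `FALSE`).
#' @return data.frame with one row per distinct date: `date` and logical
#'   `TS` (any thunderstorm report that day).
#' @export
metar_ts_days <- function(dates, reports, include_vicinity = FALSE) {
  stopifnot(inherits(dates, "Date"), length(dates) == length(reports))
  pat <- if (include_vicinity) "^[+-]?(VC)?TS[A-Z]*$" else "^[+-]?TS[A-Z]*$"
  hit <- vapply(strsplit(reports, "[[:space:]]+"), function(tok)
    any(grepl(pat, tok)), logical(1))
  agg <- aggregate(list(TS = hit), by = list(date = dates), FUN = any)
  agg[order(agg$date), , drop = FALSE]
}
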