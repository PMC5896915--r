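# Operational thunderstorm-day indicators and their agreement.
#
# Seven independent data sources each yield a daily boolean "thunderstorm
# day" series; their pairwise agreement is measured by the Equitable
# Threat Score (ETS), a chance-corrected skill score for binary events.

# Melbourne General Post Office, the reference centre for radius filters
MELBOURNE_GPO <- c(lon = 144.9632, lat = -37.8142)

indicator_series <- function(name, date, value) {
  stopifnot(inherits(date, "Date"))
  out <- data.frame(date = date, value = as.logical(value))
  out <- out[order(out$date), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("indicator_series", "data.frame"), name = name)
}

great_circle_km <- function(lon, lat, centre = MELBOURNE_GPO) {
  geosphere::distHaversine(cbind(lon, lat),
                           c(centre[["lon"]], centre[["lat"]]),
                           r = 6371000) / 1000
}

#' Thunderstorm indicators from daily and sub-daily data sources
#'
#' Each function converts one raw data source into a daily boolean
#' indicator series:
#' \describe{
#'   \item{`indicator_lightning_count`}{regional lightning-strike counts: a
#'     storm day has strictly more than `threshold` (default 2) strikes.}
#'   \item{`indicator_gridded_lightning`}{gridded strike counts: cells
#'     whose centres lie within `radius_km` of `centre` are summed per day
#'     and a storm day has at least `min_strikes` (default 1, i.e. any
#'     strike).}
#'   \item{`indicator_metar_ts`}{airport METAR/SPECI reports: any report
#'     with the thunderstorm weather group (see [metar_ts_days()]).}
#'   \item{`indicator_thunder_heard`}{observer "thunder heard" flags,
#'     passed through per day.}
#'   \item{`indicator_cape`}{sounding-derived convective available
#'     potential energy: any sounding strictly above `threshold` J/kg
#'     (default 5).}
#'   \item{`indicator_rain_rate`}{station hourly rainfall: a storm day has
#'     at least `ceiling(quorum * n_stations)` stations recording
#'     `rate_mm` or more in some hour.}
#'   \item{`indicator_storm_archive`}{severe-storm reports with
#'     coordinates: any report within `radius_km` of `centre` that day;
#'     invalid coordinates are skipped with a warning.}
#' }
#'
#' @param date `Date` vector (one entry per observation; repeats allowed
#'   for sub-daily sources).
#' @param count non-negative strike counts.
#' @param threshold strict lower threshold (strikes or J/kg).
#' @return an `"indicator_series"`: data.frame with `date` and logical
#'   `value`, one row per day.
#' @name indicators
NULL

#' @rdname indicators
#' @export
indicator_lightning_count <- function(date, count, threshold = 2) {
  if (any(!is.finite(count)) || any(count < 0))
    stopf("strike counts must be non-negative")
  indicator_series("lightning_count", date, count > threshold)
}

#' @rdname indicators
#' @param lon,lat cell-centre or report coordinates (degrees).
#' @param centre named vector `c(lon=, lat=)` of the reference point
#'   (default Melbourne GPO).
#' @param radius_km selection radius (default 75).
#' @param min_strikes daily strike total needed for a storm day
#'   (default 1).
#' @export
indicator_gridded_lightning <- function(date, lon, lat, count,
                                        centre = MELBOURNE_GPO,
                                        radius_km = 75, min_strikes = 1) {
  sel <- great_circle_km(lon, lat, centre) <= radius_km
  if (!any(sel)) stopf("no grid cell centre within %g km", radius_km)
  agg <- aggregate(list(total = count[sel]),
                   by = list(date = date[sel]), FUN = sum)
  indicator_series("gridded_lightning", agg$date,
                   agg$total >= min_strikes)
}

#' @rdname indicators
#' @param reports character METAR/SPECI report bodies.
#' @param include_vicinity also count `VCTS` reports.
#' @export
indicator_metar_ts <- function(date, reports, include_vicinity = FALSE) {
  d <- metar_ts_days(date, reports, include_vicinity)
  indicator_series("metar_ts", d$date, d$TS)
}

#' @rdname indicators
#' @param heard logical per-day "thunder heard" flags (`NA` allowed).
#' @export
indicator_thunder_heard <- function(date, heard) {
  indicator_series("thunder_heard", date, heard)
}

#' @rdname indicators
#' @param cape CAPE values in J/kg (possibly several soundings per day).
#' @export
indicator_cape <- function(date, cape, threshold = 5) {
  if (any(cape < 0, na.rm = TRUE)) stopf("CAPE must be non-negative")
  agg <- aggregate(list(hit = cape > threshold),
                   by = list(date = date), FUN = any, na.rm = TRUE)
  indicator_series("cape", agg$date, agg$hit)
}

#' @rdname indicators
#' @param station station identifier per observation.
#' @param rain_mm hourly rainfall totals (mm).
#' @param n_stations number of stations in the network (default: number
#'   of distinct stations present).
#' @param quorum fraction of stations that must report intense rain
#'   (default 0.25).
#' @param rate_mm hourly rain amount counting as intense (default 3).
#' @export
indicator_rain_rate <- function(date, station, rain_mm,
                                n_stations = length(unique(station)),
                                quorum = 0.25, rate_mm = 3) {
  if (n_stations < 1) stopf("at least one station is required")
  hit <- rain_mm >= rate_mm
  per_day_station <- aggregate(list(hit = hit),
                               by = list(date = date, station = station),
                               FUN = any)
  per_day <- aggregate(list(n_hit = per_day_station$hit),
                       by = list(date = per_day_station$date), FUN = sum)
  need <- ceiling(quorum * n_stations)
  indicator_series("rain_rate", per_day$date, per_day$n_hit >= need)
}

#' @rdname indicators
#' @param period optional `Date` range (length 2) defining the coverage
#'   period; days in the period with no report are `FALSE`.
#' @export
indicator_storm_archive <- function(date, lon, lat,
                                    centre = MELBOURNE_GPO,
                                    radius_km = 75, period = NULL) {
  ok <- is.finite(lon) & is.finite(lat) & abs(lat) <= 90 & abs(lon) <= 360
  if (any(!ok)) {
    warning(sprintf("%d report(s) with invalid coordinates skipped",
                    sum(!ok)), call. = FALSE)
    date <- date[ok]; lon <- lon[ok]; lat <- lat[ok]
  }
  near <- length(date) > 0 &
    great_circle_km(lon, lat, centre) <= radius_km
  days <- if (is.null(period)) {
    if (length(date) == 0) stopf("no valid reports and no 'period' given")
    seq(min(date), max(date), by = "day")
  } else seq(period[1], period[2], by = "day")
  hit_days <- unique(date[near])
  indicator_series("storm_archive", days, days %in% hit_days)
}

#' Contingency table of two binary event series
#'
#' @param predicted,observed logical vectors (jointly non-missing entries
#'   are used).
#' @return object of class `"contingency_table"`: list with hits `H`,
#'   misses `M`, false alarms `F`, correct negatives `C` and total `n`.
#' @export
contingency_table <- function(predicted, observed) {
  ok <- !is.na(predicted) & !is.na(observed)
  p <- predicted[ok]; o <- observed[ok]
  if (length(p) == 0) stopf("no jointly non-missing days")
  structure(list(H = sum(p & o), M = sum(!p & o), F = sum(p & !o),
                 C = sum(!p & !o), n = length(p)),
            class = "contingency_table")
}

#' Equitable Threat Score
#'
#' Chance-corrected agreement of binary event series:
#' `ETS = (H - H_e) / (H + M + F - H_e)` with expected chance hits
#' `H_e = (H + M)(H + F)/n`. Ranges from -1/3 to 1; 1 is perfect
#' agreement. When the denominator vanishes (no events observed or
#' predicted) the score is undefined and `NA` is returned rather than 0,
#' to avoid inflating agreement over event-free periods.
#'
#' @param x a `"contingency_table"`, or the number of hits `H`.
#' @param M,F,C misses, false alarms, correct negatives when `x` is given
#'   as a count.
#' @return the ETS, or `NA_real_` when undefined.
#' @export
#' @examples
#' equitable_threat_score(5, 0, 0, 5)  # 1
equitable_threat_score <- function(x, M = NULL, F = NULL, C = NULL) {
  if (inherits(x, "contingency_table")) {
    H <- x$H; M <- x$M; F <- x$F; C <- x$C
  } else H <- x
  n <- H + M + F + C
  if (n <= 0) stopf("contingency table must be non-empty")
  he <- (H + M) * (H + F) / n
  den <- H + M + F - he
  if (abs(den) < 1e-12) return(NA_real_)
  (H - he) / den
}

#' Pairwise ETS matrix over a set of indicator series
#'
#' Restricts every pair to their jointly non-missing days and computes the
#' ETS (symmetric in the two series).
#'
#' @param indicators named list of `"indicator_series"` objects.
#' @param period optional `Date` range (length 2) restricting the
#'   comparison.
#' @return list with `ets` (symmetric matrix), `events` (per-indicator
#'   event totals over its compared days) and `n_days` (matrix of jointly
#'   available day counts).
#' @export
pairwise_ets_matrix <- function(indicators, period = NULL) {
  if (length(indicators) < 2) stopf("need at least two indicators")
  nm <- names(indicators) %||% paste0("ind", seq_along(indicators))
  k <- length(indicators)
  ets <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  nd <- matrix(0L, k, k, dimnames = list(nm, nm))
  get <- function(i) {
    d <- indicators[[i]]
    if (!is.null(period)) d <- d[d$date >= period[1] & d$date <= period[2], ]
    d
  }
  events <- integer(k); names(events) <- nm
  for (i in seq_len(k)) {
    di <- get(i)
    events[i] <- sum(di$value, na.rm = TRUE)
    for (j in seq_len(k)) {
      dj <- get(j)
      m <- merge(di, dj, by = "date")
      m <- m[!is.na(m$value.x) & !is.na(m$value.y), ]
      if (nrow(m) == 0) {
        if (i != j) stopf("indicators '%s' and '%s' have no overlap",
                          nm[i], nm[j])
        next
      }
      nd[i, j] <- nrow(m)
      ets[i, j] <- equitable_threat_score(
        contingency_table(m$value.x, m$value.y))
    }
  }
  list(ets = ets, events = events, n_days = nd)
}
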