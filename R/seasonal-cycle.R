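# Annual-cycle estimation with a cyclic cubic spline.
#
# The cycle S(DOY) is a mean-zero cyclic cubic regression spline of period
# 365.25 days fitted to the population-normalised daily admission rate,
# with the smoothing parameter chosen by generalised cross validation.

#' Fit the annual cycle of admission rates
#'
#' Fits `rate ~ mean + S(DOY)` where `S` is a mean-zero cyclic cubic
#' spline over the day-of-year coordinate of [day_of_year_cyclic()] with
#' period 365.25, using [mgcv::gam()] with GCV smoothness selection.
#'
#' @param series an [admission_series()] (or any data.frame with `date`
#'   and `rate` columns) spanning at least two years.
#' @param k cyclic basis dimension before penalisation (default 30).
#' @param family model family passed to [mgcv::gam()]; Gaussian on rates
#'   by default.
#' @return an object of class `"seasonal_cycle"`: the underlying fit, the
#'   mean level, and the effective degrees of freedom of the smooth.
#' @export
fit_seasonal_cycle <- function(series, k = 30, family = stats::gaussian()) {
  stopifnot(is.data.frame(series), all(c("date", "rate") %in% names(series)))
  d <- series[!is.na(series$rate), , drop = FALSE]
  if (as.numeric(diff(range(d$date))) < 2 * 365 - 1)
    stopf("at least 2 years of data are required to fit a seasonal cycle")
  df <- data.frame(rate = d$rate, doy = day_of_year_cyclic(d$date))
  fit <- mgcv::gam(rate ~ s(doy, bs = "cc", k = k), data = df,
                   knots = list(doy = c(0, 365.25)),
                   family = family, method = "GCV.Cp")
  structure(list(gam = fit,
                 mean_level = unname(coef(fit)[1]),
                 edf = sum(fit$edf),
                 gcv = fit$gcv.ubre,
                 k = k,
                 period = 365.25),
            class = "seasonal_cycle")
}

#' Evaluate a fitted seasonal cycle
#'
#' Returns the mean-zero cyclic smooth `S(doy)` (and optionally its
#' pointwise standard error) at arbitrary day-of-year coordinates.
#'
#' @param object a `"seasonal_cycle"`.
#' @param doy numeric day-of-year coordinates (wrapped onto the period).
#' @param se also return pointwise standard errors.
#' @param ... unused.
#' @return numeric vector of smooth values, or a data.frame with columns
#'   `doy`, `effect`, `se` when `se = TRUE`.
#' @export
predict.seasonal_cycle <- function(object, doy, se = FALSE, ...) {
  doy <- doy %% object$period
  p <- predict(object$gam, newdata = data.frame(doy = doy),
               type = "terms", se.fit = TRUE)
  eff <- as.numeric(p$fit[, 1])
  if (!se) return(eff)
  data.frame(doy = doy, effect = eff, se = as.numeric(p$se.fit[, 1]))
}

#' @export
print.seasonal_cycle <- function(x, ...) {
  cat("Seasonal cycle (cyclic cubic spline, period 365.25 d)\n")
  cat(sprintf("  mean level: %.4f admissions/100,000/day\n", x$mean_level))
  cat(sprintf("  smooth EDF (GCV): %.2f of basis k = %d\n", x$edf, x$k))
  invisible(x)
}

#' Locate peaks of a fitted seasonal cycle
#'
#' Evaluates the cycle on a fine grid over one period and returns the
#' cyclic local maxima, sorted by height. Minor undulations are screened
#' out by a prominence rule: a peak must rise at least `min_prominence`
#' above the higher of its two neighbouring valleys. A cycle whose total
#' range falls below `flat_tol` is reported as peak-free.
#'
#' @param cycle a `"seasonal_cycle"`.
#' @param grid_step grid resolution in days (default 0.25).
#' @param min_prominence minimum rise above the higher adjacent valley,
#'   in rate units; default 5% of the cycle's range.
#' @param flat_tol range below which the cycle counts as flat (rate units).
#' @return data.frame with columns `doy`, `height` (the smooth value at
#'   the peak) and `prominence`, ordered by decreasing height.
#' @export
find_peaks <- function(cycle, grid_step = 0.25, min_prominence = NULL,
                       flat_tol = 1e-6) {
  stopifnot(inherits(cycle, "seasonal_cycle"))
  g <- seq(0, cycle$period - grid_step / 2, by = grid_step)
  s <- predict(cycle, g)
  empty <- data.frame(doy = numeric(0), height = numeric(0),
                      prominence = numeric(0))
  if (diff(range(s)) < flat_tol) return(empty)
  if (is.null(min_prominence)) min_prominence <- 0.05 * diff(range(s))
  n <- length(s)
  prev <- c(s[n], s[-n])
  nxt <- c(s[-1], s[1])
  peaks <- which(s > prev & s >= nxt)
  valleys <- which(s < prev & s <= nxt)
  if (length(peaks) == 0 || length(valleys) == 0) return(empty)
  prom <- vapply(peaks, function(p) {
    # nearest valley on each side, cyclically
    left <- valleys[valleys < p]
    right <- valleys[valleys > p]
    lv <- s[if (length(left)) max(left) else max(valleys)]
    rv <- s[if (length(right)) min(right) else min(valleys)]
    s[p] - max(lv, rv)
  }, numeric(1))
  keep <- prom >= min_prominence
  out <- data.frame(doy = g[peaks[keep]], height = s[peaks[keep]],
                    prominence = prom[keep])
  out[order(-out$height), , drop = FALSE]
}

#' Remove the seasonal mean from an admission series
#'
#' @param series an [admission_series()] (or data.frame with `date` and
#'   `rate`).
#' @param cycle a `"seasonal_cycle"` fitted on compatible data.
#' @return `series` with an added `residual` column equal to
#'   `rate - (mean level + S(DOY))`.
#' @export
deseasonalise <- function(series, cycle) {
  stopifnot(inherits(cycle, "seasonal_cycle"),
            all(c("date", "rate") %in% names(series)))
  s <- predict(cycle, day_of_year_cyclic(series$date))
  series$residual <- series$rate - (cycle$mean_level + s)
  series
}
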