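# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
  all(abs(x - round(x)) < 1e-8)

#' Cyclic day-of-year coordinate
#'
#' Maps calendar dates onto a cyclic coordinate with period 365.25 days.
#' In leap years 29 February is assigned the coordinate of 28 February plus
#' one half, and later days are shifted back by one so that, for example,
#' 1 March always maps to day 60. The resulting coordinate lies in
#' \code{[1, 365.25)} and is suitable as the argument of a cyclic spline of
#' period 365.25.
#'
#' @param dates a `Date` vector.
#' @return numeric vector of cyclic day-of-year coordinates.
#' @export
#' @examples
#' day_of_year_cyclic(as.Date(c("2019-03-01", "2020-02-29", "2020-03-01")))
day_of_year_cyclic <- function(dates) {
  stopifnot(inherits(dates, "Date"))
  yd <- as.POSIXlt(dates)$yday + 1          # 1..366
  y <- as.integer(format(dates, "%Y"))
  leap <- y %% 4 == 0 & (y %% 100 != 0 | y %% 400 == 0)
  out <- yd
  feb29 <- leap & yd == 60
  after <- leap & yd > 60
  out[feb29] <- 59.5
  out[after] <- yd[after] - 1
  out
}

# month number 1..12 without locale dependence
month_num <- function(dates) as.integer(format(dates, "%m"))

# weekday as factor with Sunday reference, locale independent
weekday_factor <- function(dates) {
  wd <- (as.integer(dates) + 4L) %% 7L  # 1970-01-01 was a Thursday
  factor(c("Su", "Mo", "Tu", "We", "Th", "Fr", "Sa")[wd + 1L],
         levels = c("Su", "Mo", "Tu", "We", "Th", "Fr", "Sa"))
}
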