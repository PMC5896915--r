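test_that("admission rates normalise to per-100,000 and validate inputs", {
  expect_equal(normalise_admissions(543, 100e6), 0.543)
  expect_equal(normalise_admissions(0, 4e6), 0)
  # Table-style consistency: 69 admissions at ~3.0M population prints 2.3
  expect_equal(round(normalise_admissions(69, 3.0e6), 1), 2.3)
  expect_error(normalise_admissions(5, 0), "positive")
  expect_error(normalise_admissions(-1, 1e6), "non-negative")
})

test_that("admission_series builds a gap-marked daily grid", {
  d <- as.Date(c("2001-01-01", "2001-01-02", "2001-01-05"))
  s <- admission_series(d, c(10L, 12L, 9L), 2e6)
  expect_equal(nrow(s), 5)                    # two gap days inserted
  expect_true(all(is.na(s$count[3:4])))
  expect_equal(s$rate[1], 10 / 2e6 * 1e5)
  expect_error(admission_series(rev(d), c(1L, 2L, 3L), 2e6),
               "strictly increasing")
})

test_that("wind decomposition follows the from-direction convention", {
  w <- decompose_wind(28, 360)
  expect_equal(round(c(w$EW, w$NS), 1), c(0, -28))
  w <- decompose_wind(13, 250)
  expect_equal(round(c(w$EW, w$NS), 1), c(12.2, 4.4))
  w <- decompose_wind(0, 90)
  expect_equal(c(w$EW, w$NS), c(0, 0))
  expect_error(decompose_wind(10, 361), "degrees")
  expect_error(decompose_wind(-1, 90), "non-negative")
})

test_that("wind components round-trip to speed and direction", {
  set.seed(11)
  ws <- rgamma(200, 4, scale = 5)
  wd <- runif(200, 0, 360)
  w <- decompose_wind(ws, wd)
  expect_no_difference(sqrt(w$EW^2 + w$NS^2), ws, 1e-9)
  wd_back <- (atan2(-w$EW, -w$NS) * 180 / pi) %% 360
  dd <- abs(wd_back - wd %% 360)
  expect_lt(max(pmin(dd, 360 - dd)), 1e-9)
})

test_that("backward rolling mean decomposes the series and is causal", {
  r <- rolling_backward_mean(rep(3.5, 40))
  expect_true(all(r$mean[7:40] == 3.5))
  expect_true(all(r$dev[7:40] == 0))
  r <- rolling_backward_mean(1:14)
  expect_equal(r$mean[14], 7.5)
  expect_equal(r$dev[14], 6.5)
  set.seed(2)
  x <- rnorm(100)
  r <- rolling_backward_mean(x)
  ok <- !is.na(r$mean)
  expect_equal(r$mean[ok] + r$dev[ok], x[ok], tolerance = 1e-12)
  # causality: perturbing a future value never changes earlier output
  x2 <- x
  x2[60] <- 1e6
  r2 <- rolling_backward_mean(x2)
  expect_identical(r$mean[1:59], r2$mean[1:59])
})

test_that("lagged mean excludes the current day", {
  expect_equal(lagged_mean(c(1, 2, 3, 4)), c(NA, NA, NA, 2))
  expect_equal(lagged_mean(rep(7, 10))[4:10], rep(7, 7))
  set.seed(3)
  x <- rnorm(50)
  l1 <- lagged_mean(x)
  x[30] <- 1e6
  l2 <- lagged_mean(x)
  expect_identical(l1[30], l2[30])   # own day never used
  expect_false(identical(l1[31], l2[31]))
  # hand-built 4-day pollen stub: lagged mean on day 4 is mean of days 1-3
  stub <- c(107, 73, 60, 999)
  expect_equal(lagged_mean(stub)[4], mean(stub[1:3]))
})

test_that("derive_covariates adds the engineered columns", {
  cov <- data.frame(date = seq(as.Date("2001-10-01"), by = "day",
                               length.out = 30),
                    WS = 10, WD = 90, TM = 20 + sin(1:30), RH = 60,
                    GR = 1:30, NG = 2 * (1:30))
  d <- derive_covariates(cov)
  expect_true(all(c("EW", "NS", "TM_rl", "TM_dv", "RH_rl", "RH_dv",
                    "GR_lg", "NG_lg") %in% names(d)))
  expect_equal(d$TM_dv, d$TM - d$TM_rl)
  expect_equal(d$GR_lg[5], mean(2:4))
})

test_that("the packaged HAAD table matches its printed source", {
  h <- load_haad_table()
  expect_equal(nrow(h), 16)
  r <- h[h$date == as.Date("2010-11-25"), ]
  expect_equal(r$RA, 144)
  expect_equal(r$PR, 23.0)
  expect_equal(r$RH, 92)
  expect_true(is.na(h$GR[h$date == as.Date("1993-02-14")]))
  expect_equal(sum(h$TS), 6)
  # each row's printed wind components agree with the decomposition
  w <- decompose_wind(h$WS, h$WD)
  expect_lt(max(abs(w$EW - h$EW)), 0.05)
  expect_lt(max(abs(w$NS - h$NS)), 0.05)
})

test_that("daily CSV round-trips with NA handling", {
  d <- data.frame(date = seq(as.Date("2001-01-01"), by = "day",
                             length.out = 4),
                  count = c(3L, NA, 5L, 1L), RH = c(50, 60, NA, 70))
  p <- withr::local_tempfile(fileext = ".csv")
  write_daily_csv(d, p)
  d2 <- read_daily_csv(p)
  expect_equal(d2$date, d$date)
  expect_equal(d2$count, d$count)
  expect_equal(d2$RH, d$RH)
})

test_that("METAR scanner flags thunderstorm weather groups by token", {
  dates <- as.Date("2001-01-01") + c(0, 0, 1, 2, 3)
  reports <- c("METAR YMML 0100Z 24010KT RA",
               "SPECI YMML 0130Z 24015KT TS",
               "METAR YMML 0100Z 18005KT +TSRA BKN020",
               "METAR YMML 0100Z 18005KT VCTS",
               "METAR YMML 0100Z CAVOK STS")   # TS only as substring
  out <- metar_ts_days(dates, reports)
  expect_equal(out$TS, c(TRUE, TRUE, FALSE, FALSE))
  out2 <- metar_ts_days(dates, reports, include_vicinity = TRUE)
  expect_equal(out2$TS, c(TRUE, TRUE, TRUE, FALSE))
})
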