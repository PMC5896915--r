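days <- function(n, start = "2008-01-01") seq(as.Date(start), by = "day",
                                              length.out = n)

test_that("lightning-count indicator uses a strict threshold", {
  d <- days(4)
  ind <- indicator_lightning_count(d, c(0, 2, 3, 50))
  expect_equal(ind$value, c(FALSE, FALSE, TRUE, TRUE))
  expect_error(indicator_lightning_count(d, c(-1, 0, 0, 0)), "non-negative")
})

test_that("gridded lightning selects cells by distance from the centre", {
  gpo <- c(lon = 144.9632, lat = -37.8142)
  d <- rep(days(2), each = 2)
  lon <- rep(c(gpo[["lon"]], gpo[["lon"]]), 2)
  lat <- rep(c(gpo[["lat"]] + 0.3, gpo[["lat"]] + 0.9), 2)  # ~33, ~100 km
  counts <- c(0, 5, 1, 0)   # day 1: strike only in the far cell
  ind <- indicator_gridded_lightning(d, lon, lat, counts)
  expect_equal(ind$value, c(FALSE, TRUE))
  expect_error(indicator_gridded_lightning(days(1), 10, 10, 5),
               "grid cell")
  zero <- indicator_gridded_lightning(d, lon, lat, rep(0, 4))
  expect_false(any(zero$value))
})

test_that("CAPE indicator is strict at 5 J/kg and aggregates soundings", {
  d <- as.Date("2008-01-01") + c(0, 1, 2, 2)
  ind <- indicator_cape(d, c(5.0, 5.1, 0, 12))
  expect_equal(ind$value, c(FALSE, TRUE, TRUE))
  expect_error(indicator_cape(d, c(-3, 1, 1, 1)), "non-negative")
})

test_that("rain-rate indicator needs a quorum of intense stations", {
  d4 <- rep(days(1), 16)
  st <- paste0("s", 1:16)
  rain <- c(rep(3, 4), rep(0.5, 12))
  expect_true(indicator_rain_rate(d4, st, rain)$value)
  rain3 <- c(rep(3, 3), rep(0.5, 13))
  expect_false(indicator_rain_rate(d4, st, rain3)$value)
  expect_false(indicator_rain_rate(d4, st, rep(0, 16))$value)
})

test_that("storm-archive indicator filters reports by great-circle radius", {
  gpo <- c(lon = 144.9632, lat = -37.8142)
  d <- days(3)
  # day 1 at the centre, day 2 at 76 km (outside), day 3 no report
  ind <- indicator_storm_archive(
    date = d[1:2], lon = c(gpo[["lon"]], gpo[["lon"]]),
    lat = c(gpo[["lat"]], gpo[["lat"]] + 76 / 111.1949),
    period = range(d))
  expect_equal(ind$value, c(TRUE, FALSE, FALSE))
  expect_warning(
    ind2 <- indicator_storm_archive(date = d[1:2],
                                    lon = c(gpo[["lon"]], NA),
                                    lat = c(gpo[["lat"]], 95),
                                    period = range(d)),
    "invalid")
  expect_equal(ind2$value, c(TRUE, FALSE, FALSE))
})

test_that("thunder-heard passes through with missing days preserved", {
  ind <- indicator_thunder_heard(days(3), c(TRUE, FALSE, NA))
  expect_equal(ind$value, c(TRUE, FALSE, NA))
})

test_that("the ETS formula matches hand arithmetic and handles degeneracy", {
  expect_equal(equitable_threat_score(5, 0, 0, 5), 1)
  expect_equal(equitable_threat_score(3, 1, 1, 5), 1.4 / 3.4,
               tolerance = 1e-12)
  expect_true(is.na(equitable_threat_score(0, 0, 0, 10)))
  expect_error(equitable_threat_score(0, 0, 0, 0), "non-empty")
  # a constant-true prediction has zero skill against any base rate
  set.seed(1)
  obs <- runif(400) < 0.2
  ct <- contingency_table(rep(TRUE, 400), obs)
  expect_equal(equitable_threat_score(ct), 0)
})

test_that("ETS is bounded in [-1/3, 1] over all tables up to n = 30", {
  vals <- c()
  for (n in 1:30) {
    combos <- expand.grid(H = 0:n, M = 0:n, F = 0:n)
    combos <- combos[combos$H + combos$M + combos$F <= n, ]
    combos$C <- n - combos$H - combos$M - combos$F
    e <- mapply(equitable_threat_score, combos$H, combos$M, combos$F,
                combos$C)
    vals <- c(vals, e[!is.na(e)])
  }
  expect_gte(min(vals), -1 / 3)
  expect_lte(max(vals), 1)
})

test_that("ETS is symmetric under swapping misses and false alarms", {
  set.seed(2)
  for (i in 1:50) {
    t <- sample(0:20, 4, replace = TRUE)
    if (sum(t) == 0) next
    expect_equal(equitable_threat_score(t[1], t[2], t[3], t[4]),
                 equitable_threat_score(t[1], t[3], t[2], t[4]))
  }
})

test_that("the pairwise ETS matrix is symmetric with unit diagonal", {
  set.seed(3)
  d <- days(3000)
  a <- indicator_thunder_heard(d, runif(3000) < 0.1)
  b <- indicator_thunder_heard(d, runif(3000) < 0.1)
  base <- runif(3000) < 0.12
  c1 <- indicator_thunder_heard(d, base | runif(3000) < 0.02)
  m <- pairwise_ets_matrix(list(a = a, b = b, c = c1))
  expect_equal(m$ets, t(m$ets))
  expect_equal(unname(diag(m$ets)), rep(1, 3))
  # independent indicators agree only at chance level
  expect_lt(abs(m$ets["a", "b"]), 0.05)
  expect_equal(unname(m$events["a"]), sum(a$value))
  # disjoint coverage is an error
  e1 <- indicator_thunder_heard(days(50, "2008-01-01"), rep(TRUE, 50))
  e2 <- indicator_thunder_heard(days(50, "2010-01-01"), rep(TRUE, 50))
  expect_error(pairwise_ets_matrix(list(x = e1, y = e2)), "overlap")
})

test_that("METAR indicator wraps the token scanner", {
  d <- as.Date("2008-02-01") + c(0, 0, 1)
  ind <- indicator_metar_ts(d, c("RA BKN020", "TSRA", "CAVOK"))
  expect_equal(ind$value, c(TRUE, FALSE))
})
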