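test_that("the model roster maps ids to periods and term sets", {
  expect_equal(model_spec(1)$period, "full_year")
  expect_equal(model_spec(5)$period, "full_year")
  for (id in c(2, 3, 4, 6, 7, 8))
    expect_equal(model_spec(id)$period, "oct_dec")
  expect_false(any(c("GR", "NG") %in% model_spec(1)$smooths))
  expect_true(all(c("GR_lg", "NG_lg") %in% model_spec(3)$smooths))
  expect_true(model_spec(4)$interactions)
  expect_true(all(c("O3", "PM25") %in% model_spec(7)$smooths))
  # pollen terms only appear in October-December specifications
  for (id in 1:8) {
    sp <- model_spec(id)
    if (any(c("GR", "NG") %in% sp$smooths))
      expect_equal(sp$period, "oct_dec")
  }
  expect_error(model_spec(9), "1..8")
  expect_error(model_spec(3, stepwise = TRUE), "stepwise")
})

test_that("build_design restricts period, codes references and interactions", {
  sim <- shared_sim()
  fr1 <- build_design(sim$covariates, sim$admissions, model_spec(1))
  expect_false("GR" %in% names(fr1))
  expect_true(all(format(fr1$date, "%m") %in% sprintf("%02d", 1:12)))
  expect_equal(levels(fr1$WK)[1], "Su")     # Sunday is the reference level
  fr4 <- build_design(sim$covariates, sim$admissions, model_spec(4))
  expect_true(all(format(fr4$date, "%m") %in% c("10", "11", "12")))
  expect_true("TS_x_GR_lg" %in% names(fr4))
  storm <- fr4$TS == 1
  expect_equal(fr4$TS_x_GR_lg[storm], fr4$GR_lg[storm])
  expect_true(all(fr4$TS_x_GR_lg[!storm] == 0))
  # a missing required column is reported by name
  cov2 <- sim$covariates
  cov2$GR_lg <- NULL
  expect_error(build_design(cov2, sim$admissions, model_spec(3)), "GR_lg")
})

test_that("exactly collinear covariates raise a rank-deficiency error", {
  sim <- shared_sim()
  cov2 <- sim$covariates
  cov2$NS <- cov2$EW
  fr <- build_design(cov2, sim$admissions, model_spec(1))
  expect_error(fit_admissions_model(fr), "collinear")
})

test_that("a true linear effect is fitted as near-linear and recovered", {
  cfg <- generator_config(n_years = 3, spike_multiplier = 1)
  cov <- generate_covariates(cfg, seed = 21)
  adm <- generate_admissions(cov, cfg, seed = 21)$admissions
  fr <- build_design(cov, adm, model_spec(1))
  fr$rate <- additive_response(fr, seed = 21)
  fit <- fit_admissions_model(fr)
  expect_lt(edf_of(fit, "TM_dv"), 2.5)
  sl <- smooth_slope(fit, "TM_dv")
  expect_lt(abs(sl$slope - 0.01), 2 * sl$se)
  # the null EW term is shrunk out
  expect_lt(edf_of(fit, "EW"), 0.5)
  # fitted + residual = observed
  expect_no_difference(fitted(fit$gam) + residuals(fit$gam), fr$rate, 1e-9)
})

test_that("effect sizes follow the population-scaled convention exactly", {
  sim <- shared_sim()
  fr <- build_design(sim$covariates, sim$admissions, model_spec(4))
  fit <- fit_admissions_model(fr)
  cf <- coef(fit$gam)
  es_ts <- effect_size(fit, "TS")
  expect_equal(es_ts$effect, unname(cf["TS"]) * 40)
  es_int <- effect_size(fit, "TS_x_GR_lg")
  q95 <- unname(quantile(fit$frame$GR_lg, 0.95))
  expect_equal(es_int$effect, unname(cf["TS_x_GR_lg"]) * q95 * 40)
  expect_equal(es_int$q95, q95)
  # linear in the population scale factor
  es_2m <- effect_size(fit, "TS", population = 2e6)
  expect_equal(es_2m$effect, es_ts$effect / 2)
  # weekday contrast is a plain coefficient times 40
  es_mo <- effect_size(fit, "WKMo")
  expect_equal(es_mo$effect, unname(cf["WKMo"]) * 40)
  expect_error(effect_size(fit, "nonexistent"), "not present")
})

test_that("a shrunk-out smooth reports a zero effect with a dropped flag", {
  cfg <- generator_config(n_years = 3, spike_multiplier = 1)
  cov <- generate_covariates(cfg, seed = 21)
  adm <- generate_admissions(cov, cfg, seed = 21)$admissions
  fr <- build_design(cov, adm, model_spec(1))
  fr$rate <- additive_response(fr, seed = 21)
  fit <- fit_admissions_model(fr)
  ts <- term_stats(fit)
  dropped <- ts$term[ts$dropped]
  expect_gt(length(dropped), 0)
  var_dropped <- sub("^s\\((.*)\\)$", "\\1", dropped[1])
  es <- effect_size(fit, var_dropped)
  expect_true(es$dropped)
  expect_equal(es$effect, 0)
})

test_that("predictions reproduce fitted values and warn on extrapolation", {
  sim <- shared_sim()
  fr <- build_design(sim$covariates, sim$admissions, model_spec(1))
  fit <- fit_admissions_model(fr)
  p <- predict_rates(fit, fr)
  expect_no_difference(p$predicted, fitted(fit$gam), 1e-8)
  out <- fr[1:5, ]
  out$RH_rl <- 200
  expect_warning(predict_rates(fit, out), "extrapolat")
})

test_that("variance explained is 1 for a perfect fit and the seasonal-only
          fit has no deseasonalised skill", {
  cfg <- generator_config(n_years = 3, spike_multiplier = 1)
  cov <- generate_covariates(cfg, seed = 33)
  adm <- generate_admissions(cov, cfg, seed = 33)$admissions
  fr <- build_design(cov, adm, model_spec(1))
  # noise-free additive truth: the model can fit it essentially exactly
  fr$rate <- additive_response(fr, seed = 33, sd = 1e-4)
  fit <- fit_admissions_model(fr)
  v <- variance_explained(fit)
  expect_gt(v$r_squared, 0.999)
  expect_gt(v$deseasonalised_correlation, 0.999)
  # pure seasonal signal + noise: model skill vanishes once deseasonalised
  set.seed(33)
  fr2 <- fr
  fr2$rate <- 0.5 + 0.2 * sin(2 * pi * fr2$doy / 365.25) +
    rnorm(nrow(fr2), sd = 0.1)
  fit2 <- fit_admissions_model(fr2)
  v2 <- variance_explained(fit2)
  expect_lt(abs(v2$deseasonalised_correlation), 0.2)
  expect_gt(v2$r_squared, 0.3)
})
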