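# Shared fixtures, built in code at test time.

# Constructed admission series with a smooth seasonal background, a weekday
# pattern, bounded (uniform) noise and injected spikes sized in units of the
# detector's own local scale. Because the noise is bounded, background days
# can never reach the detection threshold, so recall/precision of spike
# recovery are exact properties of the detector.
make_spike_series <- function(seed, n_days = 730, n_spikes = 5,
                              spike_sd = 8, config = haad_config()) {
  set.seed(seed)
  dates <- seq(as.Date("2001-01-01"), by = "day", length.out = n_days)
  doy <- day_of_year_cyclic(dates)
  wk <- weekday_factor(dates)
  wk_add <- c(Su = 0.012, Mo = 0.012, Tu = -0.0048, We = -0.0048,
              Th = -0.0048, Fr = -0.0048, Sa = -0.0048)
  phase <- runif(1, 0, 365)
  rate <- 0.5 + 0.15 * sin(2 * pi * (doy - phase) / 365.25) +
    wk_add[as.character(wk)] + runif(n_days, -0.1, 0.1)
  base_stats <- running_trimmed_stats(rate, config)
  # spike days: interior, pairwise separated by more than one window
  candidates <- seq(50, n_days - 50, by = config$window + 5)
  spike_idx <- sort(sample(candidates, n_spikes))
  # spike days sit exactly spike_sd local SDs above the local trimmed mean
  rate[spike_idx] <- base_stats$mean[spike_idx] +
    spike_sd * base_stats$sd[spike_idx]
  list(dates = dates, rate = rate, spike_dates = dates[spike_idx],
       series = data.frame(date = dates, rate = rate))
}

# Memoised small simulation shared across test files
.sim_cache <- new.env(parent = emptyenv())
shared_sim <- function() {
  if (is.null(.sim_cache$sim))
    .sim_cache$sim <- simulate_study(generator_config(n_years = 6), seed = 42)
  .sim_cache$sim
}

# Additive Gaussian response on generator covariates: the exact model the
# Gaussian additive fit assumes, for recovery/shrinkage tests
additive_response <- function(frame, seed, beta_tmdv = 0.01, sd = 0.08) {
  set.seed(seed + 5000)
  0.5 + 0.1 * sin(2 * pi * frame$doy / 365.25) +
    0.01 * (frame$RH_rl - 60) + beta_tmdv * frame$TM_dv +
    0.006 * frame$PR + rnorm(nrow(frame), sd = sd)
}

expect_no_difference <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a - b), na.rm = TRUE), tol)
}
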