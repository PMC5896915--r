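# stormasthma

Analysis of seasonal and episodic ("thunderstorm") asthma hospital
admissions from daily environmental time series.

Thunderstorm asthma — a sudden population-level surge of acute allergic
asthma following a thunderstorm during the grass pollen season — is rare,
recurrent and hard to predict. Studying it requires a chain of time-series
methods: estimating the annual admission cycle, flagging anomalous
high-admission days, regressing daily rates on weather/pollen/storm
covariates, evaluating rare-event classifiers, and comparing operational
thunderstorm indicators. `stormasthma` implements that chain as tested R
functions for epidemiologists and biostatisticians working with daily
admission and exposure data, together with a seeded synthetic-data
generator so every stage can be exercised without restricted hospital
records.

## Methods at a glance

* **Seasonal cycle** — the population-normalised daily rate
  *y<sub>i</sub>* (admissions per 100,000) is modelled as
  *y<sub>i</sub> = c + S(DOY<sub>i</sub>) + e<sub>i</sub>* with *S* a
  mean-zero cyclic cubic spline of period 365.25 days, smoothness chosen
  by generalised cross validation (`fit_seasonal_cycle`, `find_peaks`,
  `deseasonalise`).
* **High asthma admissions days (HAADs)** — the anomaly statistic
  *z<sub>i</sub> = (y<sub>i</sub> − m<sub>i</sub>) / s<sub>i</sub>*, where
  *m* and *s* are the trimmed mean and (consistency-rescaled) trimmed SD
  of the central 50% of values in a centred 31-day window; a HAAD is any
  day with *z ≥ 4.5* (`detect_haads`, `normalised_residuals`,
  `qq_points`).
* **Environmental regression** — eight additive Gaussian model
  specifications on the rate scale,
  *y = c + S(DOY) + Σ s(x<sub>j</sub>) + weekday + β<sub>TS</sub>I<sub>TS</sub> + e*,
  over engineered covariates (14-day rolling means/deviations, 3-day
  lagged pollen, wind components), with double-penalty shrinkage so
  uninformative terms drop to zero EDF, and effect sizes expressed as
  coefficient × q95 × 40 extra daily admissions in a population of 4
  million (`model_spec`, `fit_admissions_model`, `effect_size`).
* **Rare-event classification** — logistic regression and componentwise
  gradient boosting for HAAD/non-HAAD, evaluated over replicated 70/30
  day-level splits with top-*k* discretisation and averaged confusion
  tables (`evaluate_replicates`).
* **Thunderstorm indicators** — seven operational storm-day definitions
  (lightning counts, gridded lightning, METAR `TS`, thunder heard, CAPE,
  rain-rate quorum, storm archive), compared by the Equitable Threat
  Score *ETS = (H − H<sub>e</sub>)/(H + M + F − H<sub>e</sub>)*,
  *H<sub>e</sub> = (H+M)(H+F)/n* (`equitable_threat_score`,
  `pairwise_ets_matrix`).
* **Characterisation** — over-representation χ² tests, calendar and
  weekday structure, sex-ratio binomial tests, age–sex distributions
  (`condition_overrepresentation`, `haad_calendar_summary`).

The 16 recorded Melbourne HAADs (1993–2013) with their same-day
covariates ship as a checksummed fixture: `load_haad_table()`.

## Worked example

```r
library(stormasthma)

sim <- simulate_study(generator_config(n_years = 10), seed = 1)
cyc <- fit_seasonal_cycle(sim$admissions)
cyc
#> Seasonal cycle (cyclic cubic spline, period 365.25 d)
#>   mean level: 0.5433 admissions/100,000/day
#>   smooth EDF (GCV): 22.27 of basis k = 30
round(find_peaks(cyc), 2)
#>      doy height prominence
#> 4 317.00   0.28       0.31
#> 2 165.75   0.16       0.13
#> 3 226.25   0.15       0.12
#> 1  53.75  -0.03       0.07
```

The four seasonal peaks sit where the generator put them: the
mid-November allergy peak (day 317, the tallest), the June and August
winter peaks, and the weaker late-February return-to-school peak (which
lies below the centred cycle's zero line but is a genuine local peak —
hence the prominence column).

```r
detect_haads(sim$admissions)
#> [1] "2000-11-18" "2002-09-08" "2002-11-26" "2004-11-08" "2005-07-24"
#> [6] "2005-11-13" "2008-11-02" "2009-11-21"
sim$truth$haad_dates
#> [1] "2000-11-18" "2002-11-26" "2004-11-08" "2005-11-13"
```

All four injected admission spikes are recovered; the remaining
detections are genuine extreme days arising from the Poisson count
process — the expected behaviour of an anomaly detector on count data.

```r
fr  <- build_design(sim$covariates, sim$admissions, model_spec(3))
fit <- fit_admissions_model(fr)
fit
#> Additive admission-rate model 3 (Oct-Dec), n = 899
#>   GCV score 0.030901; deviance explained 52.7%
es <- effect_size(fit, "TS")
sprintf("Thunderstorm effect: %.2f extra admissions (95%% CI %.2f-%.2f)",
        es$effect, es$lower, es$upper)
#> "Thunderstorm effect: 7.53 extra admissions (95% CI 5.52-9.54)"
```

The thunderstorm coefficient, scaled to a population of 4 million, says
storm days carry about 7.5 extra admissions in this simulation — large
because the simulated storm days include the injected spike days.

```r
haad_calendar_summary(load_haad_table())$period
#> oct_dec     feb   other
#>      10       5       1
```

Of the 16 recorded HAADs, 10 fell in the October–December pollen season
and 5 in late February.

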