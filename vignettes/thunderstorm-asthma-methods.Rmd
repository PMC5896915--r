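---
title: "Methods: seasonal and episodic thunderstorm asthma analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonal and episodic thunderstorm asthma analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stormasthma)
```

## The problem

Thunderstorm asthma is a sudden, population-level surge of acute allergic
asthma in the hours after a thunderstorm, typically during the grass
pollen season. In south-eastern Australia such events recur every few
years and can overwhelm emergency services within hours. Epidemiological
analysis of the phenomenon works from daily time series: hospital
admission counts, midday weather observations, daily rainfall,
thunderstorm indicators, volumetric pollen counts and air-quality
averages. This package implements, as tested and reusable components, the
complete analysis chain for such data:

1. population-normalised admission rates and deterministic covariate
   engineering;
2. estimation of the annual admission cycle with a cyclic penalised
   spline;
3. detection of high asthma admissions days (HAADs) by a robust running
   anomaly statistic;
4. a roster of eight additive regression models linking daily rates to
   environmental covariates, with implicit term selection and a
   population-scaled effect-size convention;
5. replicated train/test evaluation of rare-event HAAD classifiers;
6. seven operational thunderstorm-day indicator definitions compared by
   the Equitable Threat Score;
7. descriptive characterisation of HAAD conditions, and
8. a seeded synthetic-data generator so that every stage can be exercised
   end-to-end without access to restricted hospital data.

The hospital, lightning and METAR archives behind the original Melbourne
analyses are not public. The only real-data artefact shipped with the
package is the printed 16-row table of recorded HAADs (1993--2013) with
their same-day environmental covariates, packaged verbatim as
`load_haad_table()` and integrity-checked against a checksum.

## Data conventions

**Rates.** The response throughout is the admission rate per 100,000
population, `rate = count / population * 1e5`. Admission days run
00:00--23:59 local time; series are kept on a gap-free daily grid with
explicit `NA` markers.

**Wind.** Direction is "degrees from which the wind blows", clockwise
from North. The components are `EW = -WS sin(WD)` and `NS = -WS cos(WD)`,
so positive `EW` means winds *from the west* and positive `NS` winds
*from the south*; a northerly gale has strongly negative `NS`. All 16
rows of the packaged HAAD table reproduce under this convention to the
printed 0.1 km/h.

**Rolling and lagged covariates.** Temperature and relative humidity are
decomposed into a backward-looking 14-day rolling mean (`*_rl`) and the
same-day deviation from it (`*_dv`); the window *includes* the current
day, so mean + deviation always reproduces the original value. Pollen
enters additionally as a 3-day lagged mean (`*_lg`) over the three days
strictly before the index day — the current day is never used, which the
test suite asserts as a perturbation property. Windows with more than
half of their values missing yield `NA`; this matters because pollen is
only measured from 1 October to 31 December.

## The synthetic-data generator

`generator_config()` / `simulate_study()` produce a covariate series and
Poisson admission counts with the structure the analysis assumes. The
defaults encode the study conditions of the Melbourne setting:

* **Mean rate 0.543 admissions/day/100,000**, the long-run mean of the
  real 25-year series. The linear predictor is calibrated against the
  realised covariates so this is the actual marginal mean of the
  simulation, not merely an intercept.
* **Annual cycle** with Gaussian log-scale bumps centred in late February
  (day 52, the return-to-school peak), mid-June and mid-August (winter
  viral peaks), and mid-November (day 319, the grass-allergy peak), with
  a January trough. Widths of 14--18 days keep adjacent features
  resolvable by a cyclic spline.
* **Weekday structure** with Sunday/Monday elevated (multipliers 1.15)
  and midweek slightly suppressed; the seven multipliers average to 1.
* **Thunderstorm seasonality**: expected storm days per month of about
  1.75 November--January, 1.3 in February/March/October and 0.4
  April--September, drawn as independent Bernoulli days.
* **Pollen season**: log-normal grass pollen under a Gaussian envelope
  peaking near 21 November at around 60 grains/m^3 (and a broader
  non-grass process), sampled only October--December and `NA` otherwise,
  mirroring the real monitoring window.
* **Covariate effects** on the log rate (humidity rolling mean,
  temperature deviation, rainfall, storms at +10%, lagged pollen) with
  order-of-magnitude values chosen so that no single covariate dominates
  the seasonal cycle; all are config-visible, never hard-coded.
* **HAAD spikes**: on days satisfying the trigger — storm day AND lagged
  grass pollen above its within-season 0.7 quantile AND humidity above
  its within-season median — the expected count is multiplied by the
  spike multiplier (default 3) with probability 0.5. Defaults yield
  roughly one injected HAAD every two to three years, matching the
  observed recurrence of candidate thunderstorm-asthma days. Every
  spiked date is recorded as ground truth.

Counts are Poisson under a log link by default, so the Gaussian additive
fits downstream are exercised under realistic misspecification; a
Gaussian-noise option supports exact-recovery experiments. One global
seed expands into independent substreams for weather, pollen, storms,
counts and spikes, so changing the pollen parameters cannot perturb the
simulated weather.

What the generator does **not** emulate: cross-correlation between
weather processes (real storm days are rainy and humid; simulated
triggers rely on coincidence), serial correlation in wind, within-day
structure, spatial structure, or an exposure mechanism. Tests that pass
on this generator therefore demonstrate that the machinery is correct
under its assumptions, not that the scientific effect sizes of the real
system are recovered.

## The seasonal cycle

`fit_seasonal_cycle()` fits `rate ~ mean + S(DOY)` where `S` is a
mean-zero cyclic cubic regression spline of period 365.25 days, with the
smoothing parameter chosen by generalised cross validation (GCV) in
`mgcv`. Day-of-year uses a leap-aware coordinate: 29 February maps to
28.5 February and later days shift back by one, so 1 March is day 60 in
every year. The basis cap is k = 30, enough for the four broad observed
peaks while the penalty controls wiggliness; a ±1-SE band is available
pointwise. The test suite asserts that the chosen smoothing parameter
minimises GCV over a surrounding grid and that the fit is continuous
across the year boundary.

`find_peaks()` reports cyclic local maxima screened by topographic
prominence (by default 5% of the cycle's range). Prominence, not
positivity, is the right filter: next to the deep January trough the
late-February peak of the *centred* smooth can lie below zero while still
being a genuine peak.

## The HAAD anomaly statistic

A day's normalised residual is

```
z[i] = (y[i] - m[i]) / max(s[i], floor)
```

where `m` and `s` are the trimmed mean and trimmed SD of the central 50%
(by order statistics) of the values in the centred 31-day window, and a
HAAD is any day with `z >= 4.5` (inclusive). Conventions the
implementation fixes, all configurable via `haad_config()`:

* **Kept ranks.** From `n` sorted window values, ranks
  `ceil(n/4)+1 ... ceil(3n/4)` are kept — 16 of 31 values, so up to a
  quarter of a window may be arbitrarily contaminated on the high side
  without moving either statistic (asserted as an exact invariance).
* **Scale consistency.** The SD of the retained central half of a
  Gaussian window is far smaller than the underlying SD (about 0.41 of
  it at window 31 — noticeably above the asymptotic truncated-normal
  value 0.378). The trimmed SD is therefore divided by its
  *finite-sample* Gaussian consistency constant, the expected trimmed SD
  of a standard-normal window of the same size, computed once per window
  size by a deterministic Monte Carlo integration and cached. Without
  this rescaling, z values are inflated about 2.6-fold and the 4.5
  threshold loses its meaning as "local standard deviations above the
  local mean".
* **Edges** use truncated windows down to 15 available values, else `NA`.
  The scale floor is 1e-8 on the rate scale. The spike day is a member of
  its own window; trimming removes it from the statistics in practice.

A property worth knowing before applying the detector to count data: the
trimmed SD is estimated from 16 values and fluctuates with a coefficient
of variation near 20%, so `z` has heavier-than-normal tails. On pure
Poisson backgrounds roughly 3–4 exceedances of 4.5 per 10,000 days occur
by chance. The detector-recovery tests therefore use constructed series
with *bounded* (uniform) noise around a smooth seasonal background, where
chance exceedances are impossible and recall/precision of injected spikes
(placed a fixed number of local SDs above the local trimmed mean) are
exact properties; the generator-based tests assert full recall of
injected spikes and treat occasional extra detections on Poisson noise as
the expected behaviour of any anomaly detector.

## The regression models

Eight additive model specifications share the structure

```
rate ~ S(DOY) + s(covariate smooths) + weekday + I(TS) [+ TS x pollen]
```

with Gaussian errors on the rate scale, Sunday and "no thunderstorm" as
reference levels. Models 1 and 5 run on the full year (weather, and
weather + air quality); models 2--4 and 6--8 run October--December and
add daily pollen, lagged pollen, and thunderstorm-by-pollen interactions,
with 6--8 including air quality. Interactions are indicator-by-covariate
columns (`TS * GR_lg` etc.). The roster's exact composition is this
package's own reconstruction of the eight-model design from the model
descriptions available; the fitted coefficients of the original real-data
fits are not reproduction targets.

**Implicit term selection.** Smooths are penalised cubic regression
splines (k = 10; cyclic, k = 30, for day-of-year) with the double-penalty
construction (`select = TRUE`), giving each smooth's penalty null space
its own smoothing parameter so an uninformative term can be shrunk to
zero EDF. Smoothness is selected by GCV with a BIC-type
degrees-of-freedom charge, `gamma = log(n)/2`. This combination is the
result of a measured design study: plain GCV (and the common
`gamma = 1.4` correction) retains spurious low-amplitude wiggles in a
truly null covariate in roughly one fit in five, while single-penalty
shrinkage bases under the BIC charge bias the linear component of a true
effect downward by ~14%. The double penalty with the BIC charge achieved
both reliable null-term removal (EDF < 0.5 in 50/50 replicates) and
unbiased linear recovery (slope within 2 SE in 50/50 replicates) on
synthetic data. Both `gamma` and `select` are user-configurable;
`gamma = 1` restores plain GCV.

**Effect sizes.** A term's practical importance is expressed as
additional daily admissions in a population of 4 million: coefficient x
q95(covariate) x 40 for continuous linear terms (40 = 4e6 / 1e5),
coefficient x 40 for binary and weekday terms, and the fitted smooth
evaluated at the covariate's q95 x 40 for smooths. The q95 is computed on
the period-restricted model frame actually fitted. Interaction columns
are scaled by the q95 of the underlying pollen covariate, not of the
mostly-zero product column. Confidence intervals propagate only the
coefficient's (or smooth's pointwise) uncertainty, linearly. No
multiple-testing adjustment is applied to the per-term p-values; they are
presented as-is.

**Stepwise selection** appears in the roster as a flag but is not
implemented: no procedural definition was available, so
`model_spec(stepwise = TRUE)` is an explicit error rather than a guessed
algorithm.

## Rare-event HAAD classification

`evaluate_replicates()` runs the replicated experiment: October--December
days are labelled by the detector, split 70/30 at the day level (re-drawn
until the test set holds at least two HAADs — and at least one remains
for training, else no classifier can be fitted), a classifier is trained,
and the `k` highest-scoring test days are declared modelled HAADs, where
`k` is the number of observed HAADs in the test set (the
train-prevalence rule is available as an option). Ties break by earlier
date. Per replicate, hits + false alarms = k and hits + misses = test
positives hold by construction; confusion counts are averaged over (by
default) 100 replicates, which is why the "observed" cells of the
averaged table are fractional.

The logistic variant uses linearised covariates, the fixed seasonal
effect (evaluated from a separately fitted seasonal cycle) and a
working-day indicator (weekends plus a user-supplied holiday list — no
jurisdiction's holidays are hard-coded). The boosting variant is a
componentwise functional gradient-descent booster for the logistic loss
written for this package: per-iteration candidate base learners are
simple linear fits per covariate, df-4 smoothing splines for
precipitation and the rolling temperature/humidity means, and a
depth-2 regression tree over the thunderstorm and pollen variables
jointly (admitting their interactions); the single best candidate per
iteration enters the ensemble with learning rate 0.1. The iteration count
is a fixed, user-visible `mstop` (default 100) rather than an internal
cross-validation, keeping replicated runs cheap and reproducible.

Under the default weak-signal generator configuration — spike triggers
only probabilistically tied to the covariates — true-positive rates sit
well below 50%, reproducing qualitatively the finding that rare HAADs
resist covariate-based prediction; exact percentages depend on the data
and are not targets.

## Thunderstorm indicators and the ETS

The seven indicator definitions follow their operational sources: daily
lightning counts (storm day if strictly more than 2 strikes), gridded
lightning restricted to cells whose centres lie within 75 km of the
Melbourne GPO (any strike by default), the METAR `TS` weather group
(token-based: `TS`, `TSRA`, `+TSRA` count; `VCTS` only if vicinity
reports are enabled), observer "thunder heard" flags, sounding CAPE
strictly above 5 J/kg, a quorum rule for intense rain (at least 25% of
stations at 3 mm/h or more), and severe-storm archive reports within
75 km by the haversine distance on a 6371-km sphere. Days run
00:00--23:59 local, matching the admissions day.

Agreement is measured by the Equitable Threat Score

```
ETS = (H - He) / (H + M + F - He),   He = (H + M)(H + F) / n
```

which is 1 for perfect agreement, 0 for chance, and bounded below by
-1/3. When no events are observed or predicted the score is undefined
and reported as `NA` rather than 0, to avoid inflating agreement over
event-free periods. The test suite verifies the bounds by exhaustive
enumeration of all 2x2 tables up to n = 50 and the symmetry of the
pairwise matrix.

## HAAD characterisation

Over-representation of a condition among HAADs uses the chi-squared test
for equality of proportions without Yates correction by default — with
only 16 HAADs the correction is material, so the choice is carried in the
output and flippable. "Northerly winds over 15 km/h" is operationalised
as `NS < -15` under the wind convention above; on the packaged table this
reproduces the printed 56%. The packaged table's own thunderstorm column
gives 6/16 = 37.5% storm-day HAADs, below the 44% reported from a wider
storm definition in the source analysis; the discrepancy is inherent to
the differing storm definitions and the package does not force
agreement. Mean ages from five-year bins use midpoints (87.5 for 85+), an
accepted approximation for synthetic cohorts.

## Problem sizes and numerical choices in the test suite

The shipped tests simulate 2--12 years of daily data depending on what a
property needs (12 for four-peak resolution, 6 for classification, 4 for
the 50-replicate regression studies, 2--3 for smoke tests); the
acceptance script uses a 10-year end-to-end study and 20-replicate
regression studies. Quantile thresholds in the spike trigger are computed
within the pollen season. Ties in top-k selection break by date;
equality at the detection threshold counts as detection; the ETS
denominator guard is 1e-12; collinearity is declared at |r| > 1 - 1e-10.

## Known limitations

* The generator's independence assumptions (above) make trigger
  coincidences rarer than in nature; classification TPRs on synthetic
  data are not comparable to real-data values.
* The Gaussian rate-scale regression can predict negative rates for
  extreme covariates; a count-family option exists but is not the
  default, to match the reference methodology.
* The detector's z statistic has heavy tails on count data (see above);
  its threshold is a calibrated operating point, not a p-value.
* Confidence intervals for effect sizes ignore uncertainty in the
  covariate quantile.
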