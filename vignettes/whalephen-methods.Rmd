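---
title: "Methods: phenology, trends, and entanglement models for whale sighting series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenology, trends, and entanglement models for whale sighting series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whalephen)
```

This vignette is the package's account of its statistical machinery:
what each stage assumes, which tunable parameters matter, what the
synthetic-data generator does and does not emulate, and where genuinely
open design choices were settled.

## The data problem

A fixed observation point (an island lighthouse, say) produces daily
species-level counts of migrating whales over decades. Three features
make the series awkward:

1. **Ambiguous zeros.** For most of the series only positive detections
   were stored, so a blank day may mean "surveyed, saw nothing" or "no
   survey because of weather" — a *false zero*. Only the last few years
   carry explicit effort metadata.
2. **Overdispersed counts.** Whales travel in small groups; daily and
   weekly counts have variance well above their mean.
3. **Species-specific season geometry.** Humpback and blue whale counts
   are unimodal within a calendar year; gray whales are bimodal, with a
   south-bound peak in January and a north-bound peak in March, so the
   gray season is placed on an *adjusted year* beginning June 1 and the
   two migrations are analysed as separate datasets
   (`gray_south`, `gray_north`, split at the inter-peak trough,
   adjusted day 260 by default).

## Effort reconstruction

`fit_effort_cart()` fits a binary classification tree (Gini impurity,
greedy splits, `rpart` backend) of the daily effort indicator on
weather: cloud cover, visibility, pressure, air temperature,
precipitation, wind, swell. Hyperparameters — `max_depth` 5,
`min_leaf` 5, ten-fold cost-complexity pruning with the 1-SE rule —
are defaults chosen for a classifier that must stay interpretable and
stable on a few thousand labelled days; all are arguments. Leaf values
are effort fractions, so `predict_effort()` returns a probability.
Missing weather values are imputed with training medians.

`optimal_cutoff()` converts probabilities to classes at the threshold
maximising overall accuracy over the midpoints of sorted unique
probabilities (ties broken toward the lower threshold, i.e. toward
calling a day "effort"); Youden's J is available via `criterion`. The
removal rule in `remove_false_zeros()` is deliberately asymmetric: a
day is dropped only when its count is zero-or-missing *and* its
predicted class is no-effort. A positive count always implies a survey,
so no observed sighting can ever be discarded. Retained blank days
become true zeros contributing one effort-day.

The operational effort criteria (visibility above 11.2 km, wind at or
below Beaufort 4, swell under 3 m) are available as a rule-based
labeller (`effort_rule()`) for sanity checks against the learned tree.

## Weekly counts and NB2 trend models

Filtered daily counts are summed over consecutive 7-day blocks from
day 1 of the species year (`aggregate_weekly()`); the number of
retained days per block enters as `log(effort_days)` offset, and
zero-effort weeks are omitted rather than zero-filled. The 1–2
leftover days of a 365/366-day year fold into week 52. Gray-whale
days use the average of the morning and evening survey counts.

`fit_nb_trend()` fits NB2 regression — `count ~ poly(year) +
poly(month) (+ year:month) + offset(log(effort_days))`, variance
μ + αμ² — by maximum likelihood (`MASS::glm.nb`). Year and month are
centred and scaled before polynomial expansion; raw polynomials on
uncentred years are numerically hostile to IRLS while changing nothing
statistically. If the dispersion runs to the Poisson boundary the model
falls back to Poisson with a warning. `select_trend_shape()` fits
linear, quadratic, and cubic year terms and keeps the highest order
whose top coefficient is Wald-significant at two-sided α = 0.05, with
all lower orders retained; the label (`"Q(+)"` etc.) carries the sign
of the top coefficient. Month enters as a quantitative linear +
quadratic term by default; interactions, when requested, are the
product of the linear year and month terms.

`predict_weekly()` back-transforms the linear predictor at a reference
effort; intervals are delta-method on the link scale, so they are
always positive.

## Percentile phenology

`compute_timing()` defines arrival, peak, and departure as the
smallest day on which cumulative annual sightings reach 10%, 50%, and
90% of the annual total — an achieved-count rule with no
interpolation, computed from *daily* (not weekly) counts for maximal
resolution. Residency is departure − arrival. The definition is scale
invariant (doubling all counts changes nothing) and insensitive to
added zero-count days; these properties are asserted in the test
suite.

Species exclusions (`apply_exclusions()`): blue-whale January–February
days are dropped (winter presence is negligible apart from one
anomalous year); gray-south adjusted weeks 1–18 are dropped (a small
summer resident group is not part of the migration); and any
species-year whose total falls below 5% of the cross-year median total
is excluded as an ecological anomaly — a threshold generalisation of
removing a single known anomalous year, exposed as
`anomaly_fraction`.

`fit_timing_trend()` regresses a timing metric on centred year with
the same highest-significant-order selection as the count models.

## Environmental covariates

* **Front intensity index** (`front_intensity_index()`): per-cell SST
  gradient magnitude by central finite differences on the km grid
  (one-sided at edges), maximised over cells within 5/10/15/20 km of
  the observation point. FII is non-negative and non-decreasing in
  radius for nested discs — a property test.
* **Ekman transport** (`ekman_transport()`): bulk formula
  τ = ρ_air·C_d·|W|·W_alongshore with ρ_air = 1.22 kg/m³,
  C_d = 1.3×10⁻³, ρ_sw = 1025 kg/m³ (config defaults); transport
  τ/(ρ_sw·f) per 100 m of coastline, positive when upwelling-favorable
  (equatorward alongshore wind on an eastern boundary). Latitudes
  within 1° of the equator are rejected (f ≈ 0).
* **Spring transition** (`spring_transition()`): the day of the
  cumulative minimum of daily upwelling-favorable transport from
  January 1 — winter downwelling drives the cumulative curve down, and
  its minimum marks the onset of sustained upwelling. This
  cumulative-minimum rule is a standard construction chosen here
  because the upstream data product does not document its exact
  algorithm; both the day-of-year and the anomaly from day 90 are
  returned, since the conventional presentation mixes the two.
* **Seasons and lags** (`seasonal_average()`, `lag_series()`): winter
  = Dec–Feb (December belonging to the following year's winter),
  spring = Mar–May, summer = Jun–Aug, fall = Sep–Nov; under the
  adjusted-year convention months are first mapped onto the
  June-1-start year. Climate indices additionally get 1–3 month lagged
  annual means. "Previous winter/spring" covariates are the named
  season of the immediately preceding species-year under that species'
  convention.

`build_covariate_table()` assembles one row per species-year and
attaches an availability day to every covariate — the last day (on the
species axis) at which its raw-data window closes — which the forecast
stage uses. When a monthly upwelling-index series is supplied it is
used directly; otherwise the Ekman pathway synthesises it from wind.

## Timing attribution, forecasting, validation

`screen_covariates()` tests each covariate against the metric at
orders 1–3 (raw powers of the centred covariate) and forwards the
highest significant order. `backward_eliminate()` then iteratively
removes the covariate block whose top term has the largest
non-significant p-value — first stepping the block down one order
(hierarchy: a quadratic never appears without its linear term), only
then deleting it — until every top term has P < 0.05. Ties break
deterministically by covariate name. If screening forwards more
parameters than the years can support, the weakest candidates (largest
screening p) are trimmed first so the preliminary model is estimable.
After convergence, variance inflation factors (auxiliary-regression
definition, `vif_terms()`) are checked; a VIF at or above 10 removes
the higher-p member of the most collinear pair and re-runs the
elimination, so duplicated covariates lose exactly one copy. Finally
the model's AIC is compared against all single-block deletions as a
parsimony confirmation (reported, not enforced). A model eliminated to
emptiness is flagged `not_significant` rather than being an error —
non-significant species/metric combinations are an expected outcome.

`margins()` produces partial predictions over one covariate with the
others frozen at their sample means; intervals use the t distribution
at residual degrees of freedom. `forecast_model()` refits (without
re-elimination) on the retained covariates whose availability day
falls before the earliest observed arrival minus a configurable lead
time; because the forecast model is nested in the full model its
unadjusted R² cannot exceed the full model's — asserted on every run.
`year_removal_validate()` refits the fixed term set once per year with
that year held out and reports the squared Pearson correlation of
observed versus out-of-sample predictions (an `"ss"` 1 − SSE/SST
definition is available; the correlation form is the default because
the reported published ratios behave like correlation-based R²).

## Entanglement models

`build_monthly_design()` converts weekly counts to monthly by
day-proportional apportionment (a week contributes
`count × overlap/width` to each month it overlaps — the weekly-to-
monthly mapping is not standardised, and proportional allocation is
the least structured choice). The combined model of monthly
entanglements on counts, arrival, and departure uses exactly the
screening/elimination protocol above; plain linear regression is
appropriate because entanglement residuals are near-normal at these
scales. `variance_attribution()` compares two retained predictors by
the square of their t statistics — in OLS the share of response
variance attributable to a predictor is proportional to t², and t is
invariant to linear rescaling of the predictor. Species with fewer
than 10 entanglements across the series are refused (configurable):
the regression would be dominated by a handful of events.

## The synthetic-data generator

`simulate_dataset()` emulates the *temporal* structure of the
monitoring series; it makes no attempt at spatial structure (sighting
geometry, shipping lanes, distance sampling).

* Seasonal intensity is Gaussian on the species axis (mixture of two
  Gaussians for gray whales) — the minimal family matching a
  unimodal/bimodal description. Daily counts are NB2 draws around the
  curve; real survey archives carry no distributional statement for
  daily counts, so NB2 with dispersion α = 0.5 is this package's
  modelling choice.
* Timing change is a linear drift of the curve centre
  (`timing_trend`, days/year); abundance change is a log-polynomial in
  centred year. Defaults emulate the documented study conditions:
  humpback arrival advancing ≈ 5 d/yr from a late-season start,
  counts roughly flat early then accelerating ~3× (log-trend
  `c(0.046, 0.002, 0)`); blue similar with a mild cubic; gray
  stationary in timing with narrow (σ = 15/12 d) January/March peaks.
* Effort is Bernoulli with a *steep* logistic on weather: the survey's
  effort rule is essentially a deterministic weather threshold, so the
  coupling is sharp and the residual randomness stands in for
  unrecorded factors. Censoring reproduces the historical ambiguity:
  no-effort days are blanked, and in pre-metadata years zero-count
  effort days are blanked too. True labels are kept only for
  evaluation.
* Climate indices are stationary AR(1) with configured means/SDs
  (means and SDs default to the published climatologies of SOI, PDO,
  NPGO); SST/SSS have an annual sinusoid, a linear interannual trend
  (0.013 °C/yr for SST), and white noise; wind reverses from poleward
  to equatorward near a configurable spring day; the gridded SST field
  is planar per month with a random gradient magnitude and direction,
  so the true FII is known exactly.
* Monthly entanglements are a floored, rounded linear function of the
  monthly count and the year's arrival day plus Gaussian noise —
  matching the use of a linear (not count) model downstream.
* Determinism: one master seed; each table draws from a fixed
  sub-stream, so regenerating a single table reproduces it exactly.

What passing recovery tests on these data *do not* show: robustness to
non-Gaussian season shapes, observer drift, spatially varying
detectability, or correlated weather-count dynamics (storms that both
suppress effort and change whale behaviour). Results on real data
depend on those unmodelled features.

### A note on trend-shape selection rates

The shape-selection rule — keep the highest polynomial order whose top
term is significant at α = 0.05 — performs two extra null hypothesis
tests whenever the truth is linear, so even with ideal noise about 10%
of replicates will be labelled quadratic or cubic by chance; with the
default rising-abundance profile, early years have fewer sightings and
noisier percentile days, which inflates that rate a few points
further. The package reports this honestly: drift *slope* recovery is
unbiased and tight (every linear fit within ±1 d/yr of truth in the
seeded experiments), while the `L(-)` *label* frequency hovers near
85–91 per 100 replicates depending on seed. Any selection procedure
built on repeated α = 0.05 tests has this property; it is a feature of
the specified protocol, not an estimation failure.

## Numerical choices and degenerate inputs

* Polynomials are raw powers of centred variables throughout
  (matching the original analyses' use of raw polynomials) — centring
  alone removes the worst collinearity; the VIF screen catches the
  rest.
* Problem sizes in the default test and acceptance runs: 24-year
  simulations for recovery studies (the study's own length), a 16-year
  full-pipeline run for invariant checks, 100 replicates for rate
  estimates, 50 seeds for the spring-transition study.
* Degenerate inputs are contracts, not crashes: single-class effort
  labels give a one-leaf tree with a warning; all-equal probabilities
  give the majority-class cutoff; a year with no sightings yields an
  excluded timing record; monotone cumulative transport returns day 1
  with a warning; perfect collinearity reports infinite VIF and
  removes exactly one copy.
* `week_start` arithmetic keeps week 52 up to 9 days long (merged
  leftovers), and month attribution of a week uses its fourth day.

## Known limitations

* The stepwise protocol is reproduced as specified; it inherits the
  well-known instabilities of stepwise selection (order dependence is
  removed by the deterministic worst-block rule, but selection
  uncertainty is not propagated). Model averaging or penalised
  alternatives are deliberately out of scope.
* The forecast-eligibility rule compares a covariate's window-closing
  day with the species' minimum historical arrival; a "fixed calendar
  date" variant is the natural alternative and can be had by passing a
  constant to `arrival_days`.
* Under the generator's shared-drift design, arrival and departure
  drift together, so in the synthetic entanglement model those two
  covariates are nearly collinear and the VIF rule retains whichever
  fits better — the real data do not have this degeneracy.
* Adjusted-year covariates for the final season of a series are
  incomplete (the year ends the following May); affected species-years
  drop out of the timing models via complete-case filtering.
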