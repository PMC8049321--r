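# whalephen

Tools for analysing long-term daily sighting counts of baleen whales
(humpback, blue, gray) from a fixed coastal observation point, aimed at
marine ecologists and managers working with visual-survey time series:

* **Effort reconstruction** — historical sighting databases often record
  a count only when whales were seen, so a blank day is ambiguous
  between "no whales" and "no survey" (a *false zero*). A
  classification tree (CART) learns the association between daily
  weather and survey effort from the years with effort metadata, an
  optimal probability cutoff converts tree output into effort classes,
  and days with zero-or-missing counts *and* predicted no-effort are
  removed (`fit_effort_cart()`, `optimal_cutoff()`,
  `remove_false_zeros()`).
* **Abundance trends** — weekly summed counts are modelled with NB2
  negative-binomial regression (variance μ + αμ²) on polynomial year
  and month terms with log(effort days) as offset; the retained trend
  shape is the highest polynomial order whose top term is significant
  (`aggregate_weekly()`, `fit_nb_trend()`, `select_trend_shape()`).
* **Migration phenology** — arrival, peak, and departure are the days
  on which cumulative annual sightings first reach 10%, 50%, and 90% of
  the annual total; residency is departure − arrival. Gray whales use
  an adjusted year starting June 1 so the south-bound winter migration
  is not split across calendar years (`compute_timing()`,
  `fit_timing_trend()`).
* **Environmental attribution** — per species-year covariates (SST,
  SSS, front intensity index from gridded SST, upwelling index, spring
  transition from cumulative Ekman transport, and lagged SOI/PDO/NPGO
  climate indices) are screened univariately for linear/quadratic/cubic
  form and reduced by hierarchy-preserving backward elimination
  (P < 0.05, VIF < 10, AIC parsimony check), with margins-style partial
  predictions, pre-season forecast models, and leave-one-year-out
  validation (`build_covariate_table()`, `backward_eliminate()`,
  `margins()`, `forecast_model()`, `year_removal_validate()`).
* **Entanglement risk** — monthly confirmed entanglements are related
  to monthly whale counts and migration timing by linear regression,
  with each predictor's relative contribution quantified by the square
  of its t statistic (`build_monthly_design()`,
  `fit_entanglement_models()`, `variance_attribution()`).
* **Synthetic data** — a seeded generator (`sim_config()`,
  `simulate_dataset()`) reproduces the statistical structure of such a
  monitoring series (seasonal NB counts with timing and abundance
  trends, weather-censored effort, AR(1) climate indices, coupled
  entanglements) with known ground truth for recovery testing.

All user-facing functions take a data frame first and return tibbles;
fitted objects have broom-style `tidy()`/`glance()` methods and
`autoplot()` ggplot2 methods.

## Worked example

Run the whole pipeline on a 24-year synthetic dataset and inspect the
humpback results:

```r
library(whalephen)

cfg <- pipeline_config(sim = sim_config(n_years = 24, seed = 7))
res <- run_pipeline(cfg, "out")

res$trends$humpback$fit
#> NB2 weekly count trend: year degree 2 | alpha = 0.631 | AIC = 4151.5
#> Selected shape: Q(+)

timing <- readr::read_csv("out/timing.csv")
fit <- fit_timing_trend(dplyr::filter(timing, species == "humpback"),
                        "arrival_day")
fit
#> Timing trend (arrival_day): shape L(-), slope -4.23 d/yr, n = 24 years

str(res$forecast$humpback$departure_day[c("r2_full", "r2_forecast",
                                          "ratio_forecast_full",
                                          "r2_validation")])
#> $ r2_full            : num 0.932
#> $ r2_forecast        : num 0.932
#> $ ratio_forecast_full: num 1
#> $ r2_validation      : num 0.903
```

Weekly counts rise quadratically (`Q(+)`), arrival advances about 4
days per year (`L(-)`; the generator's configured drift for this
species is −5.2 d/yr), and the departure forecast model — built only
from covariates whose data window closes before the migration starts —
retains every term of the full model (ratio 1.0) and predicts held-out
years almost as well as the full fit (validation R² 0.90).

A command-line wrapper with per-stage subcommands is installed at
`inst/scripts/run_pipeline.R`:

```sh
Rscript inst/scripts/run_pipeline.R all --outdir out --seed 7
Rscript inst/scripts/run_pipeline.R trends --outdir out
```

## Vignette

`vignettes/whalephen-methods.Rmd` documents the models, the
synthetic-data generator's assumptions, numerical choices, and known
limitations.
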