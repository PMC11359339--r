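---
title: "A hierarchical model for kiwifruit flowering time: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hierarchical model for kiwifruit flowering time: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenocast)
library(dplyr)
```

## The problem

Kiwifruit orchard management — pollination hives, pest and disease control,
crop-load decisions — hinges on knowing when vines will flower. Flowering in
*Actinidia* follows a well-known thermal logic: winter chilling releases bud
dormancy, spring warmth then drives budbreak and, some weeks later, flowering.
`phenocast` implements a two-stage ("hierarchical") statistical pipeline that
turns hourly weather records and routine budbreak surveys into a prediction of
the **first flowering day** of individual vines, with an honest uncertainty
band:

1. **Stage 1 (budbreak).** For each vine, the cumulative count of broken buds
   is modelled against growing-degree-day (GDD) accumulation; the best of
   three curve families (chosen by AIC) is inverted to find the GDD at which
   the vine reached 5% of its total budbreak. That quantity, `BB`, is a
   per-vine summary of how early the vine woke up.
2. **Stage 2 (flowering).** The first-flowering day of year is regressed on
   cultivar and day-specific thermal covariates, including the stage-1 `BB`.
   Candidate predictor sets are compared by training-data AIC, the best is
   refined by stepwise AIC, and the final model is judged on held-out years
   by the width and the empirical coverage of its 99% prediction intervals.

The pipeline targets the two main New Zealand growing regions (Kerikeri and
Te Puke) and the two major cultivars ('Hayward' and the earlier-flowering
'Zesy002'). Because orchard phenology surveys of this kind are proprietary,
the package ships a synthetic-data generator with the same statistical
structure, so every stage is testable end to end.

## Thermal-time metrics

Three standard covariates are computed from hourly temperature series
(`thermal_summary()`):

* **GDD** (`accumulate_gdd()`): daily contribution
  $\max(0, \bar T_{\text{day}} - 7\,^\circ\mathrm{C})$, summed from 1 July
  (the Southern Hemisphere season start). Negative contributions are clipped
  by the usual degree-day convention; `clip = FALSE` disables this.
* **Chilling units** (`accumulate_cu()`): the count of hours at or below
  7 °C from 1 January. The threshold is inclusive ("at or below").
* **Daylength** (`daylength()`): astronomical day length from the
  refraction-corrected solar geometry (zenith 90.833°), via
  `geosphere::daylength()`.

The flowering covariates are these metrics read on **1 September** — a fixed
calendar date rather than an accumulation to each vine's own event date, which
would otherwise build the answer into the predictor (vines that flower later
trivially accumulate more heat). Days with more than 25% of their hourly
records missing raise a data-quality error naming the dates; the tolerance is
a package decision, since no standard rule exists for this kind of series.

## Stage 1: budbreak curves and the 5% inversion

`fit_budbreak_curves()` fits, per vine and season, against GDD accumulation:

* a **binomial** GLM (logit link) for the proportion of buds broken, with the
  vine's bud count as weights;
* a **Poisson** log-linear model for the broken-bud count;
* a **quadratic least-squares** model for the count.

All three report AIC and an $r^2$ defined as the squared Pearson correlation
between observed and fitted budbreak *proportions*, putting the families on a
common scale. `select_best_family()` takes the minimum-AIC fit, breaking ties
toward fewer parameters and then toward the binomial (the family with the
natural bounded-proportion interpretation).

`invert_at_5pct()` finds the smallest GDD at which the fitted curve reaches
5% of the vine's own final observed budbreak. The default target ("5% of the
total budbreak") uses each vine's final proportion; a switch
(`basis = "total_buds"`) targets 5% of all monitored buds instead. The
crossing is located by bisection to 0.01 degree-days after bracketing on a
512-point grid over $[0, 1.5 \times \text{max observed GDD}]$ — monotone-safe
for the GLM families and returning the smallest real crossing for the
quadratic. Curves that never reach the target inside that range are flagged
`extrapolated` and the vine is dropped from stage 2 with a warning; panels
with no budbreak at all (or saturated from the first survey) are flagged
`degenerate`.

## Stage 2: the flowering regression

The vine-year record joins the stage-1 estimate with the 1 September
covariates: `CV` (1 = 'Hayward', 0 = 'Zesy002'), `BB`, `DD` (GDD on 1 Sep),
`CU` (chilling hours on 1 Sep) and `DL` (daylength on 1 Sep). `BB`, `DD` and
`CU` enter the model **per 100 units** (`thermal_scale = 100`): coefficient
magnitudes then read as days per 100 degree-days, and the calibrated
reference coefficients below are on exactly this scale.

Nine candidate predictor sets (`candidate_specs()`), all containing `CV`, are
fitted with **full interactions** on the training years and compared by AIC;
the winner is refined by bidirectional stepwise AIC (`stepwise_refine()`,
via `MASS::stepAIC`, which respects marginality — an interaction is never
kept without its main effects). The refined model is reported with the `_1`
suffix, mirroring the convention of the original field calibration.

Two reference coefficient sets are built in
(`reference_flowering_coefficients()`), for use as the generator's truth and
as worked-example checks:

$$f_{\text{full}} = 312.7 + 15.1\,CV + 10.9\,BB - 3.3\,DD - 3.5\,CV{:}BB + 1.0\,BB{:}DD$$
$$f_{\text{orchard}} = 471.2 + 32.1\,CV + 0.09\,BB - 0.61\,DD - 0.06\,CV{:}BB$$

### Prediction intervals

`predict_with_interval()` uses
$\hat y \pm z \cdot \sqrt{\mathrm{SE}_{\text{mean}}^2 + \hat\sigma^2}$, with
$z$ the standard-normal critical value rounded to three decimals — 2.576 at
the 99% level (`interval_critical_value()`). Two deliberate choices:

* **The residual variance is included.** A mean-only standard error would
  give intervals a few days wide; the intervals of interest here are
  *prediction* intervals for a new vine, whose width is dominated by
  $2 z \hat\sigma$ (about 21 days at $\hat\sigma \approx 4.1$).
* **A normal, not a t, quantile.** With hundreds to thousands of training
  records the difference is negligible, and 2.576 is the conventional
  reported value.

Model comparison on the year split (`evaluate_year_split()`) reports, per
candidate, training AIC and $R^2$, the min/max interval width over the test
years, and the **coverage** — the percentage of test vines whose observed day
falls inside their own interval. `kfold_cv()` adds a seeded k-fold
cross-validation (k = 5 by default, so each training fold holds 80% of the
records), reporting the mean and range of held-out RMSE, $R^2$ and MAE.
`positional_analysis()` repeats the comparison on a single orchard with row
and bay added as categorical main effects, to ask whether within-orchard
position explains flowering variation (in both the original calibration and
our synthetic null, it mostly inflates interval widths).

## Classification baseline

`fit_flower_classifiers()` implements the presence/absence view: one
instance per vine per date on a 1 September – 31 December grid, labelled by
whether flowering has begun. A logistic regression and a 500-tree random
forest (seeded, via `randomForest`) are fitted on scaled-and-centered
numeric predictors, the scaling statistics always coming from the training
set. Orchard is never a predictor (train/test orchard sets need not
overlap). Two predictor modes exist because the day-specific covariates can
be read **on** 1 September (default) or accumulated **since** 1 September up
to the instance date; `confusion_table()` reports the four
prediction-by-outcome cells as percentages per region × cultivar, plus
overall accuracy, sensitivity and specificity. With the default
date-constant predictors the classifiers legitimately collapse toward the
majority class — the same weakness that motivates the regression pipeline.

## Descriptive ANOVAs

`anova_two_way()` runs region × cultivar ANOVAs (Type-II sums of squares,
via `car::Anova`) on **stratum-level** responses: the mean and the range of
first-flowering days per orchard-year-cultivar stratum
(`stratum_summaries()`). Stratum-level analysis keeps the residual degrees
of freedom at the scale of orchard-years rather than vines, matching how
such surveys are summarised. Terms with a sum of squares at floating-point
zero report F = 0 rather than an undefined ratio; factors observed at a
single level are dropped from the formula, which also makes the two-group
case reduce exactly to the squared two-sample t statistic.

## The synthetic-data generator

`synthetic_config()` + `simulate_dataset()` emulate the structure the
analysis assumes, not any particular orchard's data:

* **Weather**: hourly temperature = annual sinusoid (minimum at day-of-year
  196, mid-July) + diurnal sinusoid (amplitude 4 °C, peak 14:00) + AR(1)
  noise (ρ = 0.95, stationary sd 2 °C). Kerikeri (annual mean 15.5 °C,
  amplitude 4.0) is warmer in winter than Te Puke (14.5 °C, 5.5), so Te Puke
  accumulates more chilling — the regional contrast the analysis expects.
* **Budbreak**: bud *i* of a vine breaks when GDD crosses
  $G_i \sim \text{Logistic}(m_v, 1/s)$; the vine's midpoint $m_v$ is the
  cultivar's threshold ('Zesy002' 240, 'Hayward' 320 degree-days, slope
  0.05/GDD) plus a per-vine $N(0, 25)$ jitter. The jitter gives each vine
  its own true 5% GDD ($m_v + \mathrm{logit}(0.05)/s$), so stage-1
  estimation error propagates realistically into stage 2 — without it `BB`
  would be constant within cultivar and collinear with `CV`. Surveys record
  cumulative counts every 4 days (configurable to 3) over 40 buds per vine;
  bud counts for untreated vines are not published anywhere we know of, so
  40 is an invented, configurable default.
* **Flowering**: the linear predictor above (full-data coefficient set, BB
  and DD per 100 degree-days) plus $N(0, 4.5)$ days of noise, rounded, and
  kept inside the September–December window [244, 366]. The defaults give a
  ~17-day mean cultivar offset and within-stratum ranges of 15–20 days,
  consistent with the field behaviour of untreated vines; optionally the
  reported day is censored up to the next survey visit
  (`censor_flowering_to_survey`).

Everything is a deterministic function of the configuration: each
(region, year) and (vine, cultivar, year) slice derives its own sub-seed, so
datasets are reproducible and independent of generation order.

What the generator does **not** emulate: frost and other extreme events,
humidity or rainfall, spatial autocorrelation between rows (position carries
no signal by design), within-vine bud correlation, or between-year
persistence of individual vines. Passing tests therefore demonstrate that
the machinery is correct under the assumed structure — not that the model
generalises to any particular orchard's microclimate.

## Numerical choices and degenerate inputs

* Budbreak inversion: bisection tolerance 0.01 degree-days; AIC ties broken
  toward parsimony, then binomial.
* Stepwise: bidirectional, marginality-respecting; ties favour the smaller
  model. A null interaction survives AIC-stepwise with probability
  $P(\chi^2_1 > 2) \approx 0.16$ — property tests are calibrated to that
  rate, not to zero.
* Prediction far outside the training covariate range (beyond one full
  training span past either end) is flagged per record with a warning.
* Empty region × cultivar ANOVA cells, single-class classification
  training sets, all-zero budbreak panels, overlapping train/test years and
  sub-hourly gaps all fail fast with classed errors naming the offender.

## Problem sizes

The test suite exercises the full pipeline on 5 simulated years × 2 regions
× 2 cultivars × 3 vines, and the statistical properties on directly
simulated covariate records (500 training / 2000 test records for interval
coverage; 20 replicates of 500 for coefficient recovery; 25 replicates for
candidate selection; 50-vine panels for the budbreak stage). These sizes
give the property checks comfortable statistical resolution while keeping a
full run of the suite under a minute on a laptop.

## Interfaces

The package is function-first: tibbles in, tibbles out, so the pipeline
composes with dplyr, and `run_pipeline()` + `pipeline_config()` (or a YAML
file via `pipeline_config_from_yaml()`) reproduce the whole analysis in one
call, optionally writing every table to CSV. `autoplot()` methods cover the
prediction table, the candidate comparison and per-vine budbreak fits. No
shell entry point is shipped: the expected users work in R, and
`run_pipeline()` is the single-call surface a script would wrap.

## Known limitations

* Stage-2 standard errors treat `BB` as known, although it is itself an
  estimate; a measurement-error or mixed-effects extension would propagate
  stage-1 uncertainty formally.
* The chilling metric is a simple hour count below a fixed 7 °C; richer
  chill models (Utah, dynamic/chill portions) are deliberately out of scope.
* Prediction intervals assume homoscedastic Gaussian residuals; warm-winter
  seasons in recent field data suggest variance may drift.
* The generator's vines are independent across years; longitudinal
  vine-level persistence, which would let one year inform the next, is not
  modelled.
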