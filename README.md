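# phenocast

Hierarchical prediction of kiwifruit flowering time from weather data and
budbreak dynamics.

## What it does, and for whom

Orchard managers and phenology researchers need the date of first flowering
of kiwifruit vines (*Actinidia* 'Hayward' and 'Zesy002') ahead of time —
pollination hives, pest control and thinning are all scheduled against it.
`phenocast` implements a two-stage statistical pipeline from raw inputs a
grower can actually collect: hourly temperatures from the nearest weather
station and 3–4-day field surveys of broken buds.

**Stage 1 — budbreak.** Per vine, cumulative budbreak counts are fitted
against growing-degree-day accumulation (GDD, base 7 °C from 1 July) with
three curve families — binomial GLM, Poisson GLM and quadratic least squares
— selected by AIC, and the best curve is inverted to `BB`, the GDD at 5% of
the vine's total budbreak.

**Stage 2 — flowering.** The first-flowering day of year is regressed on
cultivar (`CV`, 1 = 'Hayward') and day-specific thermal covariates — `BB`,
plus GDD (`DD`), chilling hours (`CU`, hours ≤ 7 °C from 1 January) and
daylength (`DL`) read on 1 September. Nine candidate predictor sets with
full interactions are compared by training AIC, the winner is refined by
stepwise AIC, and the final model reports 99% prediction intervals

&nbsp;&nbsp;&nbsp;&nbsp; ŷ ± 2.576 · √(SE²ₘₑₐₙ + σ̂²)

whose empirical coverage is checked on held-out years, alongside k-fold
cross-validation, a presence/absence classification baseline (logistic
regression and random forests) and region × cultivar ANOVA summaries.

The calibrated full-data flowering model carried by the package (with `BB`
and `DD` in hundreds of degree-days) is

&nbsp;&nbsp;&nbsp;&nbsp; f = 312.7 + 15.1·CV + 10.9·BB − 3.3·DD − 3.5·CV:BB + 1.0·BB:DD

and a single-orchard variant (471.2 + 32.1·CV + 0.09·BB − 0.61·DD −
0.06·CV:BB) covers the within-orchard row/bay analysis.

Because orchard phenology datasets of this kind are proprietary, the package
includes a first-class synthetic-data generator (`synthetic_config()`,
`simulate_dataset()`) with the same statistical structure — sinusoidal + AR(1)
hourly weather for Kerikeri and Te Puke, logistic per-bud budbreak, and
flowering generated from the model above — so the whole pipeline is testable
and demonstrable without any field data.

## Worked example

```r
library(phenocast)

cfg <- synthetic_config(seed = 42, years = 2016:2021,
                        n_orchards_per_region = 2, n_vines_per_orchard = 4)
res <- run_pipeline(pipeline_config(synthetic = cfg, seed = 42))
res
#> <pipeline_result>
#>   records: 192  final model: CV.BB.CU_1
#>   final coverage: 100 %

tidy(res$year_split)
#> # A tibble: 10 × 6
#>    model      interval_min interval_max coverage_pct   aic r_squared
#>    <chr>             <dbl>        <dbl>        <dbl> <dbl>     <dbl>
#>  1 CV.DL              33.1         33.8        100    633.     0.651
#>  2 CV.DD              33.0         33.1        100    632.     0.656
#>  3 CV.BB              28.0         31.3         99.0  601.     0.750
#>  4 CV.CU              32.8         33.1        100    630.     0.661
#>  5 CV.BB.DD           27.6         34.4        100    601.     0.769
#>  6 CV.BB.CU           27.7         36.5        100    601.     0.770
#>  7 CV.BB.DL           28.0         35.9        100    605.     0.760
#>  8 CV.DD.DL           32.2         33.1        100    629.     0.692
#>  9 CV.CU.DL           32.0         38.6        100    627.     0.698
#> 10 CV.BB.CU_1         27.2         30.4        100    596.     0.768
```

Reading this: each row is one candidate predictor set, fitted with full
interactions on 2016–2018 and evaluated on 2019–2021. Candidates containing
the stage-1 budbreak estimate `BB` cut the 99% interval width from ~33 to
~28 days and lift training R² from ~0.65 to ~0.77 — the hierarchical signal
the pipeline exists to exploit. The AIC-best candidate is refined by
stepwise AIC into the final `_1` model (here dropping terms to reach AIC
596), and every interval still covers ~99–100% of the held-out vines. (Under
this small simulation `CU` and `DD` are nearly exchangeable proxies for
winter temperature, so either may appear in the winning set.)

Cross-validation of the final model and the per-vine predictions:

```r
res$cv[, 1:7]
#> # A tibble: 1 × 7
#>       k rmse_mean rmse_min rmse_max r2_mean r2_min r2_max
#>   <int>     <dbl>    <dbl>    <dbl>   <dbl>  <dbl>  <dbl>
#> 1     5      5.23     4.03     6.45   0.736  0.601  0.899

autoplot(res$year_split$final_predictions)  # observed vs predicted, 1:1 line
```

The generator itself is exercised the same way at any scale:

```r
w <- simulate_weather(cfg, "Kerikeri", 2020)         # 8784 hourly records
thermal_summary(w, season_start = "2020-07-01")      # GDD / CU / daylength per day
```

## Package layout

| Area | Functions |
| --- | --- |
| Synthetic data | `synthetic_config()`, `simulate_weather()`, `simulate_vine_phenology()`, `simulate_dataset()`, `simulate_flowering_records()` |
| Thermal time | `accumulate_gdd()`, `accumulate_cu()`, `daylength()`, `thermal_summary()` |
| Budbreak (stage 1) | `fit_budbreak_curves()`, `select_best_family()`, `invert_at_5pct()`, `estimate_budbreak()` |
| Flowering (stage 2) | `candidate_specs()`, `build_design()`, `fit_flowering_model()`, `stepwise_refine()`, `predict_with_interval()`, `evaluate_year_split()`, `kfold_cv()`, `positional_analysis()` |
| Classification | `build_classification_instances()`, `fit_flower_classifiers()`, `confusion_table()` |
| Descriptives | `stratum_summaries()`, `flowering_range()`, `anova_two_way()` |
| Pipeline & IO | `pipeline_config()`, `run_pipeline()`, `read_weather_csv()`, `write_phenology_csv()`, `pipeline_config_from_yaml()` |

Fitted objects support `tidy()`, `glance()` and `autoplot()`. The methods
vignette (`vignettes/flowering-hierarchy.Rmd`) documents the model, the
generator's assumptions, numerical choices and known limitations.
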