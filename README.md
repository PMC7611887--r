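# airshift

Quantifying how abrupt changes in urban mobility affect ambient air quality
and health. The package implements the full analysis chain used to study the
2020 UK lockdowns: re-normalisation of provider mobility indices against a
pre-pandemic baseline, aggregation of monitoring-station data to city-level
NO₂ and PM₂.₅ series, **weather-corrected counterfactual prediction** of what
concentrations would have been without mobility restrictions, rank
correlation of weekly mobility and pollution changes, and an
**attributable-fraction** health impact assessment. It is aimed at air-quality
and environmental-health analysts who want these steps as tested, seeded,
reusable functions rather than one-off notebook code.

## The core models

**Mobility normalisation.** Provider indices equal 1.0 on an arbitrary
reference day. They are re-centred on a 62-day pre-pandemic window
(13 January – 14 March 2020):

    m_norm(d) = m0(d) / m_pc − 1,   m_pc = mean of m0 over the window,

so the pre-pandemic mean of `m_norm` is exactly zero and the statistic is
invariant to rescaling of the raw index.

**Weather-corrected anomaly.** A counterfactual model — ordinary least
squares or gradient-boosted shallow trees (500 trees, depth 3, learning rate
0.05) — is trained on 2015–2019 daily concentrations with calendar features
(year index, day-of-week, day-of-year sine/cosine) and meteorological
features (temperature, precipitation, wind speed, same-day and lagged 3
days). The 2020 anomaly is

    100 × (mean observed − mean predicted) / mean predicted,

with a 95% interval from a moving-block bootstrap (7-day blocks, percentile
method) of the paired daily values.

**Health impact.** With β the relative risk per 10 µg/m³ (COMEAP values:
NO₂ 1.023, PM₂.₅ 1.060) and x the annual urban-background mean:

    RR = β^(x/10),   AF = 100 × (RR − 1) / RR.

AF confidence intervals propagate β's interval endpoints exactly (both maps
are monotone).

A synthetic-data module (`city_scenario()`, `gen_city_data()`,
`write_scenario()`) generates complete city datasets — seasonal AR(1)
weather, multi-year pollutant series with weekday cycles and lagged weather
dependence, a 2020 mobility record with two lockdown dips — with the
injected suppression recorded exactly, so every stage is validated against
known ground truth. See the methods vignette
(`vignettes/weather-corrected-anomalies.Rmd`) for the models, parameter
choices and limitations in detail.

## Worked example

```r
library(airshift)

sc  <- city_scenario(seed = 42)      # default synthetic city
dat <- gen_city_data(sc)

# 1) mobility: average transit reduction across the first lockdown
panel <- mobility_panel(dat$mobility)
lock1 <- baseline_window("2020-03-23", "2020-05-10")
average_reduction(panel[panel$mode == "transit", ], lock1)
#> transit, first lockdown: -86%

# 2) weather-corrected NO2 anomaly for 2020 (gradient boosting)
res <- anomaly_pipeline(dat$stations, dat$weather, "NO2",
                        station_scope = "all", model_kind = "gbr", seed = 42)
res$anomaly
#> <anomaly_result> observed 31.90 vs predicted 35.49 ug/m3: -10.1%
#>   (95% CI -12.4% to -8.0%, 366 days)
mean(unlist(dat$truth$realized_annual_suppression$NO2))
#> injected annual suppression: -10.2%

# 3) weekly mobility-pollution rank correlation
correlate_city(panel, res$weekly, "transit", "gbr_anomaly")
#> Spearman r_s = 0.87 (p = 4.8e-17, 51 weeks)

# 4) attributable fraction of all-cause mortality (urban-background scope)
means <- annual_urban_background_means(dat$stations, 2019:2020)
af_table(means[means$pollutant == "NO2", ])
#>       city pollutant year annual_mean   rr af_percent af_low af_high
#> 1 Avonford       NO2 2019        28.4 1.07       6.25   2.24    9.80
#> 2 Avonford       NO2 2020        26.2 1.06       5.78   2.06    9.07
```

Reading them together: transit use fell 86% during the first lockdown; 2020
NO₂ came in 10.1% below the weather-expected counterfactual, matching the
10.2% suppression the generator injected; weekly mobility and NO₂ anomalies
move together strongly (r_s = 0.87); and the NO₂-attributable fraction of
mortality drops from 6.25% to 5.78% between 2019 and 2020.

File-based workflows go through `run_config()` / `full_run()`, or the thin
CLI at `inst/cli/airshift.R` (`simulate`, `full-run` subcommands), which
write `anomalies.csv`, `correlations.csv`, `af_table.csv` and a metadata
sidecar per run.

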