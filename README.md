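# climsent

Spatiotemporal Poisson relative-risk modelling of climate and social-media
sentiment in R.

`climsent` is for quantitative researchers who want to ask, on a panel of
regions: *does weekly weather move the rate of negative sentiment expressed
online, and did an extreme event shift it?* It takes geotagged, timestamped
documents (or ready-made weekly count panels), weekly regional temperature
and precipitation, and a region adjacency graph, and produces per-category
covariate effect curves with 95% bounds and a map of before-to-during
relative-risk differences around an event, with significance flags.

## The model

Weekly negative counts are Poisson with the total volume as exposure:

```
NTw(i,t) ~ Poisson( theta_tot * TTW(i,t) * relrisk(i,t) )
log relrisk(i,t) = b0 + u(i,t) + f_temp[cat_T(i,t)] + f_precip[cat_P(i,t)]
```

where `theta_tot` is the dataset-wide negative proportion, `u` is a
separable space-time Gaussian Markov random field (intrinsic CAR / Besag on
the region graph in space, stationary AR1 in time) and the `f` blocks are
random effects over ordered covariate categories (temperature in four bands
with breaks 15/19/23 °C, precipitation in three with breaks 0.01/0.035 in
the covariate's native unit). Fitting is a constrained Gaussian (Laplace)
approximation with empirical-Bayes selection of the field precision — a
deterministic, sampling-free INLA-style fit implemented in the package. A
synthetic-data generator with known ground truth (region graphs, seasonal
climate with a planted flood-like event, overdispersed exposures, Poisson
counts from the model) makes every stage testable offline.

See `vignettes/climsent-methods.Rmd` for the full methods account.

## Worked example

```r
library(climsent)

# a fully synthetic study at the reference scale: 13 merged German federal
# states, 187 weeks from 2019-01-01, a 4-week high-precipitation event in
# four western regions carrying a +10% relative-risk bump
bundle <- simulate_bundle(params = true_params(), seed = 1)
bundle$panel
#> sentiment_panel: 13 regions x 187 weeks; total documents 14593323, negative 1451814 (9.9%)

model <- build_model(bundle$panel, bundle$climate, bundle$graph)
fit <- fit_risk_model(model)
fit
#> risk_fit: intercept 0.0091, field_tau 1000 (EB), lml -11934.5, 1 Newton iteration(s)
#>   f_temp  : -0.0095 -0.0075 +0.0025 +0.0145
#>   f_precip: -0.0037 -0.0045 +0.0082

effect_summary(fit, "temperature")[, c("label", "pct", "pct_lower95", "pct_upper95", "significant")]
#>     label        pct pct_lower95 pct_upper95 significant
#> 1     low -0.9414537   -1.845394 -0.02918816        TRUE
#> 2     mid -0.7423951   -1.295768 -0.18591977        TRUE
#> 3 average  0.2460404   -0.334810  0.83027604       FALSE
#> 4    high  1.4558352    0.489141  2.43182896        TRUE

rr <- rr_difference(fit, event_windows())
rr[rr$region %in% c("NW", "RP", "SL", "HE"), c("region", "pct", "pct_lower95", "pct_upper95", "significant")]
#>    region      pct pct_lower95 pct_upper95 significant
#> 8      HE 6.318403   3.2686339    9.458239        TRUE
#> 9      NW 6.093801   2.3778774    9.944598        TRUE
#> 10     RP 7.177493   3.8760663   10.583847        TRUE
#> 11     SL 4.947203   0.1314402    9.994576        TRUE
```

Reading the output: the `pct` columns are percent relative risk,
`exp(log-RR) - 1`. The warmest temperature band carries a significantly
positive effect (+1.5%, truth +1.6% after centering) and the cooler bands
significantly negative ones; the exposed regions' before-to-during contrast
recovers most of the injected +10% bump (a Gaussian field prior shrinks
abrupt excursions; see the vignette's limitations section), and all four
exposed regions are flagged significant.

The same pipeline runs from files and one configuration object:

```r
cfg <- run_config(seed = 1, simulate = TRUE)   # or paths to docs/panel/climate CSVs
run_pipeline(cfg, out_dir = "run1")            # writes CSV/JSON artifacts + log
```

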