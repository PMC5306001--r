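# nestveg

Simulation tools for a methodological question in avian nesting ecology:
**when should nest-site vegetation be measured?** Grassland vegetation
grows through the nesting season, so a protocol that measures failed
nests on the day they fail and successful nests at fledging mechanically
records shorter vegetation at failed nests — manufacturing an apparent
"vegetation effect" on nest survival even when none exists. `nestveg`
quantifies that bias for four common measurement protocols by simulating
the whole pipeline — vegetation growth, daily nest survival, observer
visits — and fitting the models a field analyst would fit.

It is aimed at nesting-ecology researchers choosing a field protocol,
and at quantitative ecologists studying covariate measurement-timing
bias in discrete-time survival models.

## The model

Average canopy height follows a Michaelis–Menten curve
`ACH(t) = a·t / (b + t)` with nest-specific `a ~ N(1 m, 0.15)` and
`b ~ N(15 d, 3)`. A nest of age *u* on day *t* survives a daily
Bernoulli trial with probability

```
logit(φ) = β₀ + β₁·ACH(t) + εᵢ,   εᵢ ~ N(0, 0.05)
```

where `β₀ = logit(0.35^(1/28)) ≈ 3.2646` fixes baseline 28-day nest
success at 35%, and the true vegetation effect `β₁` takes values
`0, ±0.1, ±0.2, ±0.3`, crossed with Early/Late initiation timing
(14 scenarios). Observers enter at a random nest age and visit every
3 days; nests never seen active are left-truncated out. Each dataset's
encounter history is fitted with the **logistic-exposure model**
(Shaffer 2004) — a binomial GLM with link `η = logit(p^(1/t))` so an
interval of `t` days contributes `φᵗ` — once per measurement protocol:

* Method 1: ACH at initiation
* Method 2: ACH at termination, whatever the fate (the common protocol)
* Method 3: ACH at actual/estimated completion for every nest
* Method 4: Method 2 plus initiation date as a covariate

Bias is `|β̂_ACH − β₁|`; models are ranked by AIC per dataset.

## Worked example

```r
library(nestveg)

set.seed(1)
d <- simulate_dataset(scenario_config(beta1 = 0, skew = -15))
fit <- logexp(survived ~ ach_m2, d$history)
summary(fit)
#>             Estimate Std. Error z value  Pr(>|z|)
#> (Intercept)  0.53226    0.51196  1.0396    0.2985
#> ach_m2       3.98997    0.73618  5.4199 5.965e-08 ***
#> Intervals: 1574 (370 nests); logLik -468.989; AIC 941.98; irls
```

The true vegetation effect in this dataset is **zero**, yet the
termination-timed covariate (Method 2) yields a strongly "significant"
positive coefficient of 3.99 — the measurement-timing artifact the
package exists to expose. Running the full design:

```r
study <- run_study(study_design(seed = 1), replicates = 25)
study
#> Measurement-timing study: 14 scenarios x 25 replicates
#>   nests observed per dataset: mean 360.4 (range 289-421)
#>   mean absolute bias across scenarios:
#>     method1  0.516
#>     method2  1.883
#>     method3  0.522
#>     method4  1.927
```

Methods 1 and 3 (consistent timing) carry a quarter of the bias of
Methods 2 and 4 (fate-dependent timing); `study$summary` breaks this
down per scenario with confidence intervals and AIC selection
frequencies, and `plot(study, skew = -15)` draws the bias profile.
See `vignette("measurement-timing-bias")` for the model details and
the design choices.

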