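# smokelag

Exposure–lag–response modelling of smoking prevalence and lung cancer
incidence with distributed lag non-linear models (DLNMs).

## The problem

Changing the proportion of smokers in a population changes lung cancer
incidence, but with a delay that is neither fixed nor linear: the effect of
a prevalence change depends jointly on how large the change is and on how
long ago it happened. `smokelag` is for epidemiologists and policy analysts
who want to estimate that bidimensional *exposure–lag–response* from
registry-style incidence data (counts and person-years by country,
registry, 5-year age band, gender and outcome year) joined to a complete
lagged history of smoking prevalence (%, lags 0–30 years), and then ask
"what-if" questions such as *what does lowering prevalence from 50% to 40%
for a decade do to the incidence rate?*

## The model

For demographic stratum *i* observed in year *t*,

```
Y_it ~ NegBin(mu_it, theta)
log(mu_it) = alpha + log(P_it) + beta' S_itl + gamma' C_it + delta' A_it
             + eta G_it + lambda' O_it + nu' A_it G_it
```

* `Y_it` — lung cancer cases; `P_it` — person-years at risk (offset).
* `S_itl` — a **cross-basis** row: the tensor product of a restricted
  cubic (natural) spline basis over exposure (df 4) and one over lag
  (df 4, lags 0–30), summed over the stratum's 31-value exposure history.
  Exposure histories are cohort-matched: the lag-`l` exposure of an age
  band is the prevalence of the band that same birth cohort occupied `l`
  years earlier.
* The lag basis has **no intercept and is anchored at lag 0**, so the
  incidence rate ratio (IRR) is exactly 1 at lag 0: a prevalence change
  has no same-year effect.
* `C`, `A`, `O` — country, age-band and outcome-year fixed effects;
  `G` — gender (1 = male); `A G` — age-by-gender interaction.
* Estimation is full maximum likelihood (IRLS alternated with univariate
  ML for `theta`); standard errors use a **registry-clustered sandwich**
  covariance (CR1).

Effects are reported from the backward perspective as
`IRR(x, l) = exp{[b(x, l) - b(x0, l)]' beta}` against a reference
prevalence `x0` (default 50%), and cumulatively as
`IRR_cum(x, h) = exp(sum_{l<=h} log IRR(x, l))` with full delta-method
intervals. Model checking uses simulation-based scaled (quantile)
residuals; candidate models (with/without interaction, df 4 vs df 3) are
compared by AIC.

A registry-structured synthetic-data generator (`sim_config()`,
`simulate_study()`) draws smooth bounded prevalence trajectories and NB
counts from a known true surface, so the whole pipeline is testable
without any external data.

## Worked example

```r
library(smokelag)
cfg <- sim_config(n_countries = 20L, registries_per_country = 2L, seed = 1L)
sim <- simulate_study(cfg)                       # 1920 strata
design <- build_design(sim$strata, sim$cross_basis)
fit <- fit_negbin(design)
robust <- cluster_sandwich(fit, design)
surface <- predict_surface(fit, sim$cross_basis, vcov = robust)
surface
#> IRR surface: exposure 1..81% (81) x lag 0..30 (31), reference 50%
#>   min IRR 0.836 at 81% / lag 17; max IRR 1.277 at 81% / lag 30

scenario_irr_cum(fit, sim$cross_basis, reference = 50,
                 new_prevalence = 40, horizon = 10, vcov = robust)
#>    year prevalence irr_cum   low  high
#> ...
#> 11   10         40   0.821 0.777 0.869

fit_candidate_set(sim$strata, sim$histories)$aic_table
#>                model n_par   loglik     aic delta_aic
#> 1               full    54 -10391.4 20890.8    0.0000
#> 2     no_interaction    47 -10436.7 20967.5   76.7003
#> 3                df3    47 -10438.9 20971.9   81.1050
#> 4 df3_no_interaction    40 -10481.4 21042.8  152.0719
```

Reading it: holding prevalence at 40% instead of the 50% reference for 10
years multiplies the incidence rate by 0.821 (95% CI 0.777–0.869) — an
estimated 18% reduction in this synthetic world. The AIC table ranks the
four pre-specified candidate models; here the full model (df 4 splines
plus the age-by-gender interaction, which is how the data were generated)
wins decisively.

The same analysis runs end to end from a config via `run_pipeline()` or
the CLI wrapper (`inst/cli/smokelag`), with subcommands `simulate`, `fit`,
`predict`, `scenario` and `diagnose`, writing CSV tables, a YAML fit
bundle, optional PNG figures, a log and a checksum manifest.

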