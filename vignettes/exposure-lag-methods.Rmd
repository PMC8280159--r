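---
title: "Methods: distributed lag non-linear modelling of smoking prevalence and lung cancer incidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exposure-lag-response modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokelag)
```

## The model and its assumptions

`smokelag` estimates how lung cancer incidence in a population responds to
its smoking-prevalence history. The statistical unit is a demographic
stratum: a (country, registry, 5-year age band, gender) group observed in
one outcome year, with case count $Y_{it}$ and person-years at risk
$P_{it}$. The model is a negative binomial (NB2) GLM with log link,

$$\log \mu_{it} = \alpha + \log P_{it} + \boldsymbol\beta' S_{it,l}
  + \boldsymbol\gamma' C_{it} + \boldsymbol\delta' A_{it} + \eta G_{it}
  + \boldsymbol\lambda' O_{it} + \boldsymbol\nu' A_{it} G_{it},
  \qquad \mathrm{var}(Y) = \mu + \mu^2/\theta,$$

where $S_{it,l}$ is the DLNM cross-basis: a natural-spline basis over the
exposure axis (smoking prevalence, %) tensored with a natural-spline basis
over lag (years since exposure), summed over the stratum's complete lagged
exposure history $x_{t-l}$, $l = 0,\dots,30$. The coefficient vector
$\boldsymbol\beta$ therefore parameterises a smooth bidimensional
exposure–lag surface; all other terms are fixed-effect adjustments
(country, age band, outcome year, gender and an age-by-gender
interaction) that standardise the predicted effects.

Key assumptions: counts are conditionally NB2 given the linear predictor;
the exposure–lag response is common to all strata (no effect modification
by the covariates); exposure histories are complete and measured on the
same [0, 100] scale everywhere; and strata are independent *between*
registries, while arbitrary correlation *within* a registry is absorbed by
the clustered sandwich covariance rather than the likelihood.

Exposure histories are *cohort matched*: the lag-$l$ exposure of an age
band with lower bound $a$ in outcome year $t$ is the panel prevalence of
the 5-year band containing $a - l$ in calendar year $t - l$, i.e. the band
the same birth cohort occupied $l$ years earlier. Lags that are not
multiples of 5 fall inside a band; no interpolation is invented. This is
why the prevalence panel must extend 30 years before the earliest outcome
year and down to the 10–14 band.

## The lag-0 constraint

Changing the proportion of smokers cannot plausibly change lung cancer
incidence within the same year. Two mechanisms enforce this exactly:

1. the lag basis carries **no intercept**, so no lag-constant effect of
   exposure exists;
2. every lag-basis column is **anchored** — shifted by its value at
   $l = 0$ — so each column evaluates to 0 at lag 0.

Anchoring shifts each column by a constant, which only re-routes a
lag-constant contribution into the model intercept: the likelihood,
fitted values and all contrasts are unchanged. What it buys is exactness:
the predicted log-IRR at lag 0 is identically zero for every exposure
level (machine precision, asserted in the acceptance tests), instead of
approximately zero by parameterisation accident. The anchoring detail is
package configuration, not an external prescription; only the intercept
exclusion is externally given.

## Spline bases and knots

Both bases are restricted cubic (natural) splines: piecewise cubics,
continuous through second derivatives, constrained linear beyond the
boundary knots. With $k$ total knots a basis contributes $k-1$ parameters
(besides the intercept), so the default df 4 means 5 knots. The
implementation wraps the standard B-spline-projected natural spline
(`splines::ns`); the test suite checks its column space against an
independent truncated-power construction, so any basis with the same span
would be an acceptable substitute.

Knot placement (externally unspecified, so package defaults):

* **exposure axis** — boundary knots at the observed min/max of all
  history values, interior knots at equally spaced quantiles of those
  values (the conventional default);
* **lag axis** — boundary knots at 0 and 30, interior knots equally
  spaced on the $\log(\mathrm{lag}+1)$ axis (`scale = "log-lag"`),
  concentrating flexibility at short lags as is standard DLNM practice
  (df 4 puts them near lags 1.4, 4.6 and 12.1). Identity-scale placement
  is available by configuration. Note that placing knots at *quantiles*
  of the log-transformed lag values would be equivalent to identity-scale
  placement (quantiles commute with monotone transforms), which is why
  the log-lag scale uses equally spaced *values* instead.

## Estimation and inference

Coefficients and dispersion are estimated by full maximum likelihood:
IRLS (Fisher scoring with working weights $\mu\theta/(\mu+\theta)$) at
fixed $\theta$, alternated with a univariate golden-section ML step for
$\log\theta$ on $[\log 10^{-3}, \log 10^{8}]$, until the relative
log-likelihood change falls below $10^{-8}$ (at most 50 outer cycles;
non-convergence is flagged, not thrown). Initialisation is a Poisson fit
plus a moment estimate of $\theta$. On equidispersed data $\theta$ runs to
its upper bound and the fit reproduces the Poisson GLM; on NB data the
fit agrees with `MASS::glm.nb` to ~1e-7 (test-verified).

* **Model-based covariance**: inverse *observed* information at
  $(\hat\beta, \hat\theta)$, with $\theta$ held fixed.
* **Robust covariance**: CR1 cluster sandwich over registries —
  bread = model covariance, meat = summed outer products of
  cluster-summed scores, small-sample factor $G/(G-1)$. With singleton
  clusters this reduces to HC0 times $n/(n-1)$.
* **AIC** counts $\theta$ as a parameter: $-2\ell + 2(p+1)$. The
  pre-specified candidate set is full / no interaction / df 3 splines /
  both.

IRR predictions are contrasts against a reference prevalence (default
50%, chosen to sit mid-range of the observed histories; the reference
must lie inside the exposure boundary knots, otherwise a warning is
raised and the linear tails are used). Cumulative IRRs sum log-IRRs over
lags 0..h inclusive — lag 0 contributes nothing under the constraint, so
the inclusive/exclusive reading of "previous lags" is numerically moot —
and their variance uses the summed contrast vector $w' V w$ (the full
delta method; summing pointwise variances would ignore the strong
covariance between adjacent lags). Intervals are normal-approximation,
$z = 1.959964$ at 95%. Default prediction grids are exposure 1–81% by 1
and lag 0–30 by 1, matching the extremes at which results of this design
are conventionally reported.

Scenario tables interpret a prevalence path prospectively: in scenario
year $h$ the exposure at lag $l$ is the path value $h-l$ years after the
change, and the pre-change population sits at the reference (zero
contrast). A constant path therefore reproduces the cumulative IRR at
each horizon, which is the tested contract.

## Diagnostics

Scaled (quantile) residuals place each observed count within `n_sim`
(default 250) draws from its fitted NB distribution, with randomised
ranks across ties — the randomised PIT, uniform on (0, 1) under a correct
model. Each stratum's draws come from an RNG sub-stream keyed by a hash
of (seed, stratum id), so residuals are reproducible bit-for-bit and
invariant to row order. Uniformity is summarised by a Kolmogorov–Smirnov
test and a QQ table against plotting positions $(i-0.5)/n$.

## What the synthetic generator emulates — and what it does not

Defaults state a world at the scale of the real study design: 43
countries × 2 registries, eight age bands (40–44…75–79), two genders,
outcome years 2010–2012 (2064 strata), lag 0–30, prevalence panel
1980–2012 down to the 10–14 band, NB dispersion $\theta = 5$. Prevalence
trajectories are mean-reverting AR(1) walks (long-run levels ≈ 42%
male / 22% female with band-level spread 8, $\phi = 0.95$, annual
innovation 1.2 points) reflected into [0, 100] — smooth, bounded, and
wide enough to cover the 50% reference. Baseline rate and age/gender
effects are anchored to the order of magnitude of published registry
tables (incidence ≈ 1e-4…5e-3 per person-year, rising ~30-fold across
the age range, male excess growing with age); stratum person-years are
log-normal around 2.1e5. The default true surface is a damped wave —
sign set by the prevalence increment, inverted-U then U across lag, zero
at lag 0 and at 50% — projected onto the model's own cross-basis so the
truth is exactly representable and recovery can be tested sharply; an
arbitrary coefficient vector can be supplied instead.

Deliberately **not** emulated: real-world correlation between prevalence
levels and country effects (confounding), measurement error in modelled
prevalence estimates, registry churn and incomplete series, harvesting
dynamics (depletion of susceptibles — in the generator any protective
segment of the surface is simply part of the stated truth, not an
emergent population artefact), and calibration of any particular country.
A green recovery test therefore establishes internal statistical
correctness of the estimator under its own assumptions, not the
epidemiological validity of a real-data estimate.

## Numerical choices and degenerate inputs

* IRLS linear predictor capped at 700 before exponentiation; overflow
  raises a diagnostic error (separation).
* Rank-deficient designs error naming the aliased columns; single-level
  factors contribute no dummies (reference levels are recorded in the
  fit).
* Degenerate (constant) knot ranges and tied quantile knots error out
  rather than silently collapsing basis dimensions.
* Null contrasts (reference exposure, lag 0) have exactly zero
  delta-method variance; interval endpoints collapse to 1.
* The YAML fit bundle stores coefficients and covariances at 17
  significant digits, so bundle round-trips reproduce predictions to
  1e-10.

## Known limitations

* No penalised-spline or GAM variant, no two-stage meta-analytic pooling,
  no multiple simultaneous cross-bases, no absolute-risk measures — all
  out of scope by design.
* Wald intervals can undercover for extreme contrasts at small cluster
  counts; no bootstrap alternative is provided.
* AIC model selection is honest only across the packaged candidate set
  on identical data (enforced by a data fingerprint); it is not a
  general-purpose model search.
* Headline real-data quantities (surface extremes, the 50→40% scenario)
  are reproducible only with the proprietary registry and prevalence
  extracts; the package ships none of that data and the acceptance
  machinery exercises constraint exactness and simulation-based recovery
  instead.
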