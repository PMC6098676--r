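---
title: "Methods: PFC as a population-level reproductive indicator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PFC as a population-level reproductive indicator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfctools)
```

## The indicator and its problem

The proportion of females calving (PFC) — annual births divided by the
number of adult females — is attractive for monitoring megaherbivore
populations because it needs far less data than individual-level measures
such as inter-birthing intervals (IBI) or age at first reproduction (AFR).
For asynchronous breeders whose IBI exceeds a year, however, only a
fraction of adult females is available to calve in any year, which induces
negative autocorrelation in the annual series; and in small or recently
reintroduced populations, demographic stochasticity and *founding effects*
(synchronised first calvings of an introduced cohort) produce large
fluctuations that are easy to misread as density feedback or environmental
forcing. This package implements the full chain needed to compute PFC from
life histories, model it as a short autoregressive time series with
physical covariates, and — via an individual-based simulator — quantify how
much variation and how many false covariate signals pure demographic noise
produces.

## From life histories to PFC

A female is **adult** once she has calved, or on reaching seven years
without calving. For a year's denominator we count every female who was
alive as an adult during *any part* of the year (including those maturing,
dying or exported mid-year); the numerator is the number of births dated in
that year. With a 15-month gestation a female cannot calve twice in one
calendar year, so `births <= adult_females` always, and PFC is a proportion.
Years with no adult female present raise an explicit error rather than
returning 0 or `NaN`.

Census emulation needs two conventions the PFC definition itself does not:
a calf/subadult boundary (default 3.5 years) and a male adulthood age
(default 7, mirroring females). Census rows are end-of-calendar-year
compositions, which is what makes year-end totals change only through
births, deaths and imports/exports. Imported animals of unknown birth date
receive a nominal age at entry (stage midpoints: calf 1.75 y, subadult
5.25 y; adults a working value of 10 y) and are flagged `birth_imputed`;
these ages only matter for later stage transitions, never for PFC itself.

The packaged `rhino_census()` table records a closed black rhinoceros
population reintroduced into 220 km^2 of the Great Fish River Reserve,
growing from 3 year-end founders in 1986 to 110 animals in 2008, with 23
surviving introductions through 1997 and five subadults removed in 2006.
Two of its rows (1998 and 2005) print a PFC whose denominator exceeded the
year-end adult-female count by one — exactly what the part-year rule
produces when an adult female is present for only part of the year. The
integer-recovery helper `births_from_census()` accepts both rows under its
`0.5/n` consistency bound.

## Transformation

Proportions are variance-unstable near 0 and 1. Besides the standard
`asin(sqrt(p))`, the package computes a count-based modification,

$$z(x, n) = \tfrac12\left[\arcsin\sqrt{\tfrac{x}{n+1}} +
\arcsin\sqrt{\tfrac{x+1}{n+1}}\right],$$

which never touches the boundary values and behaves better for the extreme
proportions that one-adult-female years produce. Because it needs counts,
not rounded proportions, the analysis recovers integer numerators from a
published census with `births_from_census()` and pairs them with the
adult-female column. The transformed series `z` is the modelling response
throughout.

## The autoregressive model

The ACF/PACF of the transformed series (partial autocorrelations computed
by the Durbin–Levinson recursion, significance bounds $\pm 1.96/\sqrt{n}$)
point to the first two lags, so the global model is an AR(2) regression

$$z_t = b_0 + b_1 z_{t-1} + b_2 z_{t-2} + c_1\,\mathrm{density}_t +
c_2\,\mathrm{rain}_t + c_3\,\mathrm{rain}_{t-1} + \varepsilon_t,
\qquad \varepsilon_t \sim N(0, \sigma^2).$$

Density is the previous year-end total divided by the reserve area (220
km^2); rain is the calendar-year rainfall total and rain_1 its one-year
lag. The three physical covariates are centred and scaled (sample SD) over
the modelling window; the lagged responses are left on their own scale so
their coefficients read as autoregressive weights. A one-year-lagged
density is computed for diagnostics only: in a monotonically growing
population it correlates with density at 0.99 and adds nothing as a model
term.

**Fitting convention.** The likelihood is *conditional* Gaussian ML: the
first two observations serve as fixed initial lags and every candidate
model is fit to the identical response window (20 responses on the packaged
census, 1989–2008). Coefficients solve the least-squares normal equations;
$\hat\sigma^2$ uses the ML divisor $n$ while coefficient SEs use the
unbiased divisor $n-p$; $k$ counts the intercept, the slopes and
$\sigma^2$. A state-space (exact) likelihood handles the initial conditions
differently and can shift AICc values by a few tenths, which is why the
package's comparisons against externally fitted rankings carry a ±0.5
allowance. A shared window is non-negotiable: information criteria are only
comparable across models fit to the same responses.

**Model set and multi-model inference.** All $2^5 = 32$ subsets of
{lag1, lag2, density, rain, rain_1} are ranked by
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$, with Akaike weights
$w_i \propto e^{-\Delta_i/2}$. Ties are broken by fewer parameters, then by
term labels. The confidence set is the smallest weight-ordered prefix
reaching 0.95. Coefficients are model-averaged *naturally* — over the
confidence-set models containing the term, with renormalised weights —
rather than by zero-substitution, and the unconditional SE
$\sum_i w_i\sqrt{\mathrm{var}_i + (\theta_i-\bar\theta)^2}$ folds in
between-model spread. Relative importance sums weights over all ranked
models containing the term. When no rainfall series is available the
machinery runs on the 8 rain-free subsets and reports say so explicitly;
annual rainfall is rarely published alongside census tables, so this
restricted mode is the default for the packaged data.

**Degenerate inputs.** Exact interpolation (zero residual variance) is
caught and returned with infinite log-likelihood rather than a crash;
collinear designs and windows shorter than the coefficient count raise
errors; a constant covariate fails standardization with a clear message.

## Moving averages

Moving averages suppress the short-term fluctuation that the
autocorrelation structure predicts. The package uses trailing full-window
means; the dispersion of the smoothed series does not depend on the
alignment. Two conventions matter:

* **Dispersion divisor.** The headline dispersion of both the raw PFC
  series and each smoothed series is the population (divisor $n$) SD; on
  the packaged census this gives 0.24 for the raw series and 0.063/0.016
  for the 3- and 11-year windows. The sample-SD versions (0.25, 0.065,
  0.017) are reported alongside.
* **Window set.** The default windows are the odd sizes 3, 5, 7, 9, 11 —
  the centred-moving-average convention for annual series. Over this set
  the dispersion declines strictly monotonically on the packaged census;
  including even windows introduces sub-0.001 upticks (window 7 to 8 and 9
  to 10) because consecutive window lengths weight the two extreme years
  (2000 and 2001) differently.

The du Toit benchmark bands for "% of cows with calf of the year" are
packaged as `[0, 0.29)` very poor–poor, `[0.29, 0.33)` poor–moderate,
`[0.33, 0.40]` moderate–good, `(0.40, 1]` good–excellent; 0.40 itself is
deliberately *not* good–excellent, since that rating requires exceeding the
0.4 threshold.

## The individual-based simulator

`simulate_population()` generates complete life histories for a closed,
reintroduced population so that every stage of the pipeline can be tested
on data whose generating process is known exactly.

* **Clock.** Monthly steps (gestation and IBI are naturally expressed in
  months), with event days jittered uniformly within the month. Because
  registry dates are whole calendar days, validation of the 15-month
  gestation bound allows one day of rounding slack.
* **Reproduction.** The IBI is gestation (15 months) plus a post-calving
  wait drawn from a gamma distribution shifted by `ibi_min_months -
  gestation` (default shift 1 month), with shape and scale solved from the
  target IBI mean 29.0 and SD 7.9 months (the SD implied by a reported SE
  of 0.9 over 77 intervals). The distribution family is a modelling choice;
  only the mean and SD are constrained by data. Setting `ibi_sd = 0` makes
  the interval deterministic, which the tests exploit.
* **First reproduction.** `afr_years` (default 7) is the *expected* age at
  first calving: nulliparous females begin their first conception wait
  early enough that the mean first calving lands at 7 years. Realized mean
  AFR across replicates is ≈ 6.95 y.
* **Covariate injection.** Each waiting female's effective clock advances
  by `exp(density_effect * density + rain_effect * rain_anomaly)` months
  per month. With zero injectors (the default) reproduction is strictly
  independent of both covariates, so any covariate signal recovered
  downstream is false by construction; with injectors the same machinery
  produces genuine density feedback or rainfall forcing. Note that an
  effect on *conception* surfaces in *births* roughly 15 months later, so
  an injected rainfall effect loads on the prior-year rain term.
* **Mortality.** Stage-specific annual survival (calf 0.95, subadult 0.97,
  adult 0.97) are calibration constants chosen so the realized import-free
  growth rate sits near the 0.10 that a healthily expanding population of
  this kind shows; they are not measured vital rates.
* **Growth measurement.** The realized growth rate is the log-linear slope
  of year-end totals over the import-free era (after the last scheduled
  import). Fitting through the import years would confound introductions
  with reproduction: on the packaged census the all-years slope is 0.164
  while the import-free slope is 0.098.
* **Rainfall.** A stationary AR(1) annual series, default mean 450 mm, SD
  120 mm, autocorrelation 0 — Eastern Cape-like totals with negligible
  year-to-year correlation, matching the near-zero lag-1 correlation the
  modelling assumes.
* **Reproducibility.** One RNG stream per run, fully determined by `seed`;
  replicate experiments derive per-replicate seeds from a master seed and
  store them in their results.

**What the generator does and does not emulate.** It reproduces the
structural features the analysis rests on: staged introductions, stage
transitions, long gestation, multi-year stochastic IBIs, near-even birth
sex, demographic stochasticity at realistic population sizes. It omits
spatial structure, poaching, environmentally driven mortality, detection
error and individual heterogeneity in fecundity. Passing tests therefore
show the *pipeline* behaves correctly under the stated demographic
assumptions, not that real populations contain no such processes.

## Replicate experiments

`false_signal_experiment()` runs simulate → PFC → transform → rank over
replicate null populations and reports, per covariate, the distribution of
relative importance and the fraction of replicates whose model-averaged
95% CI excludes zero. With 500 replicates at the default settings that
fraction is ≈ 0.07–0.08 for rain and density — near the nominal rate,
though single replicates can show high covariate importance purely by
chance, which is precisely the caution the indicator warrants.
`pfc_variance_experiment()` summarises, across replicates, the annual PFC
mean/SD and the shrinkage of moving-average dispersion with window size.

Problem sizes used by the test-suite and the acceptance script — 500
replicate populations for calibration and false-signal rates, 500 series of
length 300 for CI-coverage checks, 100 random instances for the
least-squares oracle — were chosen to make Monte Carlo error small relative
to the tolerances asserted.

## Known limitations

* The conditional-likelihood convention makes AICc values comparable
  within the package but only approximately comparable with state-space
  fits of the same models.
* Relative importances depend on whether they are summed over all 32
  models or only a confidence set; the package sums over all ranked models
  and reports confidence-set membership separately.
* PFC requires at least one adult female per year; the indicator is simply
  undefined for rebuilding populations that pass through female-free
  years, and the package refuses to fabricate a value there.
* The simulator's survival rates are calibration constants; experiments
  about *mortality* (rather than reproduction) would need them replaced
  with measured values.
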