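# pfctools

Tools for computing and interpreting the **proportion of females calving
(PFC)** — annual births divided by the number of adult females — as a
population-level reproductive indicator for megaherbivores, built around
the demographic history of a closed, reintroduced black rhinoceros
(*Diceros bicornis minor*) population monitored with complete individual
life histories.

For species with inter-birthing intervals longer than a year, only a
fraction of adult females can calve in any year, so an annual PFC series is
negatively autocorrelated, and at realistic population sizes it fluctuates
strongly through demographic stochasticity and the synchronised first
calvings of introduced cohorts. The package implements the full analysis
chain needed to handle this properly, plus the simulation machinery to ask
when the analysis can be fooled:

* **Life histories → PFC**: registry validation (event ordering, 15-month
  gestation spacing), the calved-or-age-seven adulthood rule, part-year
  denominators, year-end sex×stage census tables, and du Toit's benchmark
  bands for "% of cows with calf of the year".
* **Transforms**: arcsine-square-root and its count-based modification
  `z(x,n) = [asin√(x/(n+1)) + asin√((x+1)/(n+1))]/2`, moving averages,
  ACF/PACF with Durbin–Levinson partial autocorrelations.
* **AR(2) model selection**: conditional Gaussian ML fits of
  `z_t = b0 + b1 z_{t-1} + b2 z_{t-2} + c1 density + c2 rain + c3 rain_1 + ε`
  for every covariate subset on a common response window, AICc ranking,
  Akaike weights, 0.95 confidence sets, natural model averaging with
  unconditional SEs, and relative importance.
* **Individual-based simulator**: monthly event loop with staged imports,
  shifted-gamma inter-birthing intervals (mean 29.0, SD 7.9 months),
  gestation 15 months, expected age at first calving 7 years, and optional
  density/rainfall effect injectors — plus replicate *false-signal* and
  *variance* experiments.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` methods for fits and rankings, and `autoplot()` methods for the
series, correlogram, ranking and simulation types.

## Worked example

The packaged census (`rhino_census()`) covers 1986–2008, growing from 3
year-end founders to 110 animals, with PFC reported from 1987:

```r
library(pfctools)
report <- reproduce_analysis(rhino_census())
report
#> PFC analysis report
#> ===================
#> PFC over 22 years: mean 0.40, SD 0.24 (divisor n; sample SD 0.25)
#> Benchmark band of the mean: mod-good
#>
#> Moving averages of PFC:
#> # A tibble: 5 × 5
#>   window n_windows  mean  sd_n sd_sample
#>    <int>     <int> <dbl> <dbl>     <dbl>
#> 1      3        20 0.401 0.063     0.065
#> 2      5        18 0.403 0.047     0.048
#> 3      7        16 0.401 0.031     0.032
#> 4      9        14 0.399 0.019     0.02
#> 5     11        12 0.399 0.016     0.017
#>
#> NOTE: no rainfall series supplied; model ranking restricted to the 8 rain-free models.
#>
#> AICc model ranking: 8 models on n = 20 responses; 5 in the 0.95 confidence set
#> # A tibble: 8 × 6
#>   model                     k    AICc  delta  weight cumweight
#>   <chr>                 <dbl>   <dbl>  <dbl>   <dbl>     <dbl>
#> 1 lag1 + lag2               4 -11.6    0     0.449       0.449
#> 2 lag1                      3 -11.1    0.482 0.353       0.802
#> 3 lag1 + lag2 + density     5  -7.98   3.61  0.0739      0.876
#> 4 lag1 + density            4  -7.94   3.65  0.0725      0.948
#> 5 null                      2  -6.35   5.23  0.0329      0.981
#> ...
```

Reading this: the mean PFC of 0.40 sits in the moderate–good benchmark
band, but the annual SD of 0.24 means single years range from "very poor"
to "excellent" without any change in the population's health — the 3-year
moving average cuts that dispersion to 0.063. The ranking is dominated by
the autoregressive lags (a female that calved last year is very unlikely to
calve this year, given a 29-month inter-birthing interval); density adds
essentially nothing, consistent with no density feedback on reproduction in
this growing population. Model-averaged coefficients for the lags are
negative (lag1 ≈ −0.61 ± 0.22), confirming the expected alternation.

Supplying an annual rainfall table (`year`, `rain_mm`) switches the same
call to the full 32-model ranking with rain and prior-year rain terms.

On the simulation side:

```r
sim <- simulate_population(sim_config(), seed = 42)
sim$summary
#> # A tibble: 1 × 8
#>   realized_growth realized_ibi_mean realized_ibi_sd n_ibi realized_afr_mean ...
#> 1          0.0778              29.3            8.06    57              6.85 ...

fs <- false_signal_experiment(sim_config(), replicates = 100, seed = 2000)
fs$summary
#> # A tibble: 3 × 4
#>   term    median_importance mean_importance frac_ci_excludes_zero
#> 1 density             0.184           0.224                0.0202
#> 2 rain                0.214           0.288                0.0707
#> 3 rain_1              0.205           0.271                0.0606
```

Reproduction in these simulated populations ignores density and rainfall by
construction, yet individual replicates can hand a covariate substantial
relative importance; across replicates the model-averaged CI excludes zero
at roughly the nominal error rate. That is the core caution: a covariate
signal in a PFC analysis needs independent evidence from vital rates before
it is believed.

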