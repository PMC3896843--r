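# bfequity

Estimation of breastfeeding-indicator prevalence for developing countries
from sparse, heterogeneous survey data; disaggregation by asset-based wealth
quintiles; and attribution of child diarrhea and pneumonia burden to
suboptimal breastfeeding.

## The scientific problem

Breastfeeding practice is measured by occasional household surveys that
differ in coverage (national vs. subnational), indicator definitions, and
timing, yet policy needs complete annual country time series with honest
uncertainty — and needs to know how much child disease burden would be
averted under full compliance with breastfeeding recommendations, and whether
improvements reach poor households.

`bfequity` implements the full chain:

1. **Harmonization.** Non-standard survey definitions are mapped onto the
   standard definition by additive logit-scale correction factors
   $\hat\delta$ estimated from surveys observed under both definitions;
   correction uncertainty inflates the observation variance.
2. **Three-stage prevalence model.** For each of six indicators
   (timely initiation, the 0–5-month exclusive/predominant/partial
   composition, continued breastfeeding at 6–11 and 12–23 months):
   * *Stage 1*: OLS of $\mathrm{logit}(p)$ on four country-year covariates
     (female education, log GDP per capita, child underweight, total
     fertility), with country-cluster-robust (CR3) inference;
   * *Stage 2*: locally weighted spatio-temporal smoothing of the stage-1
     residuals (tricube time kernel, bandwidth 10 years; spatial borrowing
     weights 1 / 0.5 / 0.25 for own country / region / super-region; a 90/10
     national/subnational renormalization);
   * *Stage 3*: per-country Gaussian process regression (Matérn-5/2,
     length-scale 10 years) around the stage-2 surface, yielding 1,000
     posterior draws per country-year.
   The 0–5-month categories are modelled as nested cumulative quantities and
   differenced per draw, so the four shares sum to exactly 1 in every draw.
3. **Wealth quintiles.** Household permanent income is a latent
   standard-normal variable measured by probit asset-ownership items
   ($P(\text{own } k) = \Phi(d_k(y - c_k))$); households are ranked into
   quintiles and per-quintile prevalence trends are classified as uniform,
   top-concentrated, bottom-concentrated or mixed.
4. **Attributable burden.** The exact categorical population attributable
   fraction
   $\mathrm{PAF} = (\sum_i P_i RR_i - \sum_i P'_i RR_i) / \sum_i P_i RR_i$
   against a 100%-compliance counterfactual, with log-normal relative-risk
   draws paired index-by-index with exposure draws, multiplied by background
   death and DALY envelopes.

Because real survey microdata cannot be redistributed, the package ships a
synthetic-world generator with known ground truth (true trajectories, true
incomes, true distortions) that emulates the multi-source survey landscape;
every stage is validated against that truth. See the methods vignette
(`vignettes/methods.Rmd`) for the full model description and parameter
rationale.

## Worked example

```r
library(bfequity)
library(dplyr)

world   <- bf_sim_world(bf_sim_config(seed = 42))
surveys <- bf_sim_surveys(world)
fit <- bf_estimate_prevalence(surveys, world$covariates, world$geo,
                              config = bf_pipeline_config(seed = 42))
fit
#> Breastfeeding prevalence estimates: 24 countries x 21 years x 6 indicators
#>   1000 posterior draws per cell

fit$estimates |>
  filter(country_id == "SR1_R1_C01", indicator == "exclusive_0_5",
         year %in% c(1990, 2000, 2010))
#> # A tibble: 3 × 6
#>   country_id  year indicator      mean lower_95 upper_95
#>   <chr>      <int> <chr>         <dbl>    <dbl>    <dbl>
#> 1 SR1_R1_C01  1990 exclusive_0_5 0.295    0.256    0.338
#> 2 SR1_R1_C01  2000 exclusive_0_5 0.348    0.319    0.377
#> 3 SR1_R1_C01  2010 exclusive_0_5 0.404    0.360    0.454

tidy(fit$stage1$cum_exclusive)   # cluster-robust stage-1 inference
#> # A tibble: 5 × 7
#>   term               estimate std.error statistic  p.value conf.low conf.high
#>   <chr>                 <dbl>     <dbl>     <dbl>    <dbl>    <dbl>     <dbl>
#> 1 (Intercept)           2.30     0.246       9.32 2.82e- 9    1.79      2.81
#> 2 maternal_education    0.156    0.0193      8.07 3.67e- 8    0.116     0.196
#> 3 log_gdp_pc           -0.356    0.0319    -11.2  9.20e-11   -0.422    -0.290
#> 4 child_underweight    -1.90     0.271      -7.01 3.79e- 7   -2.46     -1.34
#> 5 tfr                  -0.169    0.0180     -9.38 2.53e- 9   -0.206    -0.132
```

Wealth-quintile inequality:

```r
records <- bf_sim_quintile_records(gradient = 0.02, trend_per_year = 0.01,
                                   trend_quintiles = c(4, 5), seed = 42)
bf_quintile_trends(bf_quintile_prevalence(records))
#> Quintile trend comparison: verdict 'top-concentrated' (F = 6.42, p = 0.00795)
#> # A tibble: 5 × 4
#>   quintile   slope      se z_excess
#>      <dbl>   <dbl>   <dbl>    <dbl>
#> 1        1 0.00135 0.00133   -2.15
#> 2        2 0.00081 0.00172   -1.99
#> 3        3 0.00391 0.00139   -0.227
#> 4        4 0.00968 0.00179    3.04
#> 5        5 0.00917 0.002      2.48
```

Attributable burden:

```r
background <- bf_sim_burden_background(world)
burden <- bf_burden_cra(fit, background, seed = 42)
bf_aggregate_burden(filter(burden, year == 2010), by = c("year", "metric")) |>
  select(-.draws)
#> # A tibble: 2 × 7
#>    year metric background attributable_mean attributable_lower
#>   <int> <chr>       <dbl>             <dbl>              <dbl>
#> 1  2010 DALYs    3931098.          2165259.           1476479.
#> 2  2010 deaths     47650.            26246.             17897.
#> # ℹ 2 more variables: attributable_upper <dbl>, percent_of_total <dbl>
```

Everything above can also be run in one call — `bf_run_all()` writes all
artifacts as CSV plus a markdown report and a manifest of MD5 hashes:

```r
run <- bf_run_all(bf_run_config("out/run1", seed = 42))
```

Plot methods are available via `ggplot2::autoplot()` for prevalence fits,
quintile trends and burden results.

## Tests

The test suite validates every stage against independently coded brute-force
oracles, hand-computed values, and ground-truth recovery simulations
(interval calibration, coefficient coverage, distortion recovery, income
ranking, trend-verdict error rates, end-to-end byte reproducibility):

```r
devtools::test()
# or, against the installed package:
testthat::test_dir("tests/testthat", package = "bfequity",
                   load_package = "installed")
```

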