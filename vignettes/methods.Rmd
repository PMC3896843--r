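---
title: "Methods: breastfeeding prevalence estimation, wealth quintiles, and attributable burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breastfeeding prevalence estimation, wealth quintiles, and attributable burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfequity)
```

`bfequity` estimates complete country-year time series of six breastfeeding
indicators from sparse, heterogeneous survey data, disaggregates breastfeeding
by household wealth quintile, and attributes child diarrhea and pneumonia
burden to suboptimal breastfeeding. This vignette documents the statistical
model, the main modelling assumptions, every default parameter and why it has
the value it has, and the known limitations.

## The estimation problem

Survey measurements of breastfeeding practice are sparse (a handful of surveys
per country over two decades), noisy (cluster samples of ~1000 children),
and inconsistent (subnational samples, non-standard indicator definitions).
The package produces, for every country, year and indicator, a posterior
distribution of the true national prevalence, represented by 1,000 draws.

The six indicators are timely initiation (first breastfeeding within 24 hours
of birth), the 0–5-month feeding composition (exclusive, predominant, partial
breastfeeding — plus the implied "none" share), and continued breastfeeding at
6–11 and 12–23 months.

### Modelling targets: the nested cumulative scale

The three 0–5-month categories are shares of a four-category composition, so
they cannot be modelled independently without risking incoherent estimates
(shares that do not sum to one). The package instead models the three *nested
cumulative* quantities

$$C_1 = P(\text{exclusive}) \le C_2 = P(\text{exclusive or predominant})
  \le C_3 = P(\text{any breastfeeding}),$$

each on the logit scale, and recovers the category shares by differencing
draws. Any draw where the marginal posteriors violate the nesting order is
repaired by sorting the three cumulative values (`bf_enforce_composition()`),
after which exclusive + predominant + partial + none = 1 holds *exactly in
every draw*, not just in expectation. Initiation and the two continued
indicators are modelled directly on the logit scale.

## Harmonization

Surveys analysed under non-standard indicator definitions are mapped onto the
standard definition by an additive logit-scale shift,
$\mathrm{logit}(p^{std}) = \mathrm{logit}(p^{non}) + \delta$. The shift
$\delta$ is estimated per indicator as the precision-weighted mean of
$\mathrm{logit}(p^{std}) - \mathrm{logit}(p^{non})$ over country-years
observed under both definitions (surveys that report a standard re-analysis
of the same microdata). Design choices:

* **At least two pairs** are required per model; with fewer, the model is
  flagged unusable and the affected non-standard observations are *dropped*
  rather than corrected — a conservative default, since an uncorrectable
  systematic error is worse than a smaller sample.
* Corrected observations have their logit-scale variance inflated by
  $SE(\delta)^2$, so harmonization uncertainty propagates downstream.
* The correction is idempotent: corrected points are flagged and never
  shifted twice.
* Pooling across indicators (`pool = "all"`) is available for data-poor
  settings where a single definition effect is a tolerable approximation;
  the per-indicator default is correctly specified when definitions distort
  different indicators differently.

## The three-stage prevalence model

### Stage 1: covariate regression

An OLS regression of the logit of observed prevalence on four fixed
country-year covariates — female education, log GDP per capita, child
underweight prevalence, and total fertility rate — provides a prediction for
*every* country-year, including countries with no data at all. Covariate
screening (`bf_screen_covariates()`) reports correlations but never changes
the regressor set: a fixed specification keeps estimates comparable across
indicators and avoids data-dredging on sparse data.

Coefficient uncertainty uses **cluster-robust (CR3/HC3) standard errors with
country clusters** and $t$ quantiles on $G-1$ degrees of freedom.
Observations from the same country share persistent unmodelled country
effects — exactly the structure stages 2 and 3 exploit — so classical OLS
intervals would be severely anti-conservative. With a few dozen clusters the
plain cluster-robust (CR1) estimator is still too liberal; the jackknife-type
CR3 adjustment is the standard small-sample recommendation and is what the
package uses.

### Stage 2: spatio-temporal residual smoothing

Stage-1 residuals carry the country-specific, slowly varying signal the
covariates miss. For each target country-year $(c, t)$ the smoothed residual
is

$$\hat r(c,t) \;=\; \frac{\sum_{j} w^{space}_{cj}\, \pi_j(t)\, \bar r_j(t)}
  {\sum_{j} \pi_j(t)},$$

where the sums run over countries $j$ with positive spatial weight,
$\pi_j(t)$ is country $j$'s total tricube time-weight mass,
and $\bar r_j(t)$ its time-weighted mean residual. Parameters and rationale:

* **Time kernel**: tricube with bandwidth 10 years — smooth, compactly
  supported, so surveys more than a decade away never influence an estimate.
* **Space weights**: own country 1, same region 0.5, same super-region 0.25.
  Because the spatial weight appears only in the numerator, borrowed
  residuals are *shrunk toward zero* rather than averaged at full strength: a
  country with no data of its own gets half of its sibling's residual, not
  all of it.
* **National/subnational split**: when a country's local pool contains both
  nationally representative and subnational residuals, the subnational
  contribution is renormalized to 10% of the pooled value and national data
  carry the remaining 90% — subnational samples are informative but
  systematically unrepresentative. In the canonical constructed case
  (nationals all $+1$, subnationals all $-1$, both present at the target
  year) the pooled residual is $0.9 - 0.1 = 0.8$.

### Stage 3: Gaussian process regression

Per country, a one-dimensional Gaussian process over years on the logit
scale, with the stage-2 surface as prior mean and a Matérn-5/2 kernel:

* **Length scale 10 years**, matching the stage-2 bandwidth: prevalence is a
  slow secular process; year-to-year jumps are noise.
* **Amplitude** estimated per region as $1.4826 \times$ the median absolute
  deviation of the stage-2 residuals (a robust SD), floored at 0.05 so the
  posterior never collapses onto the prior. Regions with fewer than three
  observations fall back to the global MAD.
* **Observation noise** = the logit-scale sampling variance of each survey
  plus a non-sampling floor of 0.01 (survey error is never purely binomial),
  plus an extra 0.1 for subnational observations, whose deviation from the
  national quantity is systematic rather than sampling error. Without this
  term, biased subnational points would be interpolated at face value and
  intervals would undercover near data.
* **Draws**: 1,000 joint posterior draws per country, transformed to the
  probability scale; the published mean and 95% interval are the draw mean
  and the 2.5th/97.5th draw quantiles. All downstream computation (the
  composition, the burden attribution) consumes draws, never summaries, so
  nonlinear transformations propagate uncertainty correctly.
* Cholesky factorization uses an escalating jitter ($0$ to $10^{-4}$) and
  aborts rather than silently degrade if the posterior covariance is not
  positive definite.

Limiting cases, enforced by tests: with no data the posterior mean equals the
prior mean exactly; a zero-variance observation is interpolated exactly.

## Wealth quintiles

Household wealth is a latent variable measured through durable-asset
ownership. The model is a one-factor probit item-response model: household
income $y_i \sim N(0,1)$, and asset $k$ is owned with probability
$\Phi(d_k (y_i - c_k))$ with discrimination $d_k > 0$ and cutpoint $c_k$.

* **Asset selection** (`bf_select_assets()`): constant columns are dropped
  (no information), exact duplicates collapsed (double counting), and assets
  whose ownership *decreases* in the first principal axis of the asset matrix
  (reverse goods, e.g. subsistence assets) are sign-flipped.
* **First-pass cutpoints**: with a standard-normal latent income, an asset
  owned by a fraction $p$ has cutpoint $\Phi^{-1}(1-p)$ — rarer assets sit
  higher on the wealth scale.
* **Refinement**: alternating updates — given incomes, a per-asset probit
  regression of ownership on income re-estimates $(d_k, c_k)$; given asset
  parameters, each household's income is the posterior mode under the
  standard-normal prior times the probit likelihoods (a concave problem,
  solved by Newton iterations). Ten rounds or relative change below $10^{-4}$,
  whichever comes first; slope updates below 0.05 are rejected to keep the
  latent scale identified.
* **Quintiles**: households are ranked by estimated income and split into
  five groups whose sizes differ by at most one; ties keep input order, so
  the assignment is deterministic.

Per-quintile prevalence series are compared by inverse-variance-weighted
per-quintile slopes and an F-test of the year-by-quintile interaction
($\alpha = 0.05$). The pattern verdict is `uniform` when the interaction is
not significant; otherwise `top-concentrated` (`bottom-concentrated`) when
every quintile with significant positive slope excess ($z \ge 1.96$ against
the precision-weighted common slope) lies in quintiles 4–5 (1–2), and
`mixed` otherwise. Series with fewer than three time points are excluded with
an error of class `bf_excluded` rather than classified on two points.

## Attributable burden

The comparative risk assessment uses the exact categorical
population-attributable-fraction formula

$$\mathrm{PAF} \;=\; \frac{\sum_i P_i RR_i - \sum_i P'_i RR_i}
 {\sum_i P_i RR_i},$$

with $P$ the estimated exposure distribution and $P'$ the counterfactual of
100% compliance with recommendations (100% exclusive at 0–5 months, 100%
continued at 6–23 months). Design choices:

* **Exposure draws**: the 0–5-month composition enters draw by draw; the
  6–23-month exposure is the duration-weighted mix
  $(6/18)\,p^{cont}_{6\text{–}11} + (12/18)\,p^{cont}_{12\text{–}23}$ of the
  two continued indicators, reflecting the relative lengths of the 6–11 and
  12–23 month windows.
* **Relative-risk draws** are log-normal with median at the published RR and
  $\sigma = \log(RR_{upper}/RR_{lower})/(2 \times 1.96)$; intervals crossing
  1 are sampled as printed, without truncation, so protective draws yield
  negative PAF draws and the published intervals honestly reflect effect-size
  uncertainty.
* **Draw pairing**: exposure draw $d$ is always combined with RR draw $d$, so
  uncertainty correlates correctly through the nonlinear formula.
* **Exclusions**: timely initiation is modelled but never enters the burden
  (no usable effect sizes); the (discontinued breastfeeding, pneumonia) pair
  is excluded (no statistically significant published association). The
  effect-size validator rejects tables containing either, and the assessment
  never produces those cells.
* **Metrics**: deaths and DALY envelopes both use the mortality relative
  risks — child diarrhea and pneumonia DALYs are dominated by years of life
  lost. Incidence effect sizes ship in the table for morbidity-specific
  analyses.
* **Aggregation** is always at the draw level (`bf_aggregate_burden()`), and
  mixing deaths with DALYs in one sum is an error, not a warning.

## The synthetic world

Real survey microdata cannot ship with the package, so all validation runs
against a generator with known ground truth (`bf_sim_world()` and friends).
The default world is deliberately small — 3 super-regions × 2 regions × 4
countries = 24 countries over 1990–2010 — so a full pipeline run takes
seconds and calibration studies of 100 replicates stay within minutes; a
137-country `paper_scale` preset exists for larger experiments.

What the generator emulates:

* logit-linear true trajectories with country intercept/slope random effects
  nested in region and super-region, so spatial borrowing has real signal;
* covariates that truly enter every trajectory's linear predictor (default
  loadings 0.10, −0.20, −1.50, −0.10), so stage 1 has real but partial
  explanatory power;
* the multi-source survey landscape: Poisson survey counts, multinomial
  sampling of the 0–5-month composition (so the trio is jointly, not
  independently, noisy), a 20% subnational fraction with +0.3 logit bias, a
  20% non-standard fraction with −0.4 logit distortion, and a 50% chance
  that a non-standard survey also reports a standard re-analysis — the pairs
  that make correction factors estimable;
* asset ownership from the exact probit item-response model, with recorded
  true incomes and quintiles;
* burden envelopes proportional to births with declining rates, and
  DALYs ≥ 80 × deaths.

What it does not emulate: informative survey timing, non-additive definition
effects, measurement error in covariates, migration between wealth quintiles,
or correlation between breastfeeding prevalence and the background envelopes.
Conclusions about those mechanisms cannot be validated with this generator.

The generator's random-effect scales place most residual variation at the
country level. That is the regime in which country-clustered inference is
correctly specified; strong region-level shocks would correlate errors
*across* countries and no country-cluster estimator would be valid.

## Determinism

Every stochastic component draws from a named substream derived from one root
seed (`substream_seed(seed, name)`, always below $2^{31}$), and all random
sections restore the caller's RNG state. Identical configuration and seed
reproduce every artifact byte for byte; `bf_run_all()` writes a manifest with
MD5 hashes of all outputs.

## Limitations

* National estimates assume surveys are exchangeable within country-year
  after harmonization; unmodelled survey-specific biases (beyond the
  subnational and definition mechanisms) are absorbed into the non-sampling
  variance floor.
* The GP is fit per country after stage 2; cross-country posterior
  correlation is carried only through the prior mean, so aggregates of many
  countries may be slightly over-confident.
* The wealth model assumes one latent dimension; multi-dimensional wealth
  (urban/rural asset portfolios) will load onto a single axis.
* Effect sizes are treated as exchangeable log-normal summaries; no
  adjustment for study quality or confounding beyond the published CIs.
* The trend classifier tests slope heterogeneity, not level differences:
  persistent but stable inequality is classified `uniform`.
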