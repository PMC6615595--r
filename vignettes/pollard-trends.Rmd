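---
title: "From weekly transect counts to abundance trends: models and design choices"
author: "pollardtrend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From weekly transect counts to abundance trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollardtrend)
library(dplyr)
```

# The problem

Pollard-walk butterfly monitoring schemes send trained volunteers along
fixed transects at roughly weekly intervals through the flight season
(April–October, 30 weeks), counting every butterfly within about 5 m of
the route. The scientific question is deceptively simple — *is total
butterfly abundance changing, and which species are driving the change?*
— but the raw data are awkward: weeks get skipped, surveys vary in
duration and conditions, species differ enormously in phenology, and
sites enter and leave the scheme over the years.

`pollardtrend` implements the full inferential chain a scheme analyst
needs:

1. **Thermal time.** Calendar dates are converted to accumulated growing
   degree-days (GDD, base 5 °C, accumulated from January 1), the
   physiologically relevant clock for ectotherm phenology.
2. **Flight curves and imputation.** A penalized Poisson spline per
   species describes how counts vary over the season (in GDD), space,
   and year; model predictions fill in the weeks a site missed.
3. **Population indices.** The completed weekly series is integrated
   with the trapezoid rule into one index per site × year × species,
   alongside two effort covariates: mean list-length (species recorded
   per survey) and the projected season-total duration.
4. **Trends.** An overdispersed Poisson mixed model estimates the
   log-linear abundance trend; annualized and cumulative percent rates,
   bootstrap intervals, and a p < 0.05 positive/negative/stable
   classification follow from it.
5. **Comparison and traits.** Published scheme results are standardized
   to annual rates for comparison, and species' trend coefficients are
   regressed on life-history traits by OLS and by phylogenetic GLS with
   maximum-likelihood Pagel's lambda.

Because raw scheme data are not bundled, the package ships a synthetic
data generator (`simulate_monitoring()`) that emulates the statistical
structure of such a scheme with known ground truth. Everything the
package claims about its estimators is demonstrated on that generator by
the test suite and the acceptance script.

# The trend model

For one species (or the all-species total), let $N_{st}$ be the
population index at site $s$ in year $t$. The model is an overdispersed
Poisson regression on the log link:

$$
\log E[N_{st}] = \beta_0 + \beta_1\,\mathrm{year}_t + \beta_2\,L_{st}
 + \log D_{st} + a_s + b_t + c_{st},
$$

with centered numeric year, centered mean list-length $L_{st}$, the log
projected duration $D_{st}$ as an offset (so the response is a rate of
butterflies per minute), and independent normal random intercepts for
site ($a_s$), year ($b_t$), and the site-by-year observation
($c_{st}$). The observation-level term absorbs extra-Poisson variance;
the year term keeps annual swings (weather years) from masquerading as
trend. Estimation is Laplace-approximated ML via `lme4::glmer()`;
p-values are Wald z tests, matching how such schemes report their
coefficient tables.

The fitted $\beta_1$ converts to rates:

* annual rate $= 100(e^{\beta_1}-1)$ percent per year — the geometric
  mean rate of change, independent of which two years you compare;
* cumulative change over $k$ years $= 100(e^{k\beta_1}-1)$.

These two are exact inverses of `cumulative_to_annual()` /
`annual_to_cumulative()`, which standardize *published* scheme results
(reported as "−40 % over 25 years" and the like) onto the same annual
scale. Trends are classified positive/negative/stable by the sign of
$\beta_1$ at a p < 0.05 threshold.

Indices are real-valued after trapezoid integration; they are rounded to
the nearest integer for the Poisson likelihood, which preserves the
count-model family at a negligible cost for indices in the tens to
thousands.

## Goodness of fit

`r2_glmm()` reports marginal and conditional $R^2$ on the link scale:
the fixed-effect variance over the total latent variance (marginal), and
fixed plus random over the total (conditional). The
distribution-specific variance for the log-link Poisson uses the
lognormal approximation $\ln(1 + 1/\bar\lambda)$ with $\bar\lambda$ the
model-implied mean count; with indices in the hundreds this term is tiny
and the conditional $R^2$ is driven by the random-effect variance.

## Alternative models

Two deliberately different fits guard against artifacts of the main
model: `fit_trend_glm()` drops all random effects (a plain Poisson GLM),
and `fit_trend_smooth()` replaces the linear year term with a penalized
spline (random-effect smooths keep the site and observation terms),
reporting per-year relative abundance and an endpoint-to-endpoint
annualized rate. On log-linear simulated truth all three agree to a few
tenths of a percentage point per year; the tests assert this.

# Phenology: degree-days, flight curves, imputation

Daily degree-day increments use the simple averaging estimator
$\max(0, (T_{min}+T_{max})/2 - 5)$ — the standard first choice when no
within-day temperature model is warranted — accumulated within each
site-year from January 1.

A species' flight curve is fitted to all surveyed weeks pooled across
sites and years (a "regional" model, one per species), as a Poisson GAM:

* cubic regression spline in accumulated GDD (basis dimension 10 —
  enough for three broods, few enough to resist noise),
* a low-rank thin-plate smooth over site coordinates (dropped below 5
  distinct sites),
* year as a categorical term,
* log survey duration as an offset.

Smoothness is chosen by GCV (`mgcv::gam`); above 8 000 training rows the
fit switches to `mgcv::bam` with fast REML and discretized covariates,
which is numerically indistinguishable for these data but an order of
magnitude faster. Site-years contribute to training only if they have at
least 5 surveyed weeks (threshold read as inclusive). Zero-anchoring of
the season boundaries — a convention in some schemes — is *not* applied;
with degree-day support spanning the whole April–October season the
spline already returns to near zero outside the flight period.

Imputation (`impute_missing_counts()`) never touches observed counts:
they pass through bit-exactly, and only unsurveyed weeks receive the
model's expected count (a nonnegative real, not a sampled integer,
because the trapezoid integral downstream consumes expectations). Weeks
whose degree-days fall outside the training support are flagged
`extrapolated`; site-years from years the model never saw are left
unfilled with a warning.

# Inclusion filters

Three thresholds, applied by `apply_trend_filters()` and mirrored from
standard scheme practice: a site-year enters the trend analysis with at
least 10 surveys; a site needs 3 such years; a species gets its own
trend model when recorded at 5 or more retained sites in 10 or more
years. Species failing the last test still contribute to the
total-abundance aggregation — rarity is not a reason to drop a
butterfly from the total. Species trend models are additionally
restricted to site-years at sites where the species was ever recorded
(`species_index_rows()`), so structural absences outside a species'
range do not dilute its trend, while true zeros within the range do
inform it.

# What the generator emulates — and what it does not

`simulate_monitoring()` draws a full scheme dataset from the trend
model's own generative structure, so that end-to-end recovery is a fair
test of the estimators:

* **Design**: 104 sites × 21 seasons × 30 weeks by default, with weeks
  missed completely at random at rate 7/30 (matching a median of ~23 of
  30 weeks surveyed); survey durations log-normal with mean 85 and SD 30
  minutes, truncated at 10.
* **Random effects**: log-scale SDs 0.417 (site), 0.121 (year), 0.278
  (site-by-year observation) — the variance components a statewide
  total-abundance model of this kind reports — shared across species, so
  the community total inherits exactly this structure. Counts are
  Poisson conditional on the observation effect (an overdispersed
  Poisson).
* **Phenology**: flight curves are Gaussian mixtures in accumulated
  degree-days, one component per brood (1/2/3+ for
  uni-/bi-/multivoltine species); weekly expected counts are the
  mixture mass falling in that week's degree-day window. Temperatures
  are sinusoidal in day of year with a 1.5 °C-per-degree-latitude
  cooling gradient and day-level noise, roughly an Ohio-like climate.
* **Species lists**: real transect lists record every butterfly seen,
  not just the species a given analysis models. The generator therefore
  adds a background community of incidental singleton records whose
  per-survey richness varies with a latent survey-quality factor
  (weather, observer acuity). Focal-species counts rise by
  `listlength_effect` (default 0.104) log units per extra species
  listed — better survey conditions inflate both the list and the
  counts. This is precisely the confounding the list-length covariate
  exists to absorb; without an exogenous source of list variation the
  covariate would instead read community abundance itself and attenuate
  the estimated trend, which is worth remembering when interpreting
  list-length adjustments on real data from species-poor communities.
* **Baseline abundances** are log-normal (mean 3, SD 1.2 on the log
  scale), giving seasonal totals from a handful to a few thousand per
  site-year, and the default true trend is `log(0.98)` — a 2 % annual
  decline.

Not emulated: observer-specific behavior, weather-dependent
detectability beyond the scalar quality factor, spatial autocorrelation
between sites, within-week repeat visits, and any temperature trend
across years. Passing the recovery tests therefore demonstrates that the
pipeline is consistent under its own assumptions — it cannot certify
robustness to, say, detectability trends over time, which no count-based
scheme analysis can rule out without auxiliary data.

## Problem sizes used in validation

The end-to-end recovery experiment runs 20 replicates of a 50-site ×
21-year scheme with 4 focal species, chosen so the whole experiment
completes in a few minutes while the per-replicate standard error of the
trend (≈ 0.004 on the log scale, dominated by the year-level variance
component) matches what a real scheme of this size reports. The
criterion is calibration, not precision: the estimate should fall within
±2 SE of the true `log(0.98)` in at least 90 % of replicates, and the
mean annual rate within half a percentage point of −2 %.

# Trait and phylogenetic models

Species-level trend coefficients are regressed on one life-history trait
at a time (`fit_trait_ols()`, reporting adjusted $R^2$), optionally
excluding migratory species, whose trends are set outside the monitored
region. To respect phylogenetic non-independence, `fit_pgls()` fits the
same regressions by generalized least squares with residual covariance
$V(\lambda)$: the Brownian-motion matrix of shared root-to-ancestor path
lengths (`brownian_vcv()`, via `ape`) with off-diagonal entries scaled
by Pagel's $\lambda \in [0,1]$. $\lambda$ is estimated by bounded scalar
optimization of the profile log-likelihood (tolerance 1e-6), with the
endpoints checked explicitly so boundary optima are honored, and a
21-point profile retained for inspection (`autoplot()` draws it). A
near-flat profile (range < 1.92 log-likelihood units, the 95 % χ²
half-width) triggers a wide-profile warning rather than false
confidence in the point estimate.

Numerical notes: the GLS is solved through the Cholesky factor of
$V(\lambda)$ (no explicit inverse); $\hat\sigma^2$ uses $n-p$ for the
coefficient SEs but $n$ inside the ML profile; coefficients at
$\lambda = 0$ reproduce OLS to machine precision, which the tests assert
at 1e-8. Categorical traits are dummy-coded with the alphabetically
first level as reference. No multiple-testing correction is applied
across trait models — they are reported individually, as univariate
screens, and should be read as such.

# Degenerate inputs and edge behavior

* `fit_flight_curve()` refuses all-zero counts ("no phenology signal")
  and training sets with fewer than 20 nonzero surveys or fewer than 2
  sites; basis dimensions shrink automatically when distinct covariate
  values run short.
* A flight curve whose mass lies entirely outside the season draws a
  warning from the generator and produces zero counts.
* `fit_trend_glmm()` requires ≥ 10 rows, ≥ 2 distinct years, positive
  durations; singular random-effect fits report an SD of 0 with a
  warning rather than failing.
* The parametric bootstrap errors out if more than 20 % of refits fail,
  and is reproducible from its seed.
* Filters and aggregations error on internally inconsistent covariates
  (same site-year, different durations) instead of silently averaging.

# Known limitations

* Detection probability is not modelled; like the schemes it mirrors,
  the analysis assumes no systematic change in detectability, with
  list-length and duration as proxies for survey quality.
* The regional flight-curve model pools years through a categorical
  term; a species whose phenology *shape* (not just height) changes
  across years is summarized by an average curve.
* Serial autocorrelation in year effects is not modelled.
* The lognormal $R^2$ approximation degrades for indices near zero.
* With very few focal species and no exogenous list variation, the
  list-length covariate can absorb genuine trend (see the generator
  section); diagnosing that on real data requires comparing fits with
  and without the covariate.

# A minimal end-to-end run

```{r example, eval = FALSE}
cfg <- sim_config(
  n_sites = 30, n_years = 21,
  species_specs = sim_species_specs(8, annual_trend = log(0.98), seed = 2),
  seed = 42
)
sim <- simulate_monitoring(cfg)
pipe <- run_abundance_pipeline(sim)
summarize_trend(pipe$total_fit)
boot <- bootstrap_trend_ci(pipe$total_fit, n_boot = 200, seed = 1)
autoplot(pipe$total_fit, ci = boot)
```

The vignette keeps this chunk unevaluated to stay light; the same
pipeline, at the scales given above, is exercised by
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`.
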