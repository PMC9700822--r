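---
title: "Joint hierarchical modelling of route-count and checklist surveys"
author: "jointabund"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint hierarchical modelling of route-count and checklist surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointabund)
```

## The estimation problem

Structured roadside surveys such as the North American Breeding Bird Survey
(BBS) follow a fixed protocol — 50 three-minute point counts along a ~40-km
route — so their counts can be related to a well-defined effective survey
area. They are, however, sparse: many 1-degree grid cells contain one route
or none. Community-science checklists (eBird style) are far more numerous
but semi-structured: effort varies from checklist to checklist and the area
effectively surveyed is unknown. `jointabund` implements a hierarchical
Bayesian state-space model that estimates, for every cell `i` of a 111-km
reference grid, a relative abundance index and its trend, either from route
counts alone (the *BBS-only model*) or from route counts and checklists
together (the *joint model*), and quantifies what the checklists buy in
precision.

## Process model

Log year-specific relative abundance is linear in time with lognormal
year-to-year noise:

$$\mu^{[\gamma]}_{i,t} = \alpha_{i[k]} + \beta_{i[k]} \, \mathrm{YEAR}_t,
\qquad \log \gamma_{i,t} \sim N(\mu^{[\gamma]}_{i,t},\, \sigma^{[\gamma]}),$$

with years centered so the study-period midpoint is 0 (`center_years()`);
`exp(alpha_i)` is then the cell's mean relative abundance over the period
and `beta_i` its log-linear trend. Cell intercepts and slopes are random
deviations from ecoregion (BCR) means, which are themselves deviations from
grand means:

$$\alpha_{i[k]} \sim N(\mu^{[\alpha]}_{[k]}, \sigma^{[\alpha]}), \qquad
\mu^{[\alpha]}_{[k]} \sim N(\mu^{[\alpha]}, \tau^{[\alpha]}),$$

and likewise for the slopes. This partial pooling lets cells with no data
borrow strength from their ecoregion — the model estimates abundance and
trend in every in-range cell, surveyed or not. Grand means carry N(0, sd 10)
priors; every dispersion parameter written as a second Normal argument in
this package is a **variance** (not an sd) and carries an
InvGamma(0.01, 0.01) prior. The convention matters — CVs and recovery both
depend on it — so the tests pin it down through the quadrature identity of
`log_gamma_density()`.

## Observation models

Both streams are zero-inflated Poisson: with probability $\omega$ a count is
a structural zero, otherwise Poisson. For route counts,

$$\log \lambda^{[BBS]}_{j,s,i,t} =
\log\!\big(\gamma_{i,t} \cdot 25/12{,}321\big) +
\varepsilon^{[BBS]}_{j,s} + \eta \, I_{j,s,t},$$

where $25/12{,}321$ scales the cell-level index to the route level: a route
surveys about $50 \cdot \pi \cdot 0.4^2 \approx 25$ km² of a 12,321-km²
cell. $\varepsilon_{j,s}$ is a route-by-observer effect (variance
$\sigma^{[BBS]}$) — drawn once per pair and reused across that pair's years,
since the model treats it as a static characteristic of the route/observer
combination, not per-visit noise — and $\eta$ is an extra effect for an
observer's first year in the archive. For checklists,

$$\log \lambda^{[eBird]} = \log \gamma_{i,t} + \beta_0 + \beta_1 TYPE +
\beta_2 DIST + \beta_3 COSTIME + \beta_4 SINTIME + \beta_5 DURA +
\beta_6 NOOB + \varepsilon_s,$$

with a free scaling intercept $\beta_0$ in place of a known effective area,
effort covariates (survey type, distance, solar-time-of-day pair, duration,
party size), and an observer effect $\varepsilon_s$. Both $\omega$'s are
U(0, 1); $\eta$ and $\beta_{0..6}$ are N(0, sd 10).

`joint_log_posterior()` is the package's executable definition of this
posterior; the sampler is tested against it and against independent
oracles.

## Sampling

`fit_abundance()` runs a Gibbs sampler written in C++: the latent
structural-zero indicators, the zero-inflation probabilities
(Beta), all Gaussian hierarchy blocks and all variances (inverse gamma) have
exact conjugate updates; the Poisson-linked scalar nodes
($\log\gamma_{i,t}$, the random effects, $\eta$, $\beta_{0..6}$) have
log-concave full conditionals and are updated by stepping-out slice
sampling. The posterior, not the sampler, is the contract: the test suite
cross-checks the fitted posterior against an independent JAGS implementation
of the same model on a small fixture, and against Normal–Normal closed forms
in a conjugate sub-case (`fixed = list(log_gamma = ...)` conditions on a
known abundance surface, where the intercept posterior is available in
closed form).

Defaults are conservative: 3 chains, 9000 iterations, 5000 burn-in, no
thinning (at least 4000 retained draws per chain), convergence judged by
the classic Gelman–Rubin statistic with the $\hat R < 1.2$ working
threshold and trace plots
(`plot()`). `mcmc_control(profile = "test")` (3 × 1500/500) is the
development-scale profile used by the package's own recovery experiments.
Initialization is data-driven: $\log\gamma$ starts at the offset-corrected
log cell-year mean count, intercepts and slopes at per-cell least squares on
that surface, variances at 1, $\omega$ at 0.1, random effects at 0, with
chain-specific Gaussian jitter (sd 0.1) to disperse chains. A non-finite
log-posterior at initialization is reported with the offending term.

Convergence is monitored on the scientific estimands — the hyperparameters,
BCR means, cell intercepts and slopes, $\omega$'s, $\eta$ and
$\beta_{0..6}$; the per-record random effects and the cell-year latent
surface are treated as nuisance quantities.

Two numerical choices worth knowing about:

* **Covariate scaling.** DIST, DURA and NOOB are centered and scaled to unit
  variance internally (raw minutes and kilometres condition the posterior
  poorly); `coef(fit)` back-transforms to the original scale,
  `coef(fit, scale = "working")` reports the sampling scale.
* **Weak identifiability of the overall level.** A common shift of
  $\log\gamma$ can in principle be absorbed by all route-by-observer effects
  moving together (and $\beta_0$ moving against it); it is identified only
  through the mean-zero prior on the effects. With realistically many
  route-observer pairs this is unproblematic, but on very small fixtures the
  direction mixes slowly — the package's cross-check tests pin the random
  effects at zero for exactly this reason.

## Data structuring

The preprocessing functions apply the field's standard structuring rules.
Route counts are zero-filled (`zero_fill_bbs()`: a count-0 record for every
surveyed route-year without a detection) and flagged for first-year
observers against the full archive (`flag_first_year()`). Checklists are
kept only if complete and within strict effort bounds — duration < 300 min,
distance < 5 km, party < 10 observers (`filter_checklists()`; the bounds are
read literally as strict inequalities). Start times become the 24-h-period
pair $\cos(2\pi s/86400), \sin(2\pi s/86400)$ (`solar_time_covariates()`);
when only clock time is available, `clock_to_solar_seconds()` applies the
4-minutes-per-degree approximation, as no exact conversion is prescribed.
Spatiotemporal thinning (`subsample_checklists()`) operates on a 5-km
hexagonal lattice by 7-day week blocks anchored at June 1 — week boundaries
and hex orientation are package choices, documented rather than inferred —
in two modes mirroring the frequent-species vs rare-species treatments:
`"balanced"` keeps at most one detection and one non-detection per
hex-week (read literally from "one detection and one non-detection
checklist"), `"retain_detections"` keeps every detection and one
non-detection. Mode is a per-species configuration flag, never
auto-detected. Subsampling is seeded; ties are uniform.

The reference grid (`build_grid()`) is a ceil-covering tiling with half-open
cell membership and lowest-id tie-breaks for boundary centroids — both
chosen to make assignment deterministic and order-independent. All geometry
is planar in km; real data must be projected (the original analysis used
Albers Equal Area) before ingestion, which keeps projection concerns out of
the numerical core. Species range is the union of whole BCRs containing any
detection (`define_range()`), and `distance_to_edge()` measures from cell
centroids to the boundary of the union of in-range cells (the range is a
polygon union by definition) unless explicit range polygons are supplied.
Vagrant removal is deliberately an upstream user decision — an exclusion
list, never a guessed rule.

## The synthetic-data generator

`sim_config()` / `simulate_truth()` / `simulate_bbs()` / `simulate_ebird()`
forward-simulate the model exactly as written above, so every downstream
stage can be tested against known truth. The reference conditions are an
8 × 6 cell landscape in 4 ecoregions over 2010–2019 with
$\mu^{[\beta]} = 0.05$, $\tau = \sigma = 0.05$, $\sigma^{[\gamma]} = 0.01$,
$\omega = 0.3$ in both streams, two routes per cell and on average five
checklists per cell-year. The grand intercept defaults to
$\mu^{[\alpha]} = 7$: the route-level intensity is
$e^{7} \cdot 25/12{,}321 \approx 2.2$ birds per visit, a typical magnitude
for a moderately common species and the smallest scale at which the
observation models are informative at desk scale (an intercept near 0 would
put essentially every simulated count at zero). The first-year effect
defaults to $\eta = -0.2$ (first-year observers record somewhat fewer
birds), and the checklist truth to $\beta_0 = \log(25/12{,}321)$ with small
plausible effort effects $(0.3, 0.05, -0.3, 0.2, 0.002, 0.05)$ on the raw
covariate scales; these generative values are package choices where no
reference value exists, fixed once. Effort covariates span the
filter-compliant space (TYPE ~ Bernoulli(0.5), DIST ~ U(0,5) km and 0 when
stationary, DURA ~ U(5,300) min, NOOB ~ 1 + Binomial(9, 0.2), start seconds
~ U(0, 86400)), with an optional fraction drawn to breach an effort bound
for filter testing. Observer careers are simulated explicitly (tenure
changes with configurable turnover; incoming observers are new to the
archive with configurable probability), so the generator's first-year flags
derive from histories exactly as `flag_first_year()` computes them.

What the generator does **not** emulate: spatial autocorrelation beyond the
BCR blocks, preferential sampling of habitat by observers, taxonomic
reporting biases, or group-checklist duplication. Passing recovery tests on
synthetic data therefore show the estimator is correct *under the model's
own assumptions*, not that real surveys satisfy those assumptions.

## Precision comparison

Following the modified CV convention, abundance parameters are compared by
`(q97.5 − q2.5)/|q50|` of their posteriors (`cv_relative()`; cells with a
numerically zero median are flagged and excluded, since the ratio is
undefined) and trends by the raw interval width (`cv_width()` — a relative
CV would explode for near-zero trends). Quantiles are pooled-chain
empirical quantiles with linear interpolation (type 7); CV values depend on
this convention, so it is fixed and documented. `compare_models()`
differences the per-cell CVs (BBS-only minus joint; positive = joint more
precise) and reports the proportion of cells strictly improved. Because no
per-cell aggregation is prescribed for the year-specific parameter, the
package uses the mean over years of each cell's $\gamma$ CVs — one number
per cell — without asserting this matches any other convention. Optional
strata (quartiles of joint-model $\alpha$ medians, distance to range edge,
per-cell route and checklist counts) support the standard
where-does-integration-help diagnostics.

## Problem sizes and what the package's own experiments show

The package's recovery experiment simulates the reference conditions
(48 cells, 4 BCRs, 10 years, ~960 route records, ~2400 checklists) and fits
the joint model with the test profile; across 10 replicates the generative
grand mean intercept and slope fall inside their 95% intervals and all
monitored $\hat R < 1.2$. The precision experiment uses a 24-cell landscape
with at most one route per cell and ~20 checklists per cell-year over five
seeds; the joint model yields lower $\alpha$ CVs than the BBS-only model in
well over half the cells, reproducing the qualitative headline direction of
data integration. These sizes are the package's chosen desk-scale
experimental conditions; `scripts/acceptance.R` re-runs both from scratch.
At this scale the joint model also tightens trend intervals — with a single
route per cell the BBS-only trend posterior is very diffuse, so there is no
contradiction with the observation that on continental data the
structured-only model often yields tighter trends.

## Known limitations

* Linear trends only; a ten-year window can hide non-monotone change, and
  added abundance precision does not imply added trend precision.
* Relative, not absolute, abundance: neither stream supports detection
  probabilities, and the index is anchored by the assumed 25-km² effective
  route area.
* One species at a time; no SGS-style third stream; no extra lognormal
  noise on the checklist intensity (flocking species with extreme counts
  may need it).
* The sampler's chains are reproducible for a seed on a given platform;
  bit-identical draws across compilers are not guaranteed.
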