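---
title: "Distance-decay modelling of dredging pressure fields: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-decay modelling of dredging pressure fields: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumeED)
```

## The problem

Dredging near coral reefs mobilises fine sediment into turbid plumes. The
plume's pressures — elevated suspended sediment concentration (SSC),
reduced underwater light, and sediment deposition on the seabed and on
coral surfaces — all decline with distance from the excavation, but at very
different rates, and the biological responses (smothering of colonies,
mucous-sheet production, partial mortality) contract to a much smaller
footprint than the visible plume. plumeED quantifies each footprint with a
single statistic, the *effect distance*: the distance at which only a
fraction $q$ of the modelled effect remains, denoted ED10 ($q = 0.1$, 90%
of the effect dissipated) and ED50 ($q = 0.5$).

## The decay model

Each metric is transformed to a scale on which its relationship with
$\log_{10}$ distance is approximately linear with homoscedastic noise:
$\log_{10}$ for SSC, square root for the daily light integral (DLI), and
the logit for quantities bounded in $(0,1)$ — the deposition index, the
silt+clay fraction of seabed sediment, and cover-score exceedance
proportions. On the transformed scale the model is a linear mixed model,

$$y_{jk} = \beta_0 + \beta_1 \log_{10} d_j + u_j + v_k + \varepsilon_{jk},$$

with $d_j$ the distance (km) of site $j$ from the source, $u_j \sim
N(0,\sigma_u^2)$ a site random intercept, $v_k \sim N(0,\sigma_v^2)$ a
fortnight random intercept shared across sites (dredging-intensity
fluctuations move all sites together), and residual
$\varepsilon_{jk} \sim N(0,\sigma_\varepsilon^2)$. Random effects are
intercepts only. For site-level pooled responses (coral score exceedance,
seabed compositions) there is one value per site, so both random effects
are dropped and the model degenerates to a Bayesian simple regression —
keeping the variance components identifiable.

Priors are near-flat conjugate choices: $N(0, 100^2)$ on $\beta_0,\beta_1$
and InverseGamma(0.001, 0.001) on each variance. Site random effects are
retained and partially pooled even though distance is site-constant (each
site contributes a single distance); the proper prior keeps $\sigma_u$
identified, and the posterior for $\beta_1$ honestly widens to reflect the
between-site confounding.

### The Gibbs sampler

`fit_decay()` samples the posterior with a purpose-built blocked Gibbs
sampler. All location parameters $\theta = (\beta, u, v)$ are drawn in one
block from their joint multivariate-normal full conditional given the
variances,

$$\theta \mid \cdot \sim N\!\big(Q^{-1}W'y/\sigma_\varepsilon^2,\; Q^{-1}\big),
\qquad Q = W'W/\sigma_\varepsilon^2 + P,$$

with $W = [X\;Z_u\;Z_v]$ and $P$ the diagonal prior precision; the
variances then have standard inverse-gamma conditionals. Blocking matters:
the intercept and the means of the random-intercept vectors are strongly
correlated a posteriori, and one-at-a-time updates random-walk along that
ridge (split-$\widehat R$ around 1.5 at desk-scale iteration counts in our
experiments), whereas the joint draw removes the coupling entirely
(split-$\widehat R$ within 0.002 of 1). The location-block dimension is
small (2 + sites + fortnights, about 57 in the default design), so the
per-iteration Cholesky factorisation is cheap.

Chains start overdispersed in the variance components (log-uniform draws
spanning two orders of magnitude); the first location draw is then exact
given those variances. Convergence is monitored with split-$\widehat R$
(each chain split in half, so within-chain drift registers), computed for
every parameter; a warning is raised above 1.05. The production profile is
5 chains with 10,000 burn-in and 20,000 kept iterations; all package tests
and examples use `mcmc_test_profile()` (3 chains, 500 burn-in, 1,500 kept),
which these conjugate, fast-mixing conditionals comfortably support.

### Effect distances

ED is defined on the *natural* (back-transformed) scale. With
$f(d) = g^{-1}(\beta_0 + \beta_1\log_{10} d)$ the population-mean curve
(random effects at zero, transform $g$), ED$_q$ solves

$$f(\mathrm{ED}_q) = f(d_{\mathrm{far}}) + q\,\big(f(d_{\mathrm{near}}) -
f(d_{\mathrm{far}})\big),$$

between the nearest (0.19 km) and farthest (34.8 km) monitored distances.
Under the identity transform the solution is the slope-free closed form
$\log_{10}\mathrm{ED}_q = \log_{10} d_{\mathrm{far}} + q(\log_{10}
d_{\mathrm{near}} - \log_{10} d_{\mathrm{far}})$; all other transforms use
monotone bisection on the $\log_{10} d$ axis to a tolerance of $10^{-9}$.
The natural-scale definition is deliberate: on the transformed scale every
metric would collapse to the identity geometry and all EDs would be equal,
whereas back-transformed EDs depend on the coefficients through the
curvature of $g^{-1}$, which is what makes them metric-specific.

Uncertainty comes from the posterior: ED$_q$ is computed per draw, and the
reported estimate is the posterior median with the 2.5th–97.5th percentiles
as the 95% credible band. Draws whose slope has the wrong sign relative to
the posterior-median direction (or is numerically zero) have no dissipation
point in the monitored direction; they are clipped to the interval endpoint
adjacent to the zero-slope limit ($d_{\mathrm{far}}$ for $q \le 0.5$,
$d_{\mathrm{near}}$ otherwise) and counted in `n_clipped`, keeping the
posterior sample size fixed rather than biasing the band by rejection. If
more than half the draws are degenerate the ED is declared not estimable.

## Preprocessing choices

* **SSC** is turbidity (NTU) times a fixed conversion factor of 1.8 mg/L
  per NTU.
* **DLI** integrates per-second quantum flux over the civil day
  ($\Sigma\,\mathrm{flux}\times\mathrm{interval}/10^6$ mol m⁻² d⁻¹);
  missing samples are mean-imputed within the day, making the result
  sampling-interval invariant for constant flux.
* **Deposition index**: the optical-backscatter deposition sensors are
  uncalibrated and a true accumulation rate cannot be recovered from their
  output, so daily means are min-max normalised to $[0,1]$ per site. The
  index is invariant to affine rescaling of the instrument units; a
  constant series triggers a warning and maps to zero.
* **Running means** are trailing (right-aligned) — the pressure
  experienced *up to* a day, using no future data: 14 d for SSC and DLI,
  60 d for the deposition index. A window value is emitted only when at
  least half its days are present (`min_window_coverage = 0.5`), a
  pragmatic allowance for fouled and serviced loggers.
* **Fortnight summaries** take the maximum of the running-mean values in
  each non-overlapping 14-day bin anchored at the dredging start. The
  maximum is used for all three metrics, including DLI; because maximum
  light is arguably not a pressure, `preprocess_config(dli_stat = "min")`
  switches DLI to the bin minimum.
* **Score exceedance**: the fraction of observations (colony × survey)
  with cover score ≥ 3, i.e. more than 5% of the surface covered. The
  denominator is observations rather than colonies (a per-colony-ever
  variant is available). Colonies ever flagged as dislodged are excluded
  whole, including their earlier surveys. Exceedance proportions enter the
  logit fits through the empirical-logit correction
  $(xn + c)/(n + 2c)$, $c = 0.5$, applied whenever exact 0/1 occur; the
  deposition-index fit uses $n = 60$ (the smoothing-window length) and the
  composition fit $n = 100$ as effective denominators.
* **Percent-cover bands** are printed as integers (1 = 0%, 2 = 1–5%,
  3 = 6–33%, …), which leaves gaps for fractional covers; bands are closed
  downward by the half-open convention (previous upper, upper], so 5.5%
  scores category 3.
* **Particle sizes** use the four-class scheme gravel (> 2 mm), sand
  (2000–62.5 µm), silt (62.5–4 µm), clay (< 4 µm). The gravel class is
  open-ended above 2 mm, and bins straddling a class boundary are split
  pro-rata on the log-size axis (laser-diffraction output is log-binned).

## The synthetic-data generator

No monitoring data are distributed with the package, so a generator
produces datasets with exactly the statistical structure the analysis
assumes — the fitted model run forward rather than a hydrodynamic
simulation, which makes parameter recovery a well-posed test. The default
design: 17 sites log-spaced from 0.19 to 34.8 km; a 530-day dredge phase
(38 fortnights) preceded by a 98-day baseline; daily water-quality records;
50 tagged colonies per site topped up to at least 20 massive Porites;
fortnightly colony surveys; one baseline and three post-dredging
particle-size compositions per site.

Generating parameters mirror the study conditions where these are stated
and otherwise sit at values a field monitoring program would find
realistic: transformed-scale slopes of −0.8 per log10 km for SSC and the
deposition index and +1.0 for √DLI; random-effect SDs of 0.3 (site), 0.2
(fortnight) and 0.2 (residual); smothering exceedance probabilities
declining from roughly 40% near the source to under 1% at the far sites,
with branching and corymbose morphologies never smothering regardless of
distance; mucous-sheet and mortality models of the same form at lower
levels; 5% of colonies dislodged at random; and a near-field silt+clay
enrichment of 5× immediately after dredging, relaxing to 2.6× in later
surveys and declining to 1 at the far endpoint along the log-distance
axis. The baseline phase has no distance gradient and sits at each
metric's far-field (ambient) level, so pre-dredging panels are flat.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: spatially correlated plume excursions, tidal and
weather signals, sensor drift and fouling artifacts beyond daily
averaging, non-normal heavy-tailed residuals, and any feedback between
deposition and colony condition. Two structural points deserve note.
First, the fortnightly-maximum-of-running-mean summary of noisy daily data
is upward-biased relative to the fortnight-level model mean, so parameters
recovered through the full daily chain are only approximately the
generating ones; recovery tests therefore use the fortnight-level panel
generator (`simulate_decay_panel()`), which is the model itself. Second,
the per-site min-max normalisation that defines the deposition index makes
an exact noise-free round-trip impossible for that channel (a noise-free
two-level series degenerates under min-max), so round-trip identities are
tested on the SSC and DLI paths.

## Numerical choices and degenerate inputs

Bisection tolerance $10^{-9}$ on $\log_{10} d$ (60 halvings of a 2.26-wide
interval); closed forms used where available and cross-checked against
bisection to $10^{-6}$ relative in the tests. A fully saturated logit
curve (numerically flat between the endpoints) falls back to the
zero-slope limit, which is the identity-geometry ED. Designs with a single
distinct distance are rejected as singular, as are site effects with fewer
than three sites or fortnight effects with fewer than two fortnights.
`sqrt`-transformed linear predictors are truncated at zero before squaring
so the natural-scale curve stays non-negative and monotone. The empirical
variance of a constant deposition series is guarded (all-zero index with a
warning). Seeds fan out from the top-level seed by fixed offsets so any
stage can be re-run in isolation; identical configuration and seed give
byte-identical tables.

## Problem sizes used in the tests

The test suite fits the default 17 × 38 panel (646 observations) with the
desk-scale MCMC profile, runs a 20-replicate coverage experiment at the
same size (95% credible intervals are required to cover each generating
parameter in at least 80% of replicates, and the posterior-median ED10 to
sit within ±20% of the plug-in truth in at least 16 of 20), and checks the
sampler against the closed-form conjugate posterior at 4,500 kept draws.
At that draw count the Monte-Carlo standard error of a posterior *SD*
estimate is about 1% relative, so the SD comparison is made at three times
its Monte-Carlo standard error while posterior *means* are required to
match to three significant figures.

## Known limitations

The site random effect is confounded with distance (one distance per
site), so $\sigma_u$ and $\beta_1$ are only jointly identified through the
prior and the log-linear mean structure; EDs inherit that uncertainty
honestly through the per-draw inversion but cannot escape it. Fortnight
effects are shared across sites, which overstates temporal coherence if
real plume excursions are local. The ED definition is anchored to the
monitored interval's endpoints; it does not extrapolate beyond them, and a
different monitoring extent changes the statistic. Proportion metrics with
very small denominators lean on the empirical-logit correction, and
site-level pooled fits ignore within-site binomial sampling error beyond
that correction.

## A worked run

```{r run, eval = FALSE}
cfg <- run_config(sim = sim_config(seed = 1), mcmc = mcmc_test_profile(),
                  seed = 1)
run <- run_pipeline(cfg)
run$ed_table
```

The returned table has one row per metric with ED10 and ED50 posterior
medians (km, two significant figures) and their 95% credible intervals;
`run$fits` holds the per-metric posterior summaries and split-$\widehat R$
diagnostics, and `decay_curve_data(run, "ssc")` extracts the observed
values and fitted credible band for plotting.
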