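# plumeED

Distance-decay modelling of dredging pressure fields and coral smothering
responses.

Large capital dredging projects near coral reefs raise suspended sediment
concentrations (SSC), cut underwater light, and deposit fine sediment on
the seabed and on coral surfaces. Each of these pressures — and each
biological response to them — declines with distance from the excavation,
but over very different ranges: turbid plumes can be visible tens of
kilometres away while coral smothering is confined to a few kilometres.
plumeED is for environmental scientists and dredging-monitoring
practitioners who need to put a defensible number on each footprint.

## The model and the statistic

For each metric, a transformed response (log10 SSC, √DLI, logit of
bounded indices and proportions) is regressed on log10 distance with a
Bayesian linear mixed model,

    y_jk = β0 + β1·log10(d_j) + u_j + v_k + ε_jk,

where `u_j ~ N(0, σ_u²)` is a site random intercept and `v_k ~ N(0, σ_v²)`
a fortnight random intercept shared across sites. The posterior is drawn
by a purpose-built blocked Gibbs sampler (conjugate near-flat priors,
overdispersed chains, split-R̂ diagnostics).

The headline statistic is the **effect distance** ED_q: with
`f(d) = g⁻¹(β0 + β1·log10 d)` the population-mean curve on the natural
scale, ED_q is the distance where only the fraction `q` of the effect —
the difference between predictions at the nearest (0.19 km) and farthest
(34.8 km) monitored distances — remains:

    f(ED_q) = f(d_far) + q·(f(d_near) − f(d_far)).

ED10 (`q = 0.1`) marks 90% dissipation, ED50 the half-effect distance.
Applied per posterior draw, this yields a median and a 95% credible band
for every metric.

Because the underlying monitoring data of such projects are typically
proprietary, the package ships a synthetic-data module that generates
whole monitoring campaigns (daily water-quality loggers, fortnightly
colony score panels on the 1–7 cover scale, before/after seabed
particle-size compositions) with the statistical structure the analysis
assumes — so the entire pipeline is testable end to end.

## Worked example

```r
library(plumeED)
cfg <- run_config(sim = sim_config(seed = 1), mcmc = mcmc_test_profile(),
                  seed = 1)
run <- run_pipeline(cfg)
run
#> Distance-decay run: 7 metrics, max split R-hat 1.002
#>             metric ed10_km ed10_ci95 ed50_km ed50_ci95
#>                ssc     4.2   2.1-9.7    0.52 0.39-0.84
#>                dli    25.0     24-26    5.40   4.6-6.1
#>         depo_index    21.0     21-21    2.90   2.8-3.1
#>          silt_clay    17.0     16-17    2.10     2-2.3
#>       sediment_ge3     3.5     3-4.2    0.52 0.49-0.55
#>          mucus_ge3     5.6     4.5-7    0.61 0.56-0.69
#>  mortality_nonzero     1.7  0.88-7.7    0.37 0.31-0.71
```

Reading the table: on this synthetic campaign the light and deposition
pressure fields extend to ~21–25 km (ED10) while sediment smothering of
corals (`sediment_ge3`: fraction of surveys with a sediment cover score of
3 or more, i.e. >5% of the colony surface) has dissipated by 90% within
3.5 km of the source, and substantial (50%) effects are confined to the
first ~0.5 km. Each fit carries its posterior summaries:

```r
summary(run$fits$sediment_ge3)
#>                  mean         sd       2.5%        50%      97.5%      rhat
#> beta0       -2.375642 0.07864799 -2.5297624 -2.3748801 -2.2179631 0.9994934
#> beta1       -1.932205 0.09791003 -2.1232054 -1.9316113 -1.7395739 0.9998253
#> sigma_resid  0.272700 0.05513068  0.1889999  0.2648732  0.3982342 1.0002999
```

`decay_curve_data(run, "ssc")` returns the observed values and the fitted
credible band on the natural scale for plotting, and
`run_pipeline(cfg, out_dir = "out")` writes all tables (ED table, fit
summaries, curve data, JSON run log) as CSV/JSON.

See the vignette `vignettes/distance-decay-methods.Rmd` for the model,
its assumptions, the preprocessing rules (running means, fortnightly
maxima, score exceedance, fate reclassification, particle-size classes)
and the design decisions.

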