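# bymst

Bayesian spatio-temporal disease mapping for small-area count panels:
a binomial logit model with a BYM (Besag–York–Mollié) convolution prior,
an overall time trend, area-specific differential trends, and
exceedance-probability classification of areas by risk level and risk
trend.  Written for epidemiologists and biostatisticians who analyse
area × year tables of events (e.g. under-five deaths) and exposures
(live births) over a contiguity map, and who want the full pipeline —
descriptive statistics, spatial/serial autocorrelation diagnostics,
MCMC fitting, convergence checks, and risk classification — in one
reproducible package.

## The model

For area *i* = 1…N and year *t* = 1…T, with *n<sub>it</sub>* births and
*y<sub>it</sub>* deaths,

```
y_it ~ Binomial(n_it, mu_it)
logit(mu_it) = alpha + (s_i + u_i) + d0 t* + v_t + d1_i t* + eps_it
```

where `t* = t - midpoint` is the centered time index and

* `alpha` — overall logit risk (flat prior),
* `s_i` — spatially structured effect, intrinsic CAR (ICAR) prior on the
  binary contiguity matrix W: conditional mean equal to the neighbour
  average, conditional variance `sigma2_s / m_i`,
* `u_i` — spatially unstructured effect, iid Gaussian (together with
  `s_i` this is the BYM convolution),
* `d0` — overall linear trend (flat prior), `v_t` — Gaussian nonlinear
  trend residual,
* `d1_i` — area-specific differential slope, ICAR prior across areas,
  so neighbouring areas have similar trend departures,
* `eps_it` — iid Gaussian cell-level term absorbing extra-binomial
  dispersion.

`s`, `d1` and `v` carry sum-to-zero identification constraints.  The
five standard deviations get positive half-Gaussian priors `N+(0, 10)`
by default; a Gamma-on-precision alternative (with exact conjugate
updates) is available via `bym_prior("gamma")`.

Fitting is Metropolis-within-Gibbs (single-site random-walk updates,
adaptive proposals frozen at the end of burn-in, a likelihood-free
balancing move for the `s`/`u` split), with multiple chains from
overdispersed starts and Gelman–Rubin R̂ per scalar parameter
(threshold 1.04).

Areas are classified from posterior exceedance probabilities:
`p(exp(u_i + s_i) > 1 | data) > 0.8` → high risk, `< 0.2` → low risk,
otherwise medium; analogously `p(d1_i > 0 | data)` → increasing /
decreasing / stable local trend.

## Worked example

```r
library(bymst)

# a synthetic 75-area x 7-year panel with known truth
sim <- simulate_panel(study_scenario(), seed = 1)
print(sim$panel)
#> Mortality panel: 75 areas x 7 years (2011-2017)
#>   total births 7753604, total deaths 148607, pooled rate 19.17 per 1000

# preliminary diagnostics: spatial and serial autocorrelation of rates
head(moran_by_year(sim$panel, sim$adj, n_permutations = 999, seed = 2), 3)
#>   year         I    expected p_value
#> 1 2011 0.5672800 -0.01351351   0.001
#> 2 2012 0.4653631 -0.01351351   0.001
#> 3 2013 0.2321036 -0.01351351   0.002
mean_lag1_acf(sim$panel)
#> [1] 0.3202486

# fit (reduced settings; defaults are 100k iterations / 30k burn-in)
fit <- bym_st(sim$panel, sim$adj,
              control = bym_control(n_iterations = 12000, n_burnin = 3000,
                                    n_chains = 2), seed = 3)
print(fit)
#> Spatio-temporal BYM fit: 75 areas x 7 years
#>   2 chain(s), 9000 retained draws each (of 12000 iterations, burn-in 3000, thin 1)
#>   max R-hat 1.015 (threshold 1.04)
#>    parameter    mean     sd    q2.5     q50   q97.5   rhat
#> 1      alpha -3.9941 0.0146 -4.0229 -3.9943 -3.9637 1.0000
#> 2         d0 -0.0290 0.0085 -0.0484 -0.0290 -0.0121 1.0044
#> ...

# risk and trend classification
cls <- classify_areas(fit)
classification_report(cls)$risk
#>   risk_category count percent
#> 1          high    30      40
#> 2           low    33      44
#> 3        medium    12      16

# posterior risk surface and overall relative trend exp(d0 t* + v_t)
surf <- risk_surface(fit)
head(surf$trend, 2)
#>   year rel_trend       lo       hi
#> 1 2011  1.081168 1.062693 1.099776
#> 2 2012  1.031928 1.012434 1.051655
```

The posterior mean of `alpha` (−3.99, i.e. a baseline risk of about 18
per 1000 births) and of `d0` (−0.029, a ~3% annual decline in the odds)
recover the generator's truth (−4.00 and −0.03); the per-area
classification reflects the simulated spatial field.

A YAML-driven pipeline (`pipeline_simulate()`, `pipeline_fit()`,
`pipeline_classify()`) writes every artifact — panel, edge list, Moran
table, draws CSV, posterior summaries, classification, risk surface —
into an output directory for archivable, seed-reproducible runs.

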