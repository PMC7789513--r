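---
title: "Spatio-temporal BYM disease mapping: model, sampler, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal BYM disease mapping: model, sampler, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bymst)
```

## The model and its assumptions

`bymst` fits area–year panels of counts: for area $i = 1,\dots,N$ and
year $t = 1,\dots,T$ with exposures $n_{it}$ (live births) and events
$y_{it}$ (deaths),

$$
y_{it} \sim \mathrm{Binomial}(n_{it}, \mu_{it}), \qquad
\operatorname{logit}(\mu_{it}) = \alpha + (s_i + u_i) + d_0 t^{*} + v_t +
d_{1i} t^{*} + \varepsilon_{it},
$$

with $t^{*}$ the time index centered at the mid-period.  The components
and their priors:

* $s_i$ — spatially **structured** effect with an intrinsic conditional
  autoregressive (ICAR) prior on the binary contiguity matrix $W$:
  conditionally on its neighbours, $s_i$ is Gaussian with mean the
  neighbour average and variance $\sigma_s^2 / m_i$ ($m_i$ = neighbour
  count).  The joint density is the pairwise form
  $\exp\{-\tfrac{1}{4\sigma_s^2}\sum_{ij} w_{ij}(s_i - s_j)^2\}$, an
  improper distribution with rank $N-1$ on a connected graph.
* $u_i$ — **unstructured** iid Gaussian effect; together with $s_i$
  this is the BYM convolution, capturing clustering and heterogeneity
  respectively.
* $d_0 t^{*} + v_t$ — overall trend: a linear slope plus an iid
  Gaussian residual $v_t$ that lets the common trend bend.
* $d_{1i} t^{*}$ — **differential local trend**: each area's linear
  departure from the common trend, with an ICAR prior across areas so
  neighbouring areas drift similarly.  This term carries the
  spatio-temporal interaction.
* $\varepsilon_{it}$ — iid Gaussian cell-level term.  Binomial panels
  of this kind are typically overdispersed; $\varepsilon$ is the
  model's overdispersion device.  No covariates enter the linear
  predictor.

The model assumes a complete panel (every area–year cell present, at
least one exposure per cell — zero-exposure cells are rejected at
ingest rather than imputed), consecutive years, a connected contiguity
graph, and a closed population (no migration between areas).

### Identification

$\alpha$ and $d_0$ take flat priors, standard for fixed effects in this
model class.  Because the ICAR prior is invariant to constant shifts
and $v_t$ is exchangeable with $\alpha$, the vectors $s$, $d_1$ and $v$
are constrained to sum to zero; $\alpha$ then carries the overall
level, $d_0$ the overall slope.

### Hyperpriors

Each of the five standard deviations
($\sigma_s, \sigma_u, \sigma_v, \sigma_d, \sigma_\varepsilon$) gets a
positive half-Gaussian prior $N_+(0, 10)$ by default — weakly
informative on the logit scale, where plausible random-effect SDs are
well below 1.  A Gamma prior on the precisions
($1/\sigma^2 \sim \Gamma(0.001, 0.001)$ by default) is available via
`bym_prior("gamma")` for compatibility with classic WinBUGS-style
analyses; under it the variance updates are exact conjugate Gibbs
draws.  Both conventions appear in the applied literature, sometimes in
the same paper; we treat the half-Gaussian-on-SD statement as the
operative choice and keep the Gamma route as an option.

## The sampler

Estimation is Metropolis-within-Gibbs with single-site random-walk
updates (Rcpp core, one full log-likelihood cache of the linear
predictor so each update costs only its touched cells):

* $\alpha$, $d_0$: global random-walk moves.
* $s_i$, $u_i$, $d_{1i}$, $\varepsilon_{it}$: single-site moves; the
  ICAR prior ratio for $s_i$/$d_{1i}$ uses only the neighbour terms.
* After each $s$ and $d_1$ sweep the block mean is transferred into
  $\alpha$ / $d_0$.  This projection is exact MCMC: the ICAR density
  and the likelihood are both invariant along the shifted direction,
  and the receiving fixed effect has a flat prior.
* $v_t$: moves of the form $v' = v + \delta\,(e_t - \mathbf{1}/T)$,
  which never leave the sum-to-zero subspace.  The target is therefore
  exactly the centered Gaussian, whose per-coordinate variance is
  $\sigma_v^2 (1 - 1/T)$ — the quantity the prior-recovery test checks.
  (A naive "update then re-center" scheme has a proposal-scale-dependent
  stationary law; we avoided it for $v$.)
* Balancing move: $(s_i, u_i) \to (s_i + c,\, u_i - c)$ leaves
  $s_i + u_i$ — all the likelihood sees — untouched, so it needs no
  likelihood evaluation.  Without it the split between $\sigma_s^2$ and
  $\sigma_u^2$ mixes extremely slowly (a well-known BYM pathology);
  with it all core parameters reach $\hat R$ near 1 within a few
  thousand iterations on the test problems.
* Variances: random walk on $\log \sigma$ under the half-Gaussian
  prior (with the ICAR terms entering at rank $N-1$, and $v$ at rank
  $T-1$ because it lives on the centered subspace), or conjugate Gibbs
  under the Gamma prior.

Proposal scales adapt toward a 20–50% acceptance window during the
first `adapt_until` iterations only (default: the burn-in), so retained
draws come from a fixed kernel and detailed balance is preserved.
Chains run from overdispersed starts (chain-indexed offsets on
$\alpha$, alternating small/large initial variances); the plain
Gelman–Rubin $\hat R$ is reported per scalar parameter (the split-chain
variant is available via `gelman_rubin(split = TRUE)`), with a warning
threshold of 1.04.  Sampling uses R's RNG, so a seed makes every run
bit-reproducible.

Validation-oriented switches — `use_likelihood = FALSE` (prior-only
sampling) and per-block `update` flags — exist so the test suite can
check the sampler against analytic targets: prior-moment recovery for
$u$ and $v$, and an intercept-only posterior against a deterministic
quadrature oracle.

## Classification rules

With pooled post-burn-in draws, each area gets

* an excess-risk probability $p(\exp(u_i + s_i) > 1 \mid \text{data})$,
  the fraction of draws with $u_i + s_i > 0$: $> 0.8$ high risk,
  $< 0.2$ low risk, otherwise medium (codes 1/2/3);
* a trend probability $p(d_{1i} > 0 \mid \text{data})$: $> 0.8$
  increasing, $< 0.2$ decreasing, otherwise stable.

The published rule states both outer inequalities strictly, so the
boundary values 0.8 and 0.2 fall into the middle class; the tie-break
is tested explicitly.  The trend probability is computed from the same
joint posterior as the risk classification (conditioning on the risk
class changes nothing computationally, since both are functionals of
one posterior).  We apply no additional credible-interval filter on
top of the 0.8/0.2 rule.  The fitted risk surface reports
$1000\,\mu_{it}$ (posterior mean and equal-tailed 95% interval per
cell) and the overall relative trend $\exp(d_0 t^{*} + v_t)$ per year.

## Contiguity input

Queen contiguity (any shared boundary point) is the polygon default,
rook (shared segment) available by flag; an explicit edge list or a
WinBUGS-style `num`/`adj` file can be supplied instead.  With no
geometry engine among the package's dependencies, polygon contiguity is
derived from shared boundary *vertices* after coordinate snapping —
exact for grids and for administrative layers whose shared borders
carry matching vertex chains; layers digitized with mismatched vertices
should be pre-snapped or converted to an edge list.  Islands (areas
with no neighbours) and disconnected maps are rejected by default
rather than silently handled, since in a contiguous study region they
indicate data errors.

## The synthetic-data generator

`simulate_panel()` draws all latent fields from the model's own priors
($s$, $d_1$ via the exact sum-to-zero ICAR sampler — eigendecomposition
of the Laplacian with variance $\sigma^2/\lambda_k$ per non-null
eigenvector), draws births log-uniformly (default 1,000–60,000 per
area-year, mimicking right-skewed municipality sizes), and deaths
binomially.  `study_scenario()` fixes a 75-area (5 × 15 rook lattice),
7-year setting with $\alpha = \operatorname{logit}(0.018)$,
$d_0 = -0.03$, and variances
$(\sigma_s^2, \sigma_u^2, \sigma_v^2, \sigma_d^2,
\sigma_\varepsilon^2) = (0.035, 0.015, 0.0005, 0.035, 0.001)$, chosen
once so that simulated panels show per-year mean rates near 17–20 per
1000 with across-area SDs near 5–9, positive Moran's I in every year
(mean across years around 0.3–0.4), positive mean lag-1 autocorrelation,
and clear extra-binomial dispersion.

Two honest caveats about what the generator does *not* reproduce:

* **Serial correlation ceiling.**  The plug-in lag-1 autocorrelation of
  a $T = 7$ series is at most $16/28 \approx 0.57$ even for a noiseless
  linear trend, and binomial sampling noise at realistic exposures
  pulls the across-area mean to roughly 0.3–0.35 under this model.
  Real panels can show higher observed ACF than the fitted model's own
  generative process can produce at these exposures; passing tests
  therefore demonstrate correct model mechanics, not that every
  descriptive statistic of a real registry is matched.
* **Geometry.**  A rook lattice stands in for an irregular municipality
  map; degree distributions of real contiguity graphs are more skewed.

## Numerical choices and degenerate inputs

* Rates are per 1000 exposures; yearly summaries use the sample
  ($N-1$) standard deviation and unweighted across-area means.
* Moran's I uses binary (not row-standardized) weights, per the model's
  $W$; the permutation test is one-sided for positive autocorrelation
  with the $+1$ correction, default 999 permutations, seed recorded.
  Constant vectors are rejected (zero variance).
* The lag-1 ACF uses the plug-in estimator with the series mean;
  constant series are skipped with a warning.
* Cell log-likelihoods are computed on the logit scale
  ($y\eta - n\log(1+e^{\eta})$), stable for extreme $\eta$.
* `time_index()` centers at the median year for odd $T$ (integer
  $t^{*}$); for even $T$ or the general case it centers at the mean
  year, preserving $\sum_t t^{*} = 0$.
* Exact boundary probabilities 0.8/0.2 classify as medium/stable
  (strict outer inequalities).
* ICAR draws and retained $s, d_1, v$ draws satisfy their sum-to-zero
  constraints to $10^{-8}$ or better; the initial state is projected
  onto the constraint set with compensating shifts of $\alpha$, $d_0$.

## Problem sizes used for validation

The test suite exercises the full pipeline at sizes chosen to keep a
complete run comfortably fast while retaining power: oracle equivalence
on 4–6-area, 3-year instances; sampler validity on 9-area panels
(40,000-iteration prior-recovery and 60,000-iteration quadrature
checks); parameter recovery on 20 replicate 75 × 7 panels at 5,000
iterations / 1,000 burn-in with 95% CI coverage of the true $\alpha$
and $d_0$ in at least 17 of 20; Moran permutation calibration over 500
null replicates at 199 permutations.  Production analyses should use
the defaults (100,000 iterations, 30,000 burn-in, 2 or more chains) and
check the $\hat R$ table.

## Known limitations

* Single ICAR graph per fit: disconnected maps require per-component
  handling the package deliberately does not automate.
* No covariates, no CAR-proper/Leroux priors, no Poisson approximation;
  the binomial likelihood is exact.
* Cell-level $\varepsilon_{it}$ makes the parameter count proportional
  to $N \times T$; memory for retained draws grows accordingly (use
  `thin` for very long runs).
* The vertex-based polygon contiguity rule is a deliberate, documented
  approximation (see above).
* Choropleth rendering is out of scope; classifications can be exported
  to GeoJSON properties for external mapping tools.
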