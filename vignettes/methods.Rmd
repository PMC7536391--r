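---
title: "Models and methods in cropshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in cropshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cropshift` studies a question at the intersection of agronomy, climate
impacts and economics: if a changing climate shifts the geography of crop
productivity, how much of the resulting loss could be avoided by growing
crops in different places? Answering it requires three ingredients that this
package implements end to end: (i) a yield model that can predict how a crop
would respond to weather *in counties where it has never been observed*,
(ii) a validation harness that shows the model actually predicts better than
standard regression baselines, and (iii) a land-allocation optimizer that
turns predicted yields into profit-maximizing cropping patterns under
realistic constraints. Everything runs on synthetic county panels generated
by the package itself, so every claim in the test suite is checkable without
any external data.

## The hierarchical yield model

For one crop, log-yield of county $i$ in year $t$ follows

$$\log Y_{it} \sim N\!\left(\alpha_i + \beta_i^1 t + \beta_i^2\,
\mathrm{CDI}_{it} + \beta_i^3\, \mathrm{GDD}_{it} + \beta_i^4\,
\mathrm{EDD}_{it},\; \sigma_i^2\right)$$

with a linear technology trend $t$, a crop water deficit index (CDI),
growing degree days (GDD) and extreme degree days (EDD). The county
intercept and slopes are themselves modelled as linear functions of six
county-constant covariates (annual mean temperature, isothermality,
temperature seasonality, annual precipitation, precipitation seasonality,
and the crop's irrigation fraction):

$$\alpha_i \sim N\!\Big(a_0 + \sum_j b_j^0\, z_{ij},\; \sigma_\alpha^2\Big),
\qquad
\beta_i^k \sim N\!\Big(a_k + \sum_j b_j^k\, z_{ij},\; \sigma_{\beta^k}^2\Big).$$

This is partial pooling with covariate-driven means: the degree to which a
county's coefficients are shrunk toward the covariate prediction is
estimated from the data through $\sigma_\alpha, \sigma_{\beta^k}$. The
payoff is prediction in *unobserved* counties: a county that never grew the
crop still has covariates, so its coefficients are drawn from
$N(a_k + \sum_j b_j^k z_{ij}, \sigma_{\beta^k}^2)$ per posterior draw —
the covariate mean plus honest between-county dispersion. The package
asserts (and tests) that predictive spread in unobserved counties strictly
exceeds that of comparable observed counties.

Two residual-variance modes are provided: a single shared $\sigma$
(`variance_mode = "uniform"`) and per-county $\sigma_i$
(`variance_mode = "county"`). In the county mode the $\log \sigma_i$ get a
shared normal population prior; counties observed for few years would
otherwise have unidentified variances. Fits with at least two counties are
required in either mode, because the covariate model standardizes covariates
across counties.

### Scales, priors and defaults

Weather predictors are put on a per-crop standardized scale before
fitting: CDI, GDD and EDD are z-scored within crop (so coefficients read as
the fractional yield effect of a one-standard-deviation change, the
conventional way such sensitivities are mapped), and the trend is centered
at a base year but left in years, so trend coefficients are per-year rates.
Full z-scoring (not scaling alone) is used deliberately: county-mean GDD is
tens of standard deviations from zero, and an uncentered predictor would
make the county intercept nearly collinear with the GDD slope within every
county. The centers and scales are recorded and invertible
(`panel_scaling()`, `unstandardize_panel()`). Covariates are likewise
z-scored inside the model-building step, with scalings stored in the fit for
prediction in new counties.

Priors are weakly informative on the standardized scales: $N(0, 5^2)$ on
all hyper-intercepts and loadings, half-normal$(0, 2.5)$ on every standard
deviation, and in the county-variance mode $N(0,1)$ on the mean of
$\log\sigma_i$ with half-normal$(0,1)$ on its spread. With tens of counties
these priors are far weaker than the likelihood; they exist to keep the
sampler in a sane region, and the degree of pooling remains data-driven.

### The sampler

The posterior is explored by a blocked Gibbs sampler written for exactly
this model:

* each county's five effects $(\alpha_i, \beta_i^{1..4})$ are updated
  jointly from their conjugate 5-dimensional normal conditional, using
  precomputed per-county cross-products;
* each component's seven hyper-coefficients are updated jointly from their
  conjugate conditional;
* every SD parameter is updated by univariate slice sampling on the log
  scale (stepping-out with shrinkage);
* an interweaving step then re-draws each component's hyper-coefficients
  *and* group SD jointly in the non-centered parameterization, where the
  group SD enters the likelihood as a regression coefficient on the scaled
  county deviations. Alternating the two parameterizations
  (ancillarity–sufficiency interweaving) removes the slow mixing of small
  group SDs that a purely centered scheme exhibits; with it, a 200-county,
  40-year panel mixes to split-$\widehat R \le 1.01$ for all but the most
  weakly identified SD in a few thousand sweeps, in under two minutes on one
  CPU.

A non-centered parameterization throughout (the usual remedy for funnel
geometry in Hamiltonian samplers) was considered and rejected: blocked
conjugate updates do not take leapfrog steps through the funnel, and the
centered blocking with interweaving mixes better here while remaining
exactly conjugate. The sampler is deterministic given a seed, chains start
from jittered data-based estimates, and convergence is reported as
split-$\widehat R$ and effective sample size for every hyperparameter. A fit
exceeding $\widehat R = 1.01$ is flagged with a warning, never silently
returned. Slice/conjugate Gibbs transitions have no analogue of divergent
trajectories; the `divergences` diagnostic is always zero and retained only
for interface familiarity. On small datasets the sampler is cross-checked in
the test suite against an independent JAGS implementation of the identical
model.

### Pinned group SDs (the pooling limit)

`hier_spec(pin_group_sd = s)` fixes all five group SDs. Values below
$10^{-3}$ are treated as the exact degenerate limit: county effects are set
identically to their covariate-implied means, which collapses the model to a
Bayesian regression on the covariate-interacted design — precisely the
interacted least-squares specification. This is implemented as the exact
limit rather than by running the sampler at a tiny fixed SD because the
centered conditional updates then move in steps of order $s$, with mixing
time $O(1/s^2)$: the limit is well defined mathematically but pathological
computationally. The test suite verifies that posterior-mean county
coefficients under pinning match the interacted OLS point estimates to
better than 0.01 on the standardized scale.

### Point predictions

Following the convention of evaluating the mean function at the average of
the parameter draws, `point_predict()` averages parameters first and then
evaluates. Because the mean function is linear in the parameters the result
equals the average of per-draw predictions; the equality is asserted in a
test rather than assumed.

## Weather predictors

Daily degree days use the single-sine method: the diurnal cycle is
interpolated as a sine wave between `tmin` and `tmax`, and the day's degree
days above a base, capped at a ceiling, have a closed form via the
difference of two exceedance integrals. A constant-temperature day is the
analytic limit of the same formula, with no special branch. Extreme degree
days are the uncapped exceedance above the damage threshold, the standard
convention for heat-damage metrics. Seasonal GDD/EDD are sums of daily
values over the crop's calendar window, with missing days inside the window
a hard error.

The crop water deficit index is a normalized seasonal shortfall:
$\mathrm{CDI} = \sum_d \max(0, \mathrm{PET}_d - P_d) / \sum_d
\mathrm{PET}_d \in [0, 1]$. This is a deliberately simple supply–demand
deficit — it does not carry soil moisture between days or model runoff — and
it is isolated behind a single function so that a soil-moisture-accounting
alternative is a drop-in replacement. The shipped crop calendars (season
windows, GDD bases/ceilings, EDD thresholds) are conventional configuration
values, not estimates; users with crop-specific agronomy should edit them.
Note that a GDD ceiling may exceed the EDD threshold (as in the corn default
8/32 with EDD above 29): the two metrics are separate integrals, not a
partition of the temperature axis.

## The synthetic-data generator

The generator is first-class, tested code; it defines the study conditions
under which every downstream claim is evaluated. It emulates:

* six county covariates with realistic ranges (mean temperature about
  5–25 °C, warmer counties wetter by construction, Beta-distributed
  irrigation fractions);
* true hierarchical parameters: log-yield level around 4.6 (about 100
  units/acre), per-SD weather effects of realistic sign and size (EDD
  −0.20, GDD +0.15, CDI −0.12 per SD; +1%/year trend), covariate loadings of
  a few percent per SD — notably warmer counties being *less* sensitive to
  extreme heat, the adaptation signature — and residual SD 0.15;
* county-year predictors whose means track the covariates (hotter counties
  accumulate more extreme degree days) with interannual noise;
* missingness concentrated where a crop is unattractive: each crop is
  absent from counties in the bottom 15% of its covariate-implied mean
  log-yield, plus 2% random county-year dropout, with every county keeping
  at least its best crop — mirroring the fact that real panels only observe
  crops where someone chose to plant them, which is exactly the selection
  problem covariate-based prediction addresses;
* an economics table with per-crop price and cost levels, county land drawn
  lognormally, the observed (most planted) crop designated per county, and
  — by default — 40% of counties given a deliberately non-optimal observed
  crop so that hidden-cost calibration has realistic work to do. Costs of
  grown crops are floored so cultivation is profitable where it is
  observed; farmers do not persistently plant at a loss, and without this
  floor the status-quo counterfactual would include negative-profit
  baseline cells that no calibration could rationalize.

Two generator modes matter scientifically. In `"faithful"` mode the data
follow the fitted model's likelihood exactly — the regime for parameter
recovery and coverage checks. In `"misspecified"` mode county coefficients
receive additional heavy-tailed idiosyncratic noise (variance-matched
Student-$t_4$) that the covariates cannot explain. This is the regime where
the degree of pooling has empirical content: the fitted group SDs must come
out clearly positive (little pooling), covariate-interacted fixed-effects
regressions over-fit, and hierarchical shrinkage pays off out of sample.
What passing tests in these modes do *not* show is robustness to
features real panels have and the generator lacks: spatial autocorrelation
of county effects, measurement error in weather aggregation, price
endogeneity, and genuinely non-Gaussian yield shocks such as floods.

## Baselines and validation

Four least-squares specifications span the comparison space: uniform
intercept/slopes; county intercepts with uniform slopes; fully
covariate-interacted intercept and slopes; and county intercepts with
covariate-interacted slopes (the richest, which omits covariate main effects
on the intercept because county indicators absorb them). Designs are built
explicitly and rank-checked: a rank-deficient design is an error naming the
aliased columns, never a silent pseudo-inverse. Under county-intercept
specifications, prediction in an unseen county is an error by default, with
an explicitly flagged mean-intercept fallback available — the temporal
cross-validation used here holds out years, not counties, so the choice
never binds in the shipped harness.

Validation is a single temporal split (fit on the first three quarters of
years, evaluate on the rest) scored by
$R^2 = 1 - \sum(y - \hat y)^2 / \sum(y - \bar y)^2$, reported as-is even
when negative. Which observations define $\bar y$ under a temporal holdout
is genuinely ambiguous; the evaluation-set mean is the default and the
training-set mean is available via a flag. The acceptance suite checks the
qualitative pattern that matters: in-sample, richer models fit better by
nesting; out of sample on misspecified data, the county-intercept interacted
regression degrades while the hierarchical model holds up and outperforms
it, in at least nine of ten seeded replicates.

## The reallocation linear program

Given per-acre profits $\pi_{ic} = p_{ic}\hat Y_{ic} - o_{ic}$ from a
posterior draw's predicted yields, the optimizer solves

$$\max_{A_{ic} \ge 0} \sum_{ic} \pi_{ic} A_{ic}
\quad \text{s.t.} \quad
\sum_c A_{ic} \le \sum_c \bar A_{ic} \;\; \forall i, \qquad
\sum_i A_{ic} \le \sum_i \bar A_{ic} \;\; \forall c,$$

a transportation-polytope program: no county farms more land than today,
and no crop exceeds its national footprint (which also sidesteps
price-feedback effects by construction). Land may be left fallow when
nothing is profitable. A switching cost $s$ charges
$s \cdot \max(0, A_{ic} - \bar A_{ic})$ — expanding a crop beyond its
baseline footprint in a county — linearized with one slack variable per
cell; abandoning land is free. This is the simplest linearization consistent
with charging reallocation rather than abandonment; it keeps the program
linear and makes the status quo always feasible, so optimized profit
dominates status-quo profit draw by draw (asserted at run time, not
assumed).

The solver is a dense primal simplex written in the package (no LP library
ships with the supported stack): all-slack start (right-hand sides are
areas, hence non-negative, so no phase 1), Dantzig pricing with an automatic
switch to Bland's rule to guarantee termination under the heavy degeneracy
transportation polytopes produce, and the dual solution read off the final
tableau. Every solve carries an optimality certificate — relative duality
gap and maximum constraint violation, both audited post hoc at $10^{-6}$ —
and the solver is verified against exhaustive enumeration on random integer
instances and against an independent dense implementation.

### Hidden-cost calibration

Predicted profits will not, in general, rank each county's observed
most-planted crop first — in the generator, 40% of counties are mismatched
by construction. The discrepancy is interpreted as unmodelled local costs:
`calibrate_hidden_costs()` adjusts costs minimally so the observed crop
strictly leads by a configurable margin (default \$1/acre). Two modes are
offered because the direction of the adjustment is genuinely
underdetermined: raising competitor costs (default) or lowering the observed
crop's cost. The post-condition — observed crop is the per-acre-profit
argmax in 100% of counties — is asserted inside the function. After
calibration, re-optimizing at baseline climate with slack crop caps returns
every county to its observed dominant crop; with binding national caps a
small amount of shuffling among secondary crops can persist, which the
acceptance suite bounds at 5% of counties.

### Irrigation at the destination

When a crop moves into a county, its predicted yield is evaluated at the
*destination* county's crop-specific irrigation fraction — one of the six
covariates — so the coefficient prediction already reflects local irrigation
capacity. Because the coefficient model is linear in the standardized
fraction, moving a prediction between fractions shifts each draw's log-yield
by exactly the irrigation-loading path; `apply_irrigation_adjustment()`
exposes that shift as an explicit, testable operation, and the Monte Carlo
pipeline applies it implicitly by always predicting with the destination
county's own fraction.

### Monte Carlo propagation

`monte_carlo_optimize()` re-solves the program independently for each
sampled posterior draw and period, pairing each draw's optimized profit with
the same draw's status-quo profit so the with/without comparison is paired
within draw. Expected yields per draw use the mean function without
observation noise: the optimizer targets expected profit, and resampled
noise would manufacture spurious switching. Summaries are means with
equal-tailed 95% credible intervals across draws; switching rates count
counties whose largest-area crop changes (ties broken toward the baseline
crop, a conservative choice that avoids spurious switches; a fully fallowed
county counts as switched). Corn–soy swaps are identified pairwise — a
county exchanging dominance between corn and soybeans specifically — and
reported both included and excluded, since the two crops rotate routinely
and such swaps overstate disruption. Baseline-to-optimized area flows are
decomposed proportionally within county (shrinking crops feed growing crops
and fallow land in proportion), which is the natural two-margin
decomposition when only net area changes are observable.

## Problem sizes and numerical choices

The shipped test and acceptance runs use study sizes chosen to make the
statistical checks sharp at desk scale: 200 counties × 40 years for
recovery and coverage, 100 × 30 (ten replicates) for the cross-validation
pattern, 25–30 counties × 3 crops for the economics stack, and 15–30
posterior draws through the optimizer. Simplex tolerances are $10^{-9}$
relative in the solver with $10^{-6}$ audits; slice sampling uses widths of
0.3–0.5 on the log scale; county effects with pinned SDs below $10^{-3}$
take the exact degenerate path. Seeds propagate from a single root through
a deterministic stage-seed scheme, so any stage can be reproduced in
isolation and a full experiment is bit-identical under rerun.

## Known limitations

Counties are exchangeable given covariates: no spatial correlation of
effects, no county adjacency. The deficit index is a stand-in for a full
water-balance model. Prices are exogenous; the national crop-total
constraint is the only price-feedback guard. The linear program knows no
rotation agronomy, field sizes or integer constraints. The generator's
future scenarios are stated shifts of standardized predictors with county
heterogeneity — stand-ins for downscaled climate projections, suitable for
exercising the machinery but carrying no information about any actual
future.
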