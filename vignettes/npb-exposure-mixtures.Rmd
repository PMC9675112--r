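---
title: "Non-parametric Bayes shrinkage for neighborhood exposure mixtures: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-parametric Bayes shrinkage for neighborhood exposure mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npbmix)
```

## The problem

Neighborhood-level environmental hazards (air pollution, temperature, traffic,
proximity to industrial sites) and social stressors (crime, poverty,
educational attainment, hospitalization rates) are jointly associated with
neonatal outcomes such as birth weight and adiposity at birth. Assessed at the
census-tract level they are strongly inter-correlated — roughly -0.5 to 0.7
among environmental variables and up to 0.9 among social ones — so
single-exposure regressions confound each exposure's effect with its
co-exposures, while an ordinary multi-pollutant regression with all 21
exposures, their 210 pairwise products, and several hundred
exposure-by-covariate products is hopelessly ill-conditioned.

`npbmix` addresses this with non-parametric Bayes shrinkage (NPB): a linear
model whose selection coefficients carry a Dirichlet-process prior with a
point mass at zero. The point mass performs variable selection (coefficients
are *exactly* zero in most draws), the continuous slab shrinks survivors, and
the DP's clustering assigns one shared coefficient to exposures with similar
effects, which caps the variance inflation that collinearity otherwise causes.

## Model and priors

For dyad $i$:
$$y_i \mid \beta, \zeta, \gamma, \sigma^2 \sim
  N(y_0 + x_i^\top \beta + z_i^\top \zeta + w_i^\top \gamma,\; \sigma^2),$$
where $x_i$ holds the 21 standardized exposures, $z_i$ the pairwise
interactions (every unordered exposure pair once, plus exposure-by-covariate
products), and $w_i$ the adjustment covariates.

Each selection block has its own zero-spiked DP:
$$\beta_j \sim G_1,\quad G_1 \sim \mathrm{DP}(\alpha_1, G_0),\quad
  G_0 = \pi_0\,\delta_0 + (1-\pi_0)\,N(0, \tau^2),$$
and analogously $\zeta_k \sim G_2$ with concentration $\alpha_2$.
Interactions are selected by their own DP, independently of the main
effects: no strong-heredity constraint links an interaction to its parents.
That choice is deliberate — with correlated exposure mixtures an interaction
can be the only detectable signal while both main effects are shrunk away,
and forcing heredity would suppress exactly the findings this model exists
to surface.

Hyperpriors (all surfaced in `npb_config()`; the outcome is internally
centered and scaled, so these defaults are scale-free, and summaries are
back-transformed to native units):

| parameter | prior / default | role |
|---|---|---|
| $\tau$ (`slab_sd`) | 1 (standardized-outcome units) | SD of nonzero atoms |
| $\pi_0$ per block | Beta(1, 1) | base-measure mass at zero |
| $\alpha_1, \alpha_2$ | Gamma(1, 1) | DP concentrations (sensitivity grid 0.5, 1, 2, 4) |
| $\gamma$, intercept | $N(0, 10^2)$ | covariate effects |
| $\sigma^2$ | Inv-Gamma(0.5, 0.5) | error variance |

A slab SD of 1 on the standardized-outcome scale says a selected effect may
plausibly be as large as one outcome SD per exposure SD — weakly informative
for effects measured in tens of grams against a ~500 g outcome SD.

## The Gibbs sampler

Each sweep (C++ core, `src/npb_gibbs.cpp`):

1. **Cluster assignment** per selection coefficient by the conjugate
   (marginalized) Polya urn. The point mass is merged into a single spike
   cluster whose atom is exactly 0; its urn weight is
   $n_0 + \alpha \pi_0$. An occupied slab cluster with atom $\theta_c$ has
   weight $n_c \exp(\theta_c s - \tfrac12 \theta_c^2 v)$ with
   $s = x_j^\top r/\sigma^2$, $v = x_j^\top x_j/\sigma^2$; a new slab
   cluster has weight $\alpha(1-\pi_0)$ times the closed-form marginal of
   the conjugate $N(0, \tau^2)$ base measure.
2. **Atom refresh** for each slab cluster from its Normal full conditional
   (members share the atom bit-for-bit, which is the clustering-coherence
   invariant the tests check).
3. **Covariates and intercept** jointly from their Normal full conditional.
4. **$\sigma^2$** from its inverse-gamma full conditional.
5. **$\alpha_1, \alpha_2$** by the Escobar–West auxiliary-variable step,
   with $k$ = number of occupied clusters (spike included when occupied).
6. **$\pi_0$** per block from a Beta full conditional.

Because spike membership stores an exact floating-point zero, the PIP is the
plain fraction of retained draws with a nonzero coefficient — no epsilon
thresholding, and "cluster membership" and "coefficient nonzero" are the
same event by construction.

**The $\pi_0$ update.** Under the merged-spike urn the exact conditional for
$\pi_0$ given the cluster structure is nonstandard (the spike may absorb
several notional base-measure draws). We update
$\pi_0 \sim \mathrm{Beta}(a_\pi + \#\{\text{coefficients at } 0\},
b_\pi + \#\{\text{nonzero}\})$: coefficient-level counts. In the
cluster-free independent spike-slab limit this is the exact conditional, and
it is precisely that limit the enumeration oracle validates. With hundreds
of candidate interactions it also adapts $\pi_0$ close to 1 under sparsity,
which gives the model a sharp multiplicity correction: at n = 897 the
selection boundary sits near $|t| \approx 6$, so the planted interaction
($|t| \approx 10$) is selected with PIP 1.00 while null terms rarely exceed
PIP 0.01.

**Validation oracle.** `exact_spike_slab_pip()` enumerates all $2^{p+q}$
zero/nonzero patterns of a tiny covariate-free problem and integrates the
nonzero coefficients in closed form against $N(0, \tau^2)$ with $\sigma^2$,
$\pi_0$, $\tau$ fixed. The sampler in `independent_spike_slab` mode with the
same fixed values agrees with the oracle to within 0.02 at 20,000 retained
draws; this dual route (sampler vs enumeration) is the core correctness
argument for the selection machinery.

## The synthetic cohort

The real cohort contains protected health information and is not deposited,
so every downstream stage is exercised on seeded synthetic cohorts
(`simulate_cohort()`) that emulate its statistical structure:

- 21 exposures from a **Gaussian copula with Normal marginals** matched to
  the published tract-level means and SDs, with block correlations drawn
  uniformly from the reported ranges (environmental–environmental
  [-0.5, 0.7], social–social [-0.1, 0.9], cross-block [-0.3, 0.5]) and
  repaired to the nearest positive-definite correlation matrix. Only the
  correlation *ranges* are published, not the full matrix, so the default
  correlation structure is a draw from those ranges, not the true matrix.
- covariate categories (race/ethnicity, education, smoking, second-hand
  smoke, infant sex) at the published frequencies; continuous covariates as
  (truncated) Normals at the published moments; conception dates uniform
  over 2009–2014 with gestation length Normal(275, 13) days truncated to
  [196, 301].
- outcome: `outcome_mean` (default 3208 g) plus sparse planted effects per
  SD of the *latent* standardized exposures, plus Normal residual noise
  (default SD 450 g). Planted interaction products are centered by their
  expectation $\rho$ so `outcome_mean` remains the exact outcome mean. The
  default planted truth — ozone -6.4 g/SD, temperature +13.1 g/SD,
  ozone x temperature -162 g/SD·SD — reuses the published posterior means
  as simulation truth, which makes the recovery tests a like-for-like
  re-detection exercise at the study's own effect sizes.

What the generator does **not** emulate: the real marginals' skewness (the
analysis standardizes everything, so Normal marginals are adequate for the
model's operating characteristics but not for marginal tail behavior),
spatial autocorrelation of exposures across real tracts, and the cohort's
missingness patterns (generated data are complete). Passing tests therefore
demonstrate the *method's* behavior under the assumed correlation structure,
not reproduction of the original cohort's coefficient estimates — those are
unreproducible without the restricted data.

## Exposure assignment (kriging stage)

Daily (or hourly) monitor series are reduced to biweekly values — 24-h means
for PM2.5 and temperature, the mean of daily 8-h maxima for ozone — kriged
to target points, and averaged over each pregnancy weighted by days of
overlap. Decisions the published description leaves open, resolved here:

- **Variogram family**: exponential by default (spherical available) — the
  conventional choice for air-pollution fields and smooth in its parameters.
- **Fitting**: weighted least squares with pair-count weights. The model is
  linear in (nugget, partial sill) given the range, so the fit is profiled:
  constrained linear WLS at each candidate range, a grid-plus-1-D search
  over range, then a Levenberg–Marquardt polish. On noiseless
  model-generated points this recovers parameters to ~1e-8, far inside the
  1e-4 the tests require.
- **Coordinates**: projected planar km with Euclidean distance; at metro
  scale the projection distortion is negligible.
- **Completeness rules**: a day needs >= 18 of 24 valid hours (windows need
  >= 6 of 8) for an 8-h max; a biweek needs >= 1 valid day. Lenient rules
  avoid cascading missingness; failures yield NA sentinels, not errors.
- **Calendar**: consecutive 14-day blocks anchored at 2009-01-01.
- **Degeneracies**: co-located monitors are averaged before the solve so the
  kriging system is nonsingular; kriging variances negative by round-off are
  clamped at zero with a warning; a sparse network whose empirical
  semivariogram occupies < 3 lag bins falls back to a moment-based variogram
  (message emitted) rather than dropping the period.

Ordinary kriging solves the standard Lagrange-constrained system; weights
sum to 1 to 1e-8, predictions at monitor sites are exact when the nugget is
0, and predictions are translation-equivariant — all tested properties.

## Design construction

- Continuous variables are standardized by sample SD (n-1), with
  center/scale records kept so reported effects read as native outcome units
  per 1 SD.
- Categorical covariates are reference-coded (race/ethnicity reference:
  non-Hispanic White; season reference winter; year reference 2009).
- Pre-pregnancy BMI enters as continuous (the published table displays
  categories, but the methods describe BMI itself). Infant sex is included
  by default (configurable). Year and season of conception are indicator
  blocks. Longitude, latitude, and their product adjust for residual
  spatial trend; days to the body-composition measurement is appended for
  the adiposity outcome only.
- Interaction-eligible covariate columns are all of W except the intercept
  and the longitude x latitude product (itself an interaction). Indicator
  columns interact individually — the alternative (composite covariates)
  is not well defined for reference-coded factors. With the default design
  this gives 210 + 21 x 24 = 714 interaction columns.

## Baselines and stratification

Single-exposure models regress the outcome on one standardized exposure plus
the full covariate block, via QR. Wald 95% intervals use the normal 1.96
quantile rather than t quantiles — at n near 900 the difference is under
0.2% of the interval width. The stratified driver splits on maternal
race/ethnicity (non-Hispanic White vs all other), drops the stratifier's
indicators from W, and keeps the geographic terms by default (configurable,
since the published stratified table omits them while the main table keeps
them).

## Numerical and MCMC choices

- Defaults `n_iter = 25000, n_burn = 5000, thin = 4` retain 5000 draws
  (PIP Monte-Carlo error about 0.007). The test suite and acceptance script
  use shorter chains (2000 retained draws at n = 897, which resolves
  credible-interval endpoints to a few grams) and these problem sizes are
  the package's chosen demonstration scale: 20 seeds for recovery, 10 for
  null calibration, the full concentration grid for the sweep.
- A slab atom proposed at exactly 0 (a measure-zero event) would remain a
  distinct slab cluster; spike membership arises only through assignment.
- Credible intervals are equal-tailed empirical quantiles over all retained
  draws, zeros included, so selection-term rows are model-averaged effects —
  intervals may include 0 alongside a nonzero mean, matching how such
  tables are usually presented.
- Effective sample size uses Geyer's initial positive-sequence estimator
  (floored at 1 for degenerate chains); the potential scale reduction factor
  is the classic split-chain form.
- `simulate_cohort()`, `simulate_monitors()`, and `npb_fit()` restore the
  global RNG state after use; identical seeds give bit-identical output.

## Known limitations

- Linear effects only: genuinely non-linear exposure-response shapes (an
  inverted-U in temperature, say) are outside the model class; NPB is best
  read as a first-stage dimension reducer before flexible follow-up models.
- The $\pi_0$ coefficient-level update is exact only in the cluster-free
  limit; under heavy clustering it modestly overweights large blocks'
  sparsity information (documented above).
- The enumeration oracle is limited to 12 selection terms; beyond that the
  sampler is validated by properties (null calibration, recovery, coverage)
  rather than exact comparison.
- Kriging is global (all monitors), ordinary (constant unknown mean), and
  purely spatial; universal/space-time kriging and cross-validated model
  selection are out of scope.
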