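---
title: "Diachronic causal models of environmental effects on geo-phylogenetic traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diachronic causal models of environmental effects on geo-phylogenetic traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geophylocausal)
```

## Why synchronic regressions mislead

Cross-sectional tests of environment-on-culture hypotheses regress one
observation per extant language (or population) on its local environment.
When the observations descend from a common ancestor, neither the trait
values nor the environments are independent: trait similarity is inherited,
and environmental similarity is inherited too, because daughter populations
start where their parents were. A single early lineage that disperses into
a different climatic zone ("founder jump") creates two clusters in which
trait and environment co-vary for purely genealogical reasons.
`type1_error_study()` makes this concrete: under a null model in which the
trait changes at random — each edge adds `Normal(0, 1) * B` to the
ancestral value, where `B` is the branch length in ky — an ordinary least
squares regression of leaf trait on leaf humidity at `alpha = 0.05` comes
out "significant" in the large majority of replicates on a founder-jump
tree, while staying at the nominal 5% on a star phylogeny with iid
humidity. Note the null model's error scale is deliberately *linear* in
`B`, not the `sqrt(B)` of standard Brownian motion — the diagnostic is
defined on that convention, and the generator implements it as stated
rather than silently "correcting" it; `variance_scaling = "sqrt_B"`
switches to standard Brownian increments.

`node_importance()` localises the bias: adding a fixed `delta` to the trait
of every leaf descending from one node and recording the absolute change in
the fitted slope shows that a handful of early, large-clade nodes can
single-handedly set the sign and strength of the synchronic correlation.
Perturbing the root shifts all leaves equally and leaves the slope exactly
unchanged, which doubles as a correctness check; single-leaf perturbations
reproduce the rank-one OLS update formula analytically.

## The diachronic model

Rather than modelling trait levels, we model trait *changes* along the
edges of a time-calibrated, geographically annotated phylogeny. For edge
`i` from ancestor to descendant, with temporal distance `dA_i` in units of
1000 years:

* outcome: `T_desc,i - T_anc,i ~ Normal(mu_i, sigma_i)`
* mean: `mu_i = (alpha + eta * H_i + gamma * Gt_i + rho * Pt_i) * dA_i`
* scale: `sigma_i = sigma0 + beta * dA_i`

The multiplicative `dA` normalises every coefficient to an effect per
millennium, so short edges are not forced to show the same absolute change
as long ones. The residual scale grows (or shrinks — `beta` is
unconstrained, with the joint support `sigma_i > 0` enforced by rejection)
with temporal distance, since unmodelled influences accumulate over time.

The covariates:

* `H_i` is the mean of the humidity at the ancestor and at the descendant
  node, acknowledging that the time of the change within the edge is
  unknown. Node humidity comes from a space-time interpolator
  (`fit_humidity_field()`): a tensor-product spline smooth
  `te(year, lat, lon)` fitted by REML to a gridded climate table, with a
  trilinear interpolator (`bilinear_baseline()`) as the comparison
  baseline. The spline's held-out R-squared is estimated by 5-fold
  cross-validation with a fixed fold seed. Tree and climate grid may use
  different reference years (defaults 2000 CE and 1850 CE).
* `Gt_i` (contact/borrowing control) is the mean trait of lineages alive
  at the descendant node's age whose interpolated position lies within
  500 km of the descendant; trait values and positions of a crossing
  lineage are linearly interpolated along its edge with
  `v_anc + p * (v_desc - v_anc)`.
* `Pt_i` (residual inheritance control: rate variation, drift) is the
  mean trait over all nodes within a small cophenetic radius of the
  descendant, *not* filtered for contemporaneity — the variable stands for
  lineage-level propensities, not momentary contact — excluding the node
  itself and its own ancestor.

Both neighbourhood variables enter with measurement layers
`Gt_i ~ Normal(Gt_MEAN_i, Gt_SD_i)` and `Pt_i ~ Normal(Pt_MEAN_i, Pt_SD_i)`
so the within-neighbourhood spread is not discarded. Interior-node trait
values are themselves reconstructions; each node with a positive
reconstruction standard error contributes one shared latent value
`T ~ Normal(T_REC, T_SE)` across all edges it joins (per-row independent
copies of the same node would be incoherent). Leaves and fossilised nodes
(`T_SE = 0`) are fixed data.

Covariate columns are z-scaled by dividing by their sample standard
deviation *without centring*, so one model unit is one SD of the data;
`dA` is not scaled because its unit (1000 years) is the point of the
parameterisation. The scaling divisors are stored in the pair table so raw
values remain recoverable.

### The GP variant

Model GP replaces `gamma * Gt_i + rho * Pt_i` with latent per-node effects
`g_i + p_i` inside the `dA`-scaled bracket, drawn from zero-mean Gaussian
processes over the pairwise great-circle distances (squared-exponential
kernel `a^2 exp(-d^2 / (2 l^2))`, plus a small diagonal nugget) and the
pairwise cophenetic distances (Ornstein-Uhlenbeck kernel
`a^2 exp(-d / l)`), indexed by the row's descendant node. This models
similarity as a smooth gradient instead of a hard radius, at the price of
losing the contemporaneity filter (kernels need a single positive-definite
matrix over all nodes at once). Amplitudes get half-Normal(0, 1)
hyperpriors; lengthscales get a lognormal prior centred on the median
positive distance so prior mass spans the observed range — the kernel
hyperpriors are a package choice, since no canonical values exist for this
design.

## Ancestral state reconstruction

`asr_brownian()` computes, for every interior node, the exact conditional
mean and standard deviation of the trait under Brownian motion given the
leaf values and an optional fossilised root (e.g. two tones for a
reconstructed proto-language). The implementation is a linear-time
upward/downward belief-propagation sweep; the test suite verifies it to
1e-8 against a brute-force dense-covariance Gaussian conditioning oracle on
trees up to 8 leaves, which is the strongest statement of correctness we
can make. The Brownian rate is profiled out by maximum likelihood. A
large-sample MCMC reconstruction would target the identical distribution,
so the analytic conditional is used throughout: it is deterministic and
exactly testable. Optional bounds (for example 0 to 12 tone contrasts) are
applied by truncating each node's conditional normal; with bounds far from
the mass the truncated and unbounded reconstructions agree to 1e-6.
Optional empirical prior shapes for bounded inventories (a gamma for vowel
counts, a narrow normal for vowel ratios) are available as truncation
settings and default to off for synthetic runs.

`pagels_lambda()` estimates phylogenetic signal by maximum likelihood over
the lambda-scaled covariance (off-diagonals multiplied by `lambda` in
[0, 1]), with root state and rate profiled in closed form; the profile
log-likelihood is returned. At `lambda = 1` it reproduces the plain
Brownian GLS likelihood, at `lambda = 0` the iid-normal one (tested in
closed form), and it agrees with an independent implementation
(phytools) at interior optima.

## The synthetic-data generator

The generators emulate a Bantu-scale study system, and their defaults are
fixed once:

* `simulate_tree()`: pure-birth topology conditioned on `n_tips` (default
  200), rescaled to a crown age of 5 ky. A Yule tree is sufficient
  because downstream stages consume age structure, not topology realism.
* `simulate_dispersal()`: Brownian walk on raw latitude/longitude
  (sd 0.5 degrees per sqrt(ky)) from a root at (-2, 12) — no spherical
  projection correction, adequate at sub-continental extents and a
  documented limitation. An optional founder jump displaces one early edge
  (ancestor age in the top quintile, subtree closest to half the leaves)
  by 15 degrees of latitude, reproducing the two-cluster phenomenon.
* `simulate_humidity()`: a smooth deterministic field (base 0.015 kg/kg,
  north-south gradient 2e-4 per degree, iid noise sd 2e-4) evaluated at
  node locations and ages. Because locations evolve on the tree, simulated
  humidity shows Pagel's lambda above 0.9 under founder configurations —
  matching the empirically very strong signal of climate variables —
  without any literal inheritance.
* `simulate_traits_null()`: the bias-study null (`eps * B`, root value 2).
* `simulate_traits_causal()`: the generative counterpart of model LIN.
  Edges are processed root-to-tip in ancestor-age order so the Gt/Pt terms
  can be computed from already-simulated contemporaries (an empty
  neighbourhood contributes zero); the humidity covariate is z-scaled
  exactly as the inference table scales it, so generative and inferred
  coefficients share a scale. Defaults: `alpha = 0, eta = 0.5,
  gamma = 0, rho = 0, sigma0 = 0.5, beta = 0.05` — the generator's purpose
  is validating recovery of the *direct environmental path*, so the
  neighbourhood channels default off and can be switched on explicitly.
  Configurations with `sigma0 + beta * dA <= 0` on any edge are rejected.

Every generator is a pure function of its configuration and seed. What the
generators do **not** emulate: borrowing from languages outside the tree,
discrete tonogenesis mechanics, non-smooth climate fields, and tree
topologies shaped by diversification dynamics. Passing tests on synthetic
data therefore demonstrate internal statistical correctness of the
machinery, not the realism of any particular empirical analysis.

## Sampling and diagnostics

No probabilistic-programming backend is required: the LIN posterior is
sampled by a blocked Gibbs scheme in which the regression coefficients are
drawn exactly from their conjugate multivariate-normal conditional, the
per-row Gt/Pt latents and latent node values from their conjugate normal
conditionals, and only `(log sigma0, beta)` by a small adaptive Metropolis
step (three substeps per sweep; proposal scale tuned to ~23% acceptance
during warmup and then frozen). The uncentred covariate scaling puts
`alpha` and the slopes on a strong ridge, which the exact coefficient draw
handles without mixing loss. The GP posterior (4-8 hyperparameters after
analytic marginalisation of the latent effects into a multivariate-normal
likelihood) is sampled by adaptive Metropolis with a warmup-adapted full
covariance proposal.

Convergence is reported, never assumed: split-chain scale reduction and
effective sample size per parameter, with `converged = FALSE` whenever any
split-Rhat reaches 1.01. Default settings are 4 chains of 1000 post-warmup
draws each. `prior_only = TRUE` switches the likelihood off for
prior-predictive checks; note the reported prior for `(sigma0, beta)` is
the prior truncated to the positivity support, which is part of the model.

Pointwise log-likelihoods are retained for every fit: for LIN the per-row
density with the Gt/Pt latents marginalised analytically (rows are
conditionally independent given the remaining parameters, so this is the
correct leave-one-out predictive); for GP the exact per-row conditional
`p(y_i | y_-i, theta)` from the precision matrix. PSIS-LOO
(Pareto-smoothed importance sampling, with the Zhang-Stephens generalized
Pareto tail fit) is implemented in `loo_elpd()` and validated against exact
leave-one-out refits on a 30-row table; `elpd_compare()` reports pairwise
ELPD differences with standard errors from the pointwise difference
vector.

Evidence about the humidity coefficient is summarised by the Savage-Dickey
density ratio `BF10 = prior(0) / posterior(0)`, the posterior density
estimated by a Gaussian KDE with Silverman bandwidth. The estimator is
accurate when the posterior has genuine mass at the null (validated within
a few percent of the closed-form normal-family ratio) and is reported as a
floored lower bound when it does not — a sample-based KDE cannot resolve
densities tens of standard deviations into a tail, and pretending
otherwise would be worse than flagging it.

## Numerical choices and edge cases

* Zero-length edges are retained in the tree but dropped (and logged) from
  the pair table, since `dA = 0` would zero the mean model; the null and
  causal generators copy the ancestor value across them.
* Empty neighbourhoods pin the row's latent to zero on the scaled scale
  and set a flag, so the corresponding coefficient contributes nothing for
  that row.
* The cophenetic radius is interpreted in native branch-length units by
  default, with a "fraction of root age" mode, because the radius that
  corresponds to "a small clade" depends on the tree's depth scale. The
  synthetic studies use 0.5 ky (a tenth of the default crown age).
* The geographic reference point for `Gt` is the descendant node (time and
  location), with an edge-midpoint option.
* Likelihood positivity (`sigma_i > 0`) is enforced by returning `-Inf`,
  i.e. soft rejection, keeping `beta` unconstrained as specified while the
  joint density stays proper.
* CTMC transition matrices in the correlated-evolution test come from one
  eigendecomposition of the generator per likelihood call (with a
  matrix-exponential fallback near-defective generators); row sums are
  unit to 1e-10 and the pruning likelihood matches exhaustive
  interior-state summation to 1e-10 on small trees. The 8-rate dependent
  model is additionally started from the independent optimum, which also
  guarantees the nesting inequality numerically.

## Design decisions that were genuinely open

* **Recovery is assessed under a structurally matched model.** The
  generator's neighbourhood channels are off by default, so coverage of
  the humidity coefficient is evaluated with the LIN core without the
  `Gt`/`Pt` terms. Fitting the full confound set to the same data leaves
  the estimates unbiased but widens the frequentist spread along the
  eta-gamma ridge — the neighbourhood covariates are computed from traits
  that already embed the humidity effect, so the two directions are partly
  confounded. That collinearity is a real feature of the design (and of
  the empirical analyses it supports), not a defect of the sampler, and
  users should expect attenuated, wider humidity posteriors whenever the
  confounds are on and correlated with the environment. The same applies
  more strongly to the GP variant when the environmental field is purely
  spatial: a geographic kernel can absorb a spatial covariate's effect.
* **One shared latent per interior node** across all rows it joins, rather
  than per-row copies.
* **Stationary root distribution** for the CTMC tests by default, with
  fossil overrides; stepping-stone marginal likelihoods use uniform rate
  priors with a configurable upper bound, since the historical settings of
  the reference implementation are not printed anywhere.
* **Problem sizes.** The shipped studies use 150-200 tip trees, 20
  replicate fits for coverage/calibration, 100-400 replicates for the
  regression bias rates, and exact-LOO validation on a 30-row table —
  sizes at which every Monte-Carlo assertion is stable under its fixed
  seed while the whole suite stays convenient to run routinely.

## Known limitations

* Dispersal on raw coordinates ignores meridian convergence; fine at the
  scales simulated, wrong near the poles.
* The ancestral reconstruction assumes Brownian change; the causal
  generator's humidity drift violates that assumption, and
  reconstruction-based fits inherit whatever bias the reconstruction has
  (an attenuation the empirical literature acknowledges: the
  reconstruction does not see humidity, so it favours the inheritance
  component).
* The discrete correlated-evolution test's Bayes factor depends on
  unprinted prior choices in historical analyses; stepping-stone estimates
  here are calibrated against each other, not against any published
  number.
* Metropolis-based GP fits need longer chains than the Gibbs-based LIN
  fits for the same effective sample size; check the reported diagnostics
  before interpreting hyperparameters.
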