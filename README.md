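# geophylocausal

Diachronic causal models for testing environmental effects on traits that
evolve along a geo-referenced phylogeny.

## The problem

Claims that the physical environment shapes cultural or linguistic traits —
the best known being that ambient humidity favours the emergence of lexical
tone — are usually tested on *synchronic* data: one measurement per extant
language, regressed on the local climate. Such tests are badly
anti-conservative. Related languages inherit both their traits and
(through population dispersal) their environments, so a single early
lineage that wanders into a wetter or drier region creates clusters in
which traits and climate co-vary by accident. A cross-sectional regression
then "detects" an effect that a null model of purely random trait change
reproduces most of the time.

`geophylocausal` implements the diachronic alternative: put the analysis on
the branches of a time-calibrated phylogeny whose every node carries an
estimated age and location, and model the *change* in the trait between an
ancestor and its descendant as a function of the humidity the lineage
experienced, while controlling for what geographically proximate lineages
(contact/borrowing) and phylogenetically close lineages (rate, drift) were
doing.

## The model

For each ancestor→descendant edge *i* with temporal distance *dA* (in
thousands of years):

```
T_desc,i − T_anc,i ~ Normal(μ_i, σ_i)
μ_i = (α + η·H_i + γ·Gt_i + ρ·Pt_i) · dA_i
σ_i = σ0 + β·dA_i
```

* `H_i` — mean humidity at the ancestor and descendant locations/ages,
  obtained from a tensor-product spline interpolation of a gridded
  space–time climate field;
* `Gt_i` — mean trait value of lineages contemporaneous with the node and
  within 500 km, linearly interpolated along their edges (with a
  measurement layer `Gt_i ~ Normal(Gt_MEAN, Gt_SD)`);
* `Pt_i` — mean trait value of nodes within a small cophenetic radius
  (measurement layer likewise);
* interior-node trait values enter as latent variables anchored to a
  Brownian-motion ancestral state reconstruction
  (`T ~ Normal(T_REC, T_SE)`, with a fossilised root where a historical
  reconstruction exists);
* multiplying the predictor by `dA` normalises effects to "per 1000
  years", and `β` lets the residual scale grow with temporal distance.

A second variant (model GP) replaces `γ·Gt + ρ·Pt` with latent per-node
effects drawn from Gaussian processes — a squared-exponential kernel over
great-circle distance and an Ornstein–Uhlenbeck kernel over cophenetic
distance. Evidence for the environmental effect is summarised by the
Savage–Dickey density ratio for `η`, and model variants are compared by
PSIS-LOO expected log predictive density.

The package also provides the surrounding toolkit: geo-phylogeny I/O and
distance matrices, synthetic data generators (Yule trees, Brownian
dispersal with an optional founder jump, smooth humidity fields, null and
environment-driven trait histories), the type-I-error inflation diagnostic,
node-importance perturbation analysis, Pagel's λ, and the
correlated-evolution tests (Pagel's discrete CTMC test, bivariate Brownian
correlation) used as phylogeny-only baselines.

## Worked example

```r
library(geophylocausal)

# a 200-tip synthetic system with a founder jump and NO humidity effect
cfg  <- sim_config(n_tips = 200, founder_jump = founder_jump(), seed = 11)
tree <- simulate_geophylo(cfg)

# 1. naive synchronic regression: grossly inflated false positives
type1_error_study(tree, n_datasets = 100, alpha = 0.05, seed = 42,
                  config = cfg)
#> Null-model leaf regression study: 100 replicates
#>   significant at alpha = 0.05 : 80 ( 80 % )
#>   95% binomial CI for the rate: [ 0.708 , 0.873 ]

# 2. the diachronic causal model on data WITH a real effect (eta = 0.5)
cfg2 <- sim_config(n_tips = 160, founder_jump = founder_jump(),
                   trait = list(model = "causal"), seed = 21)
g    <- simulate_geophylo(cfg2)
pair <- build_node_pair_table(g, phylo_radius = 0.5)
fit  <- fit_dcm(pair, variant = "lin", chains = 4, iter = 1000,
                warmup = 1000, seed = 1)
summary(fit)[2, c("mean", "lower", "upper")]
#>        mean     lower     upper
#> 2 0.5087681 0.4102417 0.6076886
```

Eighty of one hundred null datasets look "significant" to the synchronic
regression, while the diachronic model pins the true per-millennium
humidity coefficient (0.5) inside a tight credible interval — and, on null
data, its Savage–Dickey Bayes factor correctly supports no effect.

Real datasets enter through `run_archived_study()`, which reads a local
directory containing a Newick tree, a node table (id, parent, age, lat,
lon, traits) and a gridded humidity table; nothing is ever downloaded.

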