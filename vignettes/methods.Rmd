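---
title: "Methods: habitat regimes and climatic niche evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habitat regimes and climatic niche evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ouniche` implements an inference pipeline that links where species occur
(habitat, canopy cover, nesting position) to how their climatic niches
evolve. It was designed around the kind of analysis done for large ant
phylogenies: clean a table of georeferenced occurrence records; summarize
each species' climate and biome occupancy; code a three-state canopy
character; reconstruct its history under a constrained Markov model; and
ask, with multi-regime Ornstein-Uhlenbeck (OU) models, whether climatic
optima and evolutionary rates differ between nesting regimes. Every stage
can be exercised end to end on synthetic data with known truth, which is
how the test suite validates it.

## Occurrence cleaning

Records carry a species label, coordinates, a reported country, biome and
realm labels, and 36 environmental variables (19 bioclim, net primary
productivity, potential evapotranspiration, elevation, and 14 topsoil
variables). Cleaning proceeds in four steps.

**Coordinate validation and repair.** Mis-entered coordinates are
commonly swapped or sign-flipped. `validate_records()` tries eight
variants of each record in a fixed order — as given, latitude flip,
longitude flip, both flips, then the same four after interchanging
latitude and longitude — and accepts the first variant that is on land
and within a tolerance (default 1 degree, configurable; country-match
buffers are not standardized across cleaning tools) of the reported
country.
The deterministic order makes results reproducible; records failing all
eight variants are rejected with a reason code (`off-land`,
`wrong-country`, `unknown-country`).

**Deduplication and completeness.** Exactly one record is kept per
distinct (species, latitude, longitude) triple — first occurrence wins —
and records missing any required environmental variable are dropped with
a logged count.

**Per-species summaries.** Medians are taken per variable over each
species' surviving records. Temperature-family bioclim variables are
stored in tenths of a degree in raw layers and are divided by 10 so the
summaries read in degrees Celsius; the family is taken to be BIO1-BIO11
except BIO3 (a dimensionless index) and BIO4 (a standard deviation x 100
on its native scale), and the set is overridable since published
pipelines rarely enumerate it. Division before versus after the median is
mathematically equivalent; it is applied before reporting. The median of
an even record count is the midpoint of the central pair. Species with a
single record are retained — real datasets contain many such species —
and biome/realm occupancy proportions are tabulated over unique records.

## Canopy coding

Biomes are mapped to canopy classes by an editable scheme: forest-type
biomes (including mangroves and, under the primary scheme, Mediterranean
forests, woodlands & scrub) are *closed*; grasslands, savannas,
shrublands, tundra and deserts are *open*. The `mediterranean_open`
scheme differs only in the Mediterranean biome, supporting the robustness
analysis in which those mixed-canopy communities count as open habitat.

Two binary flags are set with a strict threshold: a species occupies
closed (respectively open) canopy habitat if **more than** one third of
its unique records fall in closed (open) biomes. A share of exactly 1/3
does not set the flag. The composite character is `closed` (1,0), `both`
(1,1) or `open` (0,1); (0,0) is impossible when the two classes partition
the biomes, and is treated as an error.

## Constrained Mk model and marginal reconstruction

The canopy character evolves under a three-state continuous-time Markov
model with all-rates-different parameterization and two structural
zeros: direct transitions between the specialist states `closed` and
`open` are prohibited, so change must pass through the generalist `both`
state. That leaves four free rates.

The likelihood is computed by Felsenstein's pruning algorithm with
per-node renormalization of partial likelihoods (log-scale accumulation),
so large trees do not underflow. Transition kernels use the
scaling-and-squaring matrix exponential provided by `ape::matexpo`; an
eigendecomposition shortcut was rejected because near-defective
generators arise at extreme rate ratios. Root state weights use the
FitzJohn-Maddison-Otto ("maddfitz") weighting — weights proportional to
the root conditional likelihoods themselves — with flat and fixed-vector
alternatives.

Rates are optimized on the log scale within [1e-9, 100] events/Ma by
bounded quasi-Newton (`L-BFGS-B`) with 10 seeded restarts drawn
log-uniformly; these optimizer settings are this package's own choices,
sized so that the parameter-recovery tests converge reliably.

Marginal ancestral probabilities combine the rootward (pruning) pass with
a tipward pass that carries the likelihood of the rest of the tree; the
product, renormalized per node, is the exact marginal given the root
weighting. Both passes are validated against brute-force enumeration over
all internal-state assignments on trees of up to six tips (tolerance
1e-8), with kernels computed by an independent matrix-exponential
implementation.

Tips scored `both` are treated by default as observations of the real
intermediate state — the transition constraint is only meaningful if
`both` is a state — but an alternative mode treats them as ambiguity over
{closed, open}, since published descriptions of such characters sometimes
read that way. Ambiguity sets are written `"closed&open"`; `"?"` means
fully missing.

## The BM/OU model family

Per-species climatic medians evolve on a time-scaled tree whose branches
are painted with one of k regimes (here k = 2: ground versus arboreal
nesting). Branch regime defaults to the rootward node's state, with a
tipward option for terminal branches. Seven models are fitted:

| model | optima theta | pull alpha | rate sigma^2 | free parameters (k = 2) |
|-------|--------------|------------|--------------|--------------------------|
| BM1   | —            | 0          | shared       | 2  (sigma^2, root mean)  |
| BMS   | —            | 0          | per regime   | 3  (sigma^2_k, root mean)|
| OU1   | shared       | shared     | shared       | 4  (+ theta0)            |
| OUM   | per regime   | shared     | shared       | 5                        |
| OUMV  | per regime   | shared     | per regime   | 6                        |
| OUMA  | per regime   | per regime | shared       | 6                        |
| OUMVA | per regime   | per regime | per regime   | 7                        |

The counts include every independently estimated quantity, including the
ancestral value `theta0`, which is estimated in all models except BMS
(whose mean structure is a single ancestral value).

**Likelihood.** The tip distribution is Gaussian with moments obtained by
exact per-branch integration: along a segment of length t in regime j the
expectation decays toward theta_j with factor `exp(-alpha_j t)` and the
variance propagates as
`v' = v e^(-2 alpha t) + sigma^2 (1 - e^(-2 alpha t)) / (2 alpha)`;
the covariance of two tips is the variance at their most recent common
ancestor times the decay along both descending paths. Segments with
`alpha * t < 1e-8` switch to the Brownian limits (`v' = v + sigma^2 t`),
which avoids 0/0 without a user-facing mode switch. The log-density is
evaluated through a Cholesky factorization (no explicit inverse), with a
relative jitter of 1e-10 times the mean diagonal; failure to factorize
after jitter is a hard error reporting the offending eigenvalue. The same
recursions power the forward simulator (`simulate_ou`), which uses the
exact one-step transition per branch rather than Euler steps, so
simulator and likelihood are mutually consistent and closed-form test
oracles apply.

**Optimization.** Only `alpha` and `sigma^2` are searched (log scale,
bounds [1e-6, 50] 1/Ma and [1e-8, 1e6]); the linear parameters (theta0
and the optima) are profiled out at every evaluation by generalized least
squares against the design matrix [root decay, per-regime optimum
weights]. This reduces OUMVA to a four-dimensional search and improves
stability. Restarts jitter the heuristic start (variance over tree depth
for sigma^2, `ln 2 / (depth/3)` for alpha) by uniform log-offsets.

**Diagnostics.** After fitting, the Hessian of the negative
log-likelihood over the full free-parameter vector is computed by central
finite differences, with step sizes floored at 0.01 (and capped at half
the value for the positive parameters) so that weakly curved directions
are probed above the numerical noise of the likelihood. A fit passes only
if (a) no search parameter sits at a box bound, and (b) the smallest
eigenvalue is not resolvably negative, operationalized as
`min(eig) > -1e-8 * max(|eig|)`. The relative tolerance matters: on tall
trees with strong pull, `theta0` is nearly unidentifiable and its
curvature is many orders of magnitude below the largest eigenvalue —
below what double-precision eigensolvers can distinguish from zero — so a
literal strictly-positive test would reject healthy fits on numerical
noise. Saddle points and boundary-stuck `alpha` still fail decisively.
Diagnostic failures are excluded from AICc weights (their rows remain,
flagged), mirroring the practice of dropping ill-behaved fits from model
comparison.

**Model comparison and derived quantities.** Models are ranked by
`AICc = -2 lnL + 2p + 2p(p+1)/(n-p-1)` with Akaike weights
`w proportional to exp(-delta/2)`. Per regime the phylogenetic half-life
`ln(2)/alpha` (time to move halfway to the optimum) and the stationary
variance `sigma^2 / (2 alpha)` (equilibrium spread around it) are
reported, infinite under Brownian motion.

## Parametric bootstrap

`parametric_bootstrap()` simulates 50 datasets (the conventional setting;
configurable) under the fitted model at its ML parameters, refits the
same model to each (warm-started at the generating values, with a looser
optimizer tolerance appropriate for refits), and reports 95% percentile
intervals — plain order-statistic percentiles; bias-corrected variants
were rejected as unstable at 50 replicates — for every parameter
including the derived half-life and stationary variance. Replicates
failing the curvature diagnostic are dropped with a recorded count; more
than 50% failures aborts. Regime differences are called significant when
the two 95% intervals are disjoint (closed intervals: a shared endpoint
overlaps); published analyses of this kind report significance without
stating a criterion, so this operationalization is documented rather than
asserted as the original's.

## Synthetic data and what passing tests mean

The generators provide known-truth inputs for every stage:

* `simulate_tree()` — crown-conditioned forward birth-death simulation,
  stopped when the extant count first reaches n and extended by one
  exponential waiting time; extinct lineages are pruned; full extinction
  is retried up to 1,000 times before an explicit failure.
* `simulate_discrete()` — exact event-path (Gillespie) simulation of the
  Mk process; end states follow `expm(Q t)` and the event log makes
  structural zeros auditable.
* `simulate_ou()` — the exact piecewise-OU transition described above.
* `generate_occurrences()` — records drawn around species range centres
  in a toy world of six rectangular countries carrying realm labels,
  latitudinal biome bands covering all 14 biome types, and smooth
  deterministic climate fields (temperature variables in tenths of
  degrees, like raw layers). Corruption is applied at configurable rates:
  lat/lon swap, latitude sign flip, displacement into the ocean, and
  missing environmental values; the uncorrupted truth rides along as a
  sidecar.

The world's geometry is chosen so that the land latitude band, the land
longitude band, and their negations are pairwise disjoint (land spans
longitudes -150 to -61, latitudes 5 to 45). Consequently any swap or
sign flip of a land point leaves land, every corruption is detectable,
and the first repairing variant in the fixed order is provably the true
one — swap-only corruption is recovered at rate 1.0, which the tests
assert. This is deliberately *not* geographic realism: there are no
raster formats, no coastline complexity, no spatial autocorrelation in
sampling, and climate fields are smooth functions of coordinates. Passing
tests therefore demonstrate the correctness of the cleaning logic and
estimators under the stated model, not robustness to the messiness of
real gazetteers or rasters.

## Problem sizes and numerical conditions used by the test suite

Oracle equivalences (pruning and marginals versus enumeration) run on 100
random instances of up to 6 tips; OU moments are checked against 50,000
forward simulations on 10 random two-regime instances of up to 8 tips for
all seven models. With roughly 3,000 elementwise Monte-Carlo comparisons,
an every-element-within-3-SE gate would fail by chance (the two-sided
3-SE tail is ~0.27%), so agreement is asserted as: at least 99% of
elements within 3 SE and every element within 4.5 SE — calibrated to pass
for a correct implementation and to fail decisively for a wrong formula
(a missing factor of 2 sits tens of SEs out).

The parameter-recovery study uses 20 replicate datasets on 400-tip trees
with a two-state nesting character (transition rate 0.02/Ma, paintings
with both regimes at 15% of tips or more), generating model OUMVA with
theta = (20, 23), alpha = (1.2, 2.0)/Ma and sigma^2 = (0.5, 0.25) — optima
separated by more than 3 stationary standard deviations, half-lives well
inside the ~6 Ma tree depth so the optima are identifiable. Each
replicate is bootstrapped with 50 simulations. These sizes were chosen as
the smallest at which the estimator's statistical claims (median optimum
error under 10%, generating model within AICc rank 2, bootstrap coverage)
are meaningful desk-scale statements.

All stochastic stages take explicit integer seeds; derived stage seeds
are computed from the master seed and stay within 32-bit range. The
pipeline manifest contains no timestamps, so a configuration plus a seed
reproduces every output byte for byte.

## Known limitations

* The dense-covariance likelihood is O(n^3) per evaluation. It is
  comfortable at a few thousand tips (the scale of real ant trees) but a
  pruning-style contrasts algorithm would be needed far beyond that.
* `theta0` is weakly identified whenever `alpha x depth` is large: its
  information decays like `exp(-2 alpha T)`. The profiled estimate can
  then wander to extreme values along a near-flat ridge — occasionally
  such ridge fits genuinely improve the likelihood while failing the
  curvature diagnostic, which is precisely the situation the diagnostic
  exists to catch; downstream reporting uses the best diagnostics-passing
  model.
* No measurement-error term on the species medians, and no within-branch
  regime shifts (paintings are constant per branch; stochastic-map
  paintings are out of scope).
* The Mk machinery covers plain multistate characters with structural
  zeros; hidden-rate (HMM) extensions are out of scope.
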