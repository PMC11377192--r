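---
title: "Methods: diversification, disparity, biogeography, and path analysis on time trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversification, disparity, biogeography, and path analysis on time trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(macroevopaths)
```

This vignette is the package's account of its models, defaults, and
numerical choices. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## Conventions

All trees are rooted, ultrametric, time-calibrated phylogenies with branch
lengths in Myr; node ages are measured backwards from the present in Ma,
so a paleo-curve indexed by age and a tree share one axis. Ultrametricity
is enforced at a relative tolerance of `1e-6` of the crown age: the
reading functions accept slightly ragged trees, but every likelihood
rejects trees outside the tolerance rather than silently coercing them.
Polytomies are tolerated by the tree utilities; the birth-death and DEC
likelihoods require fully bifurcating trees. Tip labels are matched by
exact string equality after whitespace trimming; a mismatch is an error,
never a silent drop.

## The synthetic-data generators

The generators are first-class, tested code; their defaults encode the
study system the pipeline targets: a clade of roughly 139 sampled species
(global sampling fraction f = 0.46) with a ~30 Ma crown age, one clade
with a ~3-fold elevated diversification rate arising in the mid-Miocene
(shift age ~12 Ma), clade-structured multivariate trait rates, a binary
mountain/lowland background, DEC-style ranges over a handful of areas,
and smooth paleotemperature-like and uplift-like curves.

* **Birth-death trees** are simulated forward from two crown lineages by
  thinning against a constant rate bound, run to a fixed crown age;
  extinct lineages are pruned, each extant tip is kept independently with
  probability f, and the whole simulation is rejected until at least one
  sampled survivor remains on *each* side of the crown. This matches the
  crown-age + both-lineages-survive conditioning of the likelihood. The
  tip-count variance of this process is large — helpers that need a
  specific size scan seeds deterministically rather than tuning rates.
* **The rate shift** is two-phase: base rates to the shift age, then one
  lineage alive at that moment (chosen uniformly) continues with
  multiplied rates. The shifted clade's sampled tips are recorded as
  truth. The focal lineage can die or go unsampled; downstream consumers
  check the clade is non-trivial.
* **Traits**: BM increments per branch with per-clade rate multipliers
  (painted on the MRCA subtree, stem excluded); OU by exact per-branch
  transition sampling, with `alpha = 0` reproducing BM draw-for-draw
  under the same seed. Binary characters use the exact 2-state transition
  probabilities; the root is drawn from the stationary distribution
  unless fixed.
* **DEC ranges** are simulated with the same cladogenetic event set and
  weights as the likelihood; a lineage whose range hits the empty (null)
  state is re-drawn from its branch start, conditioning each lineage on
  being observed (see the DEC caveat below).
* **Path datasets** build the five variables in topological order as
  `sum(coef * standardized parent) + noise`, where the noise is
  multivariate normal with covariance `sigma^2 [lambda V* + (1 - lambda) I]`
  (V* the unit-diagonal BM covariance), i.e. residuals carry Pagel's-lambda
  signal (default lambda 0.5, sigma 1). BG is a latent phylogenetic
  variable thresholded at its median, which guarantees both classes. With
  residual sd 0.6 for the downstream variables of a 0.8-coefficient chain,
  each variable has roughly unit variance, so recovered standardized
  coefficients sit on the generating scale.

What the generators deliberately do not emulate: fossil tips, protracted
or trait-dependent (SSE) speciation, diversity dependence, occurrence- or
measurement-level noise, and correlated trait axes. Passing tests
therefore show that the estimators are faithful to their own model
families at realistic sizes — not that those families describe any
particular empirical system.

## Tip rates

`dr_statistic()` computes the inverse equal-splits measure:
`ES_i = sum_j l_j 2^{-(j-1)}` over the root-to-tip edges (terminal edge
first), `DR_i = 1/ES_i`. `ridge_rates()` regresses tip values on the
tips-by-branches incidence matrix of branch lengths, after subtracting
the GLS (BM) root estimate, with an L2 penalty; the per-axis coefficient
of a branch is its evolutionary rate, and a tip's scalar rate is the norm
of its terminal-branch coefficients across axes. The scalar-per-space
reduction is needed because the path analysis consumes one variable per
trait space; per-axis rates remain available from `branch_rates`. The
`"auto"` penalty minimizes generalized cross-validation over a 19-point
log grid spanning `1e-6..1e3` times `tr(L'L)/n_branches`; GCV was chosen
because it is deterministic, needs no replication, and its value is
recorded in the output. The clade rate-shift test compares the mean
absolute tip rate in the focal clade to equal-sized random tip subsets,
with an add-one two-tailed p-value, so `p >= 1/(reps + 1)` always.

## Environment-dependent birth-death models

Rates are `lambda(a) = lambda0 exp(alpha D(a))` and
`mu(a) = mu0 exp(beta D(a))` with `D` either the age itself (time
dependence, so `alpha > 0` means higher rates deeper in time — the sign
convention is stated here because published tables are often ambiguous)
or a smoothed paleo-curve. Curves come from `smooth_curve()`, a penalized
cubic smoothing spline with requested effective degrees of freedom
(default 80, capped at the number of points, where it interpolates),
tabulated once on a dense grid and constant-extrapolated outside its
support.

The reconstructed-tree likelihood solves, in age `a`,
`dE/da = mu - (lambda + mu) E + lambda E^2` with `E(0) = 1 - f`, and
accumulates each branch's flow through the cumulative integrals of
`lambda + mu` and `lambda E`; internal nodes contribute `log lambda`, tips
`log f`, and the total is conditioned on the crown age and the survival
of both crown lineages (division by `lambda(a_root) (1 - E(a_root))^2`).
Whether the original analyses conditioned on stem or crown is not
recoverable; crown conditioning is fixed here and recorded. The solver is
adaptive lsoda (rtol 1e-8 / atol 1e-10 by default) with FMM cubic-spline
interpolants on a 401-point grid; the constant-rate closed form is
reproduced to ~1e-8, and to ~1e-11 at the tightened settings the oracle
tests use. Fitting is multi-start (informed start from the nested simpler
model plus jittered replicates), Nelder-Mead (Brent in one dimension) with
a BFGS polish, on log-transformed rates.

The 14-model battery is: pure birth; constant birth-death; and for each
driver in {time, temperature, elevation} the four forms lambda(D)/mu = 0,
lambda(D)/mu constant, lambda constant/mu(D), lambda(D)/mu(D). Free
parameter counts are 1, 2, 2, 3, 3, 4 respectively.
`AICc = -2 logL + 2k + 2k(k+1)/(n-k-1)` with n the tip count; Akaike
weights normalize `exp(-dAICc/2)`. Equal support across 14 models gives
weight 1/14 = 0.071.

## Disparity

Gower distances implement the typed per-trait rules (continuous and
ordinal: range-normalized absolute difference; binary and nominal: 0/1
mismatch; missing values excluded pairwise, a fully incomparable pair is
an error). PCA is `prcomp` on centered, scaled data; PCoA is classical
scaling with the Cailliez correction applied when negative eigenvalues
exceed tolerance. Disparity is the mean squared pairwise Euclidean
distance — algebraically twice the summed per-axis sample variance
(denominator n - 1), which the suite asserts. Rarefaction draws
equal-sized subsets (default 4 species, 100 times) per clade and compares
distributions by the Bhattacharyya coefficient on a shared Sturges
binning of the pooled pair (deterministic and scale-free); the
conventional "distinct if BC < 0.05" flag is configurable.

DTT evaluates, at each internal-node age (or user bins; the classic five
6-Myr bins can be supplied), the mean over crossing lineages of relative
subclade disparity; the root is 1 by construction and the curve is
invariant to uniform rescaling of the scores. The BM null estimates
per-axis rates by the contrasts estimator and simulates axes
independently (ordination axes are orthogonal). MDI is the signed
trapezoid area between the observed curve and the pointwise null
*median* (the median/mean choice is not documented in common usage; the
median is the default and configurable in spirit via the stored null
curves), over relative time. The reported p-value is the add-one
two-sided rank of the observed MDI among the null MDIs.

## OU regime models

`fit_ou()` implements the Hansen model on one trait axis: the expected
tip value mixes the regime optima with exponentially decaying weights
along each root-to-tip path; the root sits at the root regime's optimum
(the standard stationarity-flavored default — an estimated root is a
possible extension, not currently exposed); the covariance is the
non-stationary OU covariance for ultrametric trees. Optima are profiled
by GLS, sigma^2 analytically, and alpha is optimized on the log10 scale
over [1e-4, 100]/Myr with the `alpha = 0` BM limit handled analytically
and compared explicitly. Each axis is fitted separately. `compare_ou()`
ranks by `BIC = -2 logL + (2 + m) ln n` or by
`pBIC = BIC + 2 ln C(edges, m-1)`, a deterministic multiplicity
correction for the number of possible shift placements — the lasso-based
original's exact penalty is not reproduced, so outputs should be read as
"pBIC(config-count)". Exploratory (data-driven) shift searches are out of
scope; only user-supplied paintings are fitted, and a "convergence"
hypothesis is expressed by painting two distant clades with the same
regime id.

## DEC biogeography

States are the nonempty subsets of the areas up to a maximum range size
(default 5) plus an absorbing null range that is excluded from
cladogenesis, tips, and the root. Anagenetic rates: dispersal into a new
area sums `d m_s(b, a)^w` over occupied source areas `b` (per-stratum
multiplier matrices, conventionally in [0.00001, 1], exponent w in
[0, 3]); extirpation `e` per occupied area. Cladogenesis enumerates
narrow sympatry, subset sympatry (both orders), vicariance (both orders,
deduplicated for two-area ranges), and, with `j > 0`, founder-event jumps
weighted by `j` before per-state normalization — classic DEC weights with
a BioGeoBEARS-style +J extension. Branch transitions are dense matrix
exponentials multiplied segment-wise across stratum boundaries (the state
space stays at desk scale, <= ~400 states, so no sparse machinery).
The root is weighted uniformly over allowed states. The four-stratum
scheme 34-20, 20-15, 15-5, 5-0 Ma is expressed by
`strata_ma = c(34, 20, 15, 5, 0)`; concrete multiplier matrices are user
input, and an adjacency constraint can be expressed through the
multiplier matrices themselves (near-zero entries).

A caveat established by the test suite: on reconstructed trees the
extirpation rate `e` is effectively unidentifiable — ML drives it toward
zero whatever the generating value, because extirpation histories end in
the unobservable null range. The dispersal rate `d` is recovered within a
factor of 2 at the sizes tested; `e` estimates should be treated as lower
bounds, a known property of this model family rather than an
implementation artifact (the likelihood itself is verified against
exhaustive enumeration).

## Phylogenetic path analysis

Causal models are DAGs over {BG, climR, vegR, florR, SR}. The Shipley
basis takes one claim per non-adjacent pair; the response is the later
member in topological order (lexicographic tie-break), conditioned on the
union of both members' parents. The suite checks every basis claim
against brute-force d-separation over exhaustive small DAG families.
Claims with a continuous response use `pgls_lambda()` — GLS with
covariance `sigma^2 [lambda V* + (1 - lambda) I]`, lambda profiled by ML
on [0, 1] with explicit endpoint checks, t-based p-values on n - p df.
Claims with the binary response use `phylo_logistic()` — Firth-penalized
logistic regression (finite under complete separation) with an optional
single phylogenetic variance component on V*, chosen by Laplace
approximation over a small grid including 0 (at 0 it is plain Firth
logistic regression; in the default model set BG is exogenous, so the
logistic branch is exercised by its own tests rather than the d-sep
tests). Continuous variables are z-scored once; predictors — including
BG — are standardized inside each regression so all reported path
coefficients are on the standardized scale, while BG stays 0/1 whenever
it is the logistic response.

`C = -2 sum ln p_i` is referred to chi-squared with `2k` df;
`CICc = C + 2qn/(n - 1 - q)` with q = number of edges by default (the
convention differs across the literature; edges + vertices is available
and the choice is recorded). Ranking normalizes `exp(-dCICc/2)`; the
averaging set is `dCICc < 2`, and averaging is conditional (an edge is
averaged only over models that contain it) with Buckland-style SEs;
full-set averaging with absent edges as zero is the natural alternative
but is not the default. The default model set has 11 models: four single
direct effects, six increasingly complex combinations adding the
biogeography-to-climate link and trait cascades, and a full model. The
full model uses 7 edges (three remaining independencies); the
most-complex published variants differ between a 7- and an 8-edge
reading, and the set is overridable from a JSON file for exactly that
reason. Models 1-4 each imply nine independencies.

## Calibration and problem sizes

The suite runs every oracle and recovery check at desk scale, chosen so
the whole suite stays in the minutes range: 50 random trees for the
constant-rate likelihood oracle; <= 20-tip trees for the dense MVN
oracles; 10 replicates of trees with at least 120 sampled tips for the
environment-dependent birth-death recovery (the property concerns large
trees; small simulated trees are skipped, not re-rolled);
12 for OU optima (within 0.2 of truth); 8 DEC fits at ~100 tips; 20-25
replicates at ~100-150 tips for path-coefficient and structure recovery;
250 replicates on a fixed ~150-tip tree for Fisher's-C type-I error
(observed within [0.01, 0.12] at nominal 5%); 60 BM datasets with
120-simulation nulls for MDI calibration. `scripts/acceptance.R` repeats
the same computations at similar sizes from a single `--seed`.

## Known limitations

Single-trait (per-axis) OU only; no measurement error in traits or
rates; no fossil or non-ultrametric tips; DEC `e` unidentifiable as
discussed; the phylogenetic correction in the binary regression is one
published variant (Firth + one variance component) among several; tip
rates carry estimation noise into the path analysis that is not
propagated (the same limitation applies to any tip-rate-based synthesis).
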