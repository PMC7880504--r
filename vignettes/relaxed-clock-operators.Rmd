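---
title: "Relaxed-clock MCMC: models, operators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relaxed-clock MCMC: models, operators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relclock)
```

## The model

`relclock` implements Bayesian inference for a rooted binary time tree `T`
with `N` contemporaneous tips under an uncorrelated log-normal relaxed
molecular clock.  The posterior factorises as

    p(T, R, sigma, muC, theta | D)  ∝
        p(D | T, r(R), muC, theta) p(T | lambda) p(R | sigma)
        p(sigma) p(muC) p(theta)

where each non-root node `i` carries a parental branch of duration
`tau_i` and a substitution rate `r_i`, so that the expected number of
substitutions on the branch (its *genetic distance*) is `muC * r_i * tau_i`.
Rates are iid Log-normal with log-mean `-sigma^2/2`, fixing the prior mean
rate at 1 so the overall clock rate `muC` stays identifiable.

Three parameterisations of the branch-rate vector are supported, all
exposing the same `branch_rates()` surface:

* **real** — the rates themselves (`r(R) = R`), with the log-normal prior
  density evaluated explicitly;
* **cat** — integer bin indices into an `n`-bin discretisation of the
  log-normal (default `n = 2N - 2`); each bin takes its median rate, the
  quantile `(i + 0.5)/n`, and the prior over indices is uniform;
* **quant** — continuous rate quantiles in (0,1) with a flat prior, mapped
  to rates through a piecewise approximation of the log-normal inverse CDF.

### The piecewise quantile map

Evaluating the exact log-normal inverse CDF for every branch at every
proposal is expensive, so the `quant` transform uses 100 equal-width
quantile pieces: the first and final pieces evaluate the exact inverse CDF
while the 98 interior pieces interpolate linearly *in rate space* between
exact knot values.  The inverse map (`quant_from_rate()`) inverts the same
pieces exactly, so transform-and-back is the identity to machine precision —
a property the distance-preserving operators rely on for exact
reversibility.

The approximation is accurate to better than 1e-3 (relative) across the
central quantile range (about [0.05, 0.90]) but degrades to a few percent in
the outermost interior pieces (around q = 0.015 and 0.985) where the inverse
CDF's curvature diverges; this is intrinsic to equal-quantile linear pieces.
Because proposals and priors only ever use the approximate map and its exact
piecewise inverse consistently, this bias affects the meaning of a quantile,
not the correctness of the sampler.

### Priors

`sigma ~ Gamma(shape 0.5396, scale 0.3819)`; per partition,
`kappa ~ Log-normal(1, 1.25)`, base frequencies `~ Dirichlet(10,10,10,10)`
and relative clock rate `muC ~ Log-normal(-0.18, 0.6)` with the
site-count-weighted mean of `muC` held at 1 by a weighted delta-exchange
move (with a single partition `muC` is fixed at 1); the Yule birth rate
`lambda ~ Log-normal(1, 1.25)`.  Log-normal(a, b) always means log-space
mean `a` and log-space standard deviation `b`.  The Gamma prior is read as
shape/scale.

The Yule tree prior uses the labelled-history waiting-time construction:
descending from the root, the interval with `k` extant lineages lasts
`Exp(k * lambda)` and a uniformly chosen lineage splits.  For a fixed
topology this collapses to `(N-1) log(lambda) - lambda * tree_length`, and
`sim_yule_tree()` samples exactly this model, which is what makes the
well-calibrated coverage study a clean closed loop.

### Likelihood

`tree_log_likelihood()` runs Felsenstein pruning over compressed site
patterns with closed-form HKY transition probabilities (the rate matrix is
normalised to unit expected rate, so branch lengths are expected
substitutions).  The pruning kernel is compiled (Rcpp), as is conventional
for phylogenetic likelihoods; gaps and ambiguity codes are treated as
missing data.  Per-pattern rescaling guards against underflow.

## Proposal kernels and tuning

Tunable operators draw a step `s * Sigma` where `Sigma` comes from either a
Uniform(-1, 1) kernel or the Bactrian(m) kernel — the equal mixture of
Normal(±m, sd = sqrt(1 - m^2)), unit-variance and increasingly bimodal as
`m` grows (default m = 0.95, which avoids wastefully small steps).  The
scale `s` adapts by a diminishing Robbins-Monro rule in batches of 50
proposals, `log s += (observed - target)/sqrt(batch)`, towards an
acceptance target of 0.234 for uniform kernels and 0.3 for Bactrian ones.
Tuning freezes when the adaptive weight-sampling phase begins, so learned
operator weights are not chasing moving step sizes.

## The operator family

Single-dimension moves (`op_random_walk`, `op_scale`, `op_interval`,
`op_swap`, `op_uniform_resample`, `op_sample_from_prior`) follow the
standard forms; out-of-domain proposals are rejected rather than reflected,
which keeps every Hastings ratio elementary.

The *constant-distance* family exploits the rate-time correlation ridge:
`op_constant_distance` shifts an internal node height and rescales the
three incident branch rates so every incident genetic distance — and hence
the likelihood — is unchanged; `op_simple_distance` does the same at the
root and `op_small_pulley` shifts genetic distance between the two root
branches at constant total.  Their Green ratios are products of old/new
branch-duration ratios (checked against finite differences in the tests);
in `quant` mode the piecewise-map derivatives multiply in.

`op_cis_scale` scales `sigma` while keeping each rate's *quantile* constant
(`real`) or each quantile's *rate* constant (`quant`), so a clock-variance
move does not drag the whole rate vector off the posterior ridge.

`op_leaf_avmvn` proposes all `N` leaf rates jointly from an adaptive
multivariate normal on log (real) or logit (quant) scale, with covariance
`(2.38^2/N) * ((1 - beta) * SigmaN + beta * I)`, `beta = 0.05`, where
`SigmaN` is a streaming covariance estimate accumulated after burn-in.  The
operator stays unavailable until 200 samples have accumulated; the adaptive
sampler cannot select it before then.

## Narrow exchange rate (NER)

A narrow exchange relocates an uncle branch so a nephew and uncle swap
places; heights are unchanged and the move always alters the topology by
Robinson-Foulds distance exactly 1 (the package RF convention is the
one-sided clade-difference count, i.e. symmetric difference / 2).  NER
variants additionally propose the four incident rates `r_A..r_D` so that a
chosen subset of the six pairwise genetic distances among the nodes A, B, C
and the grandparent E is conserved.

The constraint systems are linear in the proposed rates with coefficients
polynomial in the node heights.  `solve_constraint_set()` performs exact
fraction-free Gauss-Jordan elimination over integer-coefficient
multivariate polynomials (`R/poly.R`), with unconstrained rates keeping
their current values; a subset is *unsolvable* when elimination leaves a
generically nonzero residual, and *zero-Jacobian* when the determinant of
the 4x4 rate-map block (the height row of the full 5x5 Jacobian is
(0,0,0,0,1)) vanishes identically.  The census over all 2^6 = 64 subsets
gives 54 solvable systems, 6 of them with identically zero Jacobian —
irreversible maps — leaving 48 valid operators, or 96 variants counting
each with and without a random walk on t_D (NERw).

Numerical note: the closed-form solutions are exact (verified by
substituting them back into the constraints in integer polynomial
arithmetic), but the *expanded* polynomials for the largest systems lose
several digits to cancellation when evaluated in floating point.  Proposals
therefore instantiate the linear system at the current numeric state and
solve it directly with the same pivot and free-variable convention — the
two routes are cross-checked in the tests.  The Green ratio uses |det|;
proposals with non-positive rates, a vanishing determinant, or `t'_D`
outside `(max(t_B, t_C), t_E)` are rejected, as are configurations whose
taller child is a leaf or whose child heights tie exactly.

The default chain configuration uses only `NER{}` (classic narrow exchange)
and `NER{DAE,DBE,DCE}` — the variant that conserves the distances from A, B
and C to the grandparent — wrapped in an adaptive sampler.  This pair is
closed under the move's reverse labelling, so each is its own reverse and
detailed balance holds with the stated Jacobians.  Arbitrary subsets can be
screened for acceptance rate (`screen_ner_variants()`), where only relative
acceptance against the null operator is measured, not equilibrium sampling.

## Adaptive operator weighting

`adaptive_operator()` wraps a roster of sub-operators and runs three phases
(defaults: first 10% burn-in, next 10% learn-in, then sampling).  During
sampling a sub-operator is drawn uniformly with probability Omega = 0.01
and otherwise proportionally to its accepted squared scaled distance per
unit cumulative cost, where the distance of an accepted move is the squared
RF distance for a tree-valued parameter of interest or
`(1/|p|) (||x - x'|| / sigma_p)^2` for a numerical one (`sigma_p` is the
parameter's running sample standard deviation, pooled over components).  A
meta-operator's parameters of interest are either numerical or the tree,
never both.  The cost is wall time by default, rewarding cheap-and-effective
operators; `cost = "count"` substitutes proposal counts, which makes
equal-seed runs bit-identical at the price of ignoring per-operator compute
cost.  The Omega floor plus diminishing kernel adaptation keep the chain
ergodic.

The named configurations mirror the standard operator-weighting schemes:
`nocons` (simple moves only), `cons` (adds the constant-distance family at
fixed weights), `adapt` (adaptive samplers over sigma, rates and root), and
`avmvn` (splits rates into leaf/internal adaptive samplers, the leaf one
carrying the AVMVN operator).  Within each, the weight behind the rate
vector sums to 30 with node-set weights proportional to `N`-dependent
fractions, sigma carries 10, and the topology (narrow-exchange) weight is
15.

## Simulation harnesses and what the tests show

`simulate_dataset()` draws a Yule tree, iid log-normal branch rates and an
HKY alignment; it emulates rate heterogeneity across branches with
contemporaneous tips and no rate autocorrelation, alignment gaps,
selection, or model misspecification — so passing tests demonstrate
correctness of the sampler under its own generative model, not robustness
on real data.

Three study designs are wired into the test suite at desk scale, chosen to
keep the default run within minutes while leaving the statistics
interpretable:

* **Prior sampling** — data-free chains of 1e5 states under every operator
  configuration must reproduce each analytic prior marginal
  (Kolmogorov-Smirnov on ESS-thinned subsamples, p > 0.01; branch rates are
  checked through the probability integral transform given the sampled
  sigma).
* **Well-calibrated coverage** — 50 replicates at N = 8, L = 500 sites:
  truths drawn from the priors, data simulated, chains of 16,000 states;
  95% credible intervals for sigma, tree length and kappa must cover at the
  exact binomial band around 0.95.
* **Directional screening** — on 6 strong-signal (sigma = 0.8, L = 2 kb)
  and 6 weak-signal (sigma = 0.1, L = 0.2 kb) datasets with N = 10,
  NER{DAE,DBE,DCE} must beat the null operator's acceptance rate on the
  former and lose on the latter, reproducing the qualitative
  signal-dependence of the operator.

## Numerical and design choices

* Node indexing is 1-based with tips 1..N in input order and internals
  N+1..2N-1; the root entry of the branch-rate vector is `NA`.
* Heights derive from newick depths as `max depth - depth`, so
  non-ultrametric inputs keep positive tip heights; the Yule prior demands
  ultrametric trees.
* Ties in child heights reject a narrow-exchange proposal (measure-zero
  under continuous heights; avoids an irreversible branch).
* Degenerate ESS input (a constant series) reports `n` with a degeneracy
  flag; the estimator is the initial-positive-sequence truncation of the
  autocorrelation sum.
* Chains stop immediately on an initial state with a -Inf posterior rather
  than silently burning in from an impossible state.

## Known limitations

* Single-chain driver only; no heated/coupled chains, checkpointing, or
  parallel likelihood.
* HKY (with Jukes-Cantor as a special case) is the only substitution model;
  the clock prior is log-normal only.
* Starting trees are drawn from the Yule prior rather than from a
  distance-based estimate, so burn-in on strongly informative alignments is
  longer than it would be with a data-informed start.
* The general NER census covers all 48 valid operators, but chains only
  employ the self-reverse pair {NER{}, NER{DAE,DBE,DCE}}; arbitrary subsets
  are exposed for screening, where reverse-pairing is irrelevant because
  only acceptance rates are compared.
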