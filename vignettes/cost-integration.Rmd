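---
title: "Separating connectivity strength from topology by cost-integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating connectivity strength from topology by cost-integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costnet)
```

## The problem

Functional brain networks — and weighted networks in the biomedical sciences
generally — arrive as symmetric association matrices: correlations between
regional time series, partial correlations, synchronization likelihoods.
Comparing the *topology* of two such networks is confounded by their
*connectivity strength*: thresholding two matrices at the same absolute
cutoff gives the denser network more edges, and almost every topological
metric increases with edge count. A difference in mean correlation then
masquerades as a difference in architecture.

`costnet` implements the cost-integration approach to this confound. The
wiring **cost** of an unweighted graph is its edge density N_E/M, with
M = N(N-1)/2 the saturated count. A weighted network on N nodes can be
thresholded to *any* cost on the discrete grid P = {k/M : k = 1..M} by
keeping its top-k edges by weight rank. Treating cost as a random variable C
with a chosen probability mass function over P, the cost-integrated version
of a metric T is the expectation

E[T(tau(W, C))] = sum_k p(c_k) T(tau(W, c_k)),

where tau is the rank-based thresholding function. The package's two
recommended outputs for any comparison are therefore (i) the **weighted
cost** (mean off-diagonal weight) of every network, capturing strength, and
(ii) one or more cost-integrated topological metrics, capturing
architecture.

## Why ranks make this work

`thresholdAtCost()` keeps edge (i, j) iff its percentile rank (rank/M,
rank 1 = largest weight) is at most the requested cost, so the thresholded
graph has *exactly* cost·M edges — off-grid costs are rejected rather than
rounded, because this exactness is part of the contract. Ranks are invariant
under any strictly monotone increasing transformation of the weights, hence
so is every thresholded graph and every cost-integrated metric, for every
metric and every distribution over cost. This is the central invariance the
package is built around, and the test suite exercises it directly with
x^2, sqrt, affine and exponential transforms: the integrated values agree
to well below 1e-12 (in fact exactly, since the thresholded graphs are
identical). For a monotone *decreasing* transform the order reverses;
`edgeRanks(net, decreasing = FALSE)` ranks from the smallest weight so the
invariance remains testable in that direction too.

The flip side of the invariance is that cost-integration is *blind* to
strength: `proportionalPair()` builds networks with weighted costs in an
exact ratio yet identical integrated topology. That is the point — strength
is reported separately — but it also means cost-specific topological
differences are averaged over, and genuinely cost-localized effects can be
masked (see Limitations).

Tied weights would make the ranking ambiguous. Ties are resolved by the
lexicographic order of the index pairs, never randomly: random allocation
would inject spurious random topology at the tied levels.
`countTiedRanks()` reports how many weights are involved in ties, and the
`cmdCost()` report warns when the count is non-zero, since networks
differing markedly in tie counts are not cleanly comparable.

## Metrics

Global efficiency is the mean reciprocal shortest-path length over ordered
pairs, with 1/Inf = 0 for disconnected pairs, so it is defined at every
cost level (unlike the characteristic path length, which is infinite on
disconnected graphs). Local efficiency averages, over nodes, the global
efficiency of each node's neighbor-induced subgraph; nodes with fewer than
two neighbors contribute zero, which keeps the metric integrable down to
the sparsest costs. Both lie in [0, 1] and equal 1 on the saturated graph.
`integrateExact()` also accepts *any* user function of a `BinaryGraph`, so
the framework is metric-agnostic.

Weighted efficiency (`weightedEfficiency()`) uses shortest paths on edge
lengths phi(w), with the reciprocal map as default; phi is pluggable
(e.g. -log w) but alternatives fall outside the collapse result below.
Whenever every direct edge is itself a weighted shortest path — guaranteed
as soon as max(W) <= 2 min(W), since any two-edge detour has length at
least 2/max(W) >= 1/w — the weighted efficiency *equals* the weighted cost.
Standardized correlation matrices sit in or near this regime routinely, so
weighted efficiency rarely adds information beyond mean connectivity; the
package keeps it available mainly to let users verify this on their own
data. A three-node counterexample with weights {1, 0.4, 1} gives weighted
efficiency 5/6 against weighted cost 0.8.

Weighted metrics require a fully weighted network (all weights strictly
positive): a zero weight has infinite reciprocal length and is rejected
rather than silently dropped. Rank-based operations, by contrast, accept
any finite symmetric matrix, standardized or not.

## Distributions over cost

Three families are provided, all with pmfs summing to 1 within 1e-12:

* `uniformCostDistribution()` — mass 1/M everywhere; the default when no
  cost regime is preferred.
* `betaBinomialCostDistribution(grid, alpha, beta)` — the level with k
  edges gets the Beta-binomial mass at k-1 with M-1 trials. The unit shift
  matches the exclusion of the null cost from the grid. alpha = beta = 1
  recovers the uniform exactly; alpha = beta > 1 de-emphasizes the extreme
  costs; asymmetric choices are allowed. Masses are computed in log space
  (log-gamma) and renormalized once, so a 90-node grid (M = 4005) is safe
  from underflow. The closed form for the mean edge count,
  1 + (M-1)alpha/(alpha+beta), is asserted in the tests.
* `restrictToInterval()` — conditional distribution on a sub-range of the
  grid. Because the support is discrete, whether an endpoint is included
  changes the result, so the closure (closed / half-open on either side) is
  an explicit argument, defaulting to closed; the bounds and closure travel
  with the descriptor and are echoed in all reports, since conclusions are
  conditional on them.

The null cost is excluded from the default grid. The two-node example shows
why: a 2-node network has M = 1, its single thresholded graph is the
connected pair with efficiency 1, so the uniformly integrated efficiency is
1 for *any* weight in (0, 1) — the natural standardization. Retaining the
null cost would pull every such value to 1/2 for no informational gain.
`costGrid(n, includeNull = TRUE)` reproduces that diagnostic.

## Exact evaluation and its cost

Exact integration evaluates the metric at every support level. The package
walks the *nested* threshold profile — edges inserted one rank at a time —
instead of re-thresholding from scratch. For the built-in metrics the
evaluation itself is incremental:

* global efficiency: inserting one unit-length edge (i, j) can only create
  shortest paths through it, so d'(u,v) = min(d(u,v), d(u,i)+1+d(j,v),
  d(u,j)+1+d(i,v)) — an exact O(N^2) update per level, verified against
  igraph's BFS and, on graphs of up to 7 nodes, against exhaustive path
  enumeration;
* local efficiency: inserting (i, j) only changes the neighbor subgraphs of
  i, j and their common neighbors, so only those per-node contributions are
  recomputed (via a small Floyd–Warshall kernel).

A full-grid global-efficiency curve for N = 90 (4005 levels) takes a few
seconds on one CPU. Both incremental paths are tested to agree exactly with
direct evaluation at each level.

## Monte-Carlo integration

For large grids, `mcIntegrate()` approximates the integral by the empirical
mean of the metric at n costs sampled i.i.d. from the pmf (plain Monte
Carlo, no variance reduction — the reported standard error describes
exactly this estimator). The MC standard error is sd(draws)/sqrt(n);
`confidenceBand()` gives estimate ± 2 SE by default, and `runningTrace()`
exposes the cumulative mean and SE for convergence plots. Seeds are
mandatory arguments and are stored in the result, so every stochastic
number in a report is reproducible. Because the metric value at a grid
level is deterministic, repeated draws of a level reuse one evaluation;
the estimator is unchanged. The suite checks ~95% empirical coverage of
the exact value by the ±2 SE band over 100 seeds on a 90-node network,
and that seed-averaged estimates converge to the exact integral.

## Synthetic generators

The generators stand in for real connectivity data and define the
conditions under which the package's guarantees are exercised:

* `randomWeightedNetwork()` — i.i.d. uniform weights, almost surely
  tie-free; the generic property-test fixture.
* `proportionalPair()` — strength differs, ranks identical.
* `twoNodePair()` — the minimal grid (M = 1).
* `layeredAssociationMatrix()` — matrices whose thresholded topology
  changes by cost band: "regular" bands follow a ring-lattice ordering
  (edges by increasing ring distance, then index), "random" bands draw
  uniformly among unused pairs. Weights are any strictly decreasing
  sequence in rank order — rank invariance makes every such choice
  equivalent, which is the invariance used constructively. Band boundaries
  are configurable; the defaults split the grid into thirds, and the
  fixtures are built at N = 90 (M = 4005) to mirror a standard 90-region
  cortical parcellation. Two specs sharing their leading band yield
  *identical* thresholded graphs throughout that band (so restricted
  integrals agree exactly), while a regular/random/regular hybrid is
  strictly more globally efficient than an all-regular matrix over the
  full grid, its random layers acting as shortcuts. These checks are
  directional by design: the construction fixes an ordering, not
  particular numeric efficiencies.

What the generators do *not* emulate: empirical correlation matrices have
dependent entries, heavier-tailed weight distributions, block/community
structure and measurement noise. Passing tests therefore demonstrate the
algebraic guarantees (exact cost, nesting, invariance, collapse, coverage)
— which hold for any input by construction — not that any particular real
dataset is well described by these fixtures.

## Numerical choices

* Grid membership uses |cost - k/M| <= 1e-9; grid levels are generated as
  k/M so `binaryCost(thresholdAtCost(W, c)) == c` holds bit-for-bit.
* Symmetry repair averages with the transpose when the relative asymmetry
  is within 1e-8 (errors otherwise); the diagonal is always zeroed.
* Infinite distances are IEEE `Inf`; 1/Inf is exactly 0, matching the
  disconnected-pair convention without sentinels.
* The exact standardization map from correlations is a user choice:
  |r| (default) or (r+1)/2. Both send negative correlations to positive
  association, but they order the weights differently when negatives are
  present, so the method is recorded in the object and reports rather than
  silently resolved.
* MC requires n >= 2 (the standard error is undefined at n = 1); the
  running SE at the first draw is reported as NA.

## Problem sizes

The shipped tests run at desk scale, chosen to finish in a couple of
minutes on one CPU while still exercising every guarantee at a non-trivial
size: 20-node networks (M = 190) for the invariance suite, 15 nodes for
the collapse regime, 90 nodes (M = 4005) for the layered examples and the
Monte-Carlo coverage study (100 seeds x 1000 draws), graphs of up to 7
nodes for exhaustive-enumeration oracles.

## Limitations

Cost-integration averages over cost and can mask cost-localized
differences — the layered example is exactly a pair of networks
indistinguishable on one band and different overall; integrating only over
that band would miss the difference, which is why restricted-domain results
are always reported with their bounds. Comparability requires equal node
counts *and* equal numbers of positive weights; for sparser networks the
recommended route is integration over a sub-interval reflecting the common
sparsity, which the tools expose but do not auto-select. Dependence between
the nested thresholded graphs is not modeled: the integral weights levels
by the pmf, while the topologies at neighboring levels share most of their
edges. Directed networks and sign-aware (inhibitory vs excitatory) analyses
are out of scope.
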