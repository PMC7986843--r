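---
title: "Bootstrap stability of correlation-network modules: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap stability of correlation-network modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netstab)
```

## The estimation problem

A correlation network is an *estimated* object. With `N` subjects and `p`
variables, every entry of the Pearson correlation matrix carries sampling
error of order `1/sqrt(N)`, and hard-thresholding at `t` turns that noise
into discrete presence/absence of edges. Community detection then amplifies
it further: a handful of flipped edges can merge two modules or split one.
`netstab` treats this honestly by propagating the sampling variability
through the whole pipeline with the nonparametric bootstrap, and by scoring
thresholds on how much *more* stable their modules are than chance.

Two design commitments follow from what the data are. First, the nodes are
variables, not subjects, so the resampling unit is the subject (row): each
bootstrap replicate redraws the `N` rows with replacement and recomputes the
correlation matrix, the graph, and the modules. Second, because the node set
is fixed across replicates, partitions can be compared *through nodes* —
no module-matching step is ever needed.

## Stability at three levels

For two partitions and a node `n`, the similarity
`A(n) = Jaccard(M_a(n), M_b(n))` compares the node's module in each
partition. Averaging over nodes gives the agreement between two partitions;
averaging over bootstrap replicates gives the conditional stabilities:
node-level (mean Jaccard against the reference over replicates),
module-level (mean node stability over a module's members — the normalized
form, bounded by 1 and consistent with the node definition), and overall
(mean over all nodes, identically the mean agreement of replicates with the
reference). Two exact identities — module stability is the member mean, and
overall stability is the all-node mean — are asserted in the test suite to
`1e-12` on every run; they are algebraic, not statistical, properties.

All of these condition on the reference partition M⁰. For threshold
*selection* a symmetric quantity is needed, so the unconditional observed
stability `S_obs` averages the agreement over all pairs among the `B + 1`
partitions, reference included.

## The null correction and threshold selection

Raw stability rewards the two trivial graphs: complete (one module, always)
and edgeless (all singletons, always). The profile therefore subtracts the
stability expected under "same degrees, no structure": `m` degree-preserving
randomizations of the reference graph (double-edge-swap MCMC with `10 |E|`
attempted swaps, rejecting loops and multi-edges, so the degree sequence is
conserved exactly in node order), each clustered, and the mean pairwise
agreement among the resulting `m` partitions taken as `E[S_null]`. The
selected threshold maximizes `S_delta = S_obs - E[S_null]` on the grid.

Numerical and procedural choices here, all deliberate:

- **Strict inequality** `|C| > t` defines an edge; ties at exactly `t` are
  excluded. At `t = 0` a correlation of exactly zero therefore yields no
  edge — the rule is applied literally rather than special-cased.
- **Tie-break toward the smaller threshold** when several grid points share
  the maximal gap: under-thresholding merges information that clustering can
  still separate, while over-thresholding destroys it, so the smaller `t` is
  the cheaper mistake. The simulations bear this out — selected thresholds
  one step below the separating value still recover the true partition.
- **The null ensemble is generated once per threshold** from the reference
  graph, not per bootstrap replicate: the null hypothesis concerns the
  reference graph's degree sequence, and the `m(m-1)/2` pairwise agreements
  are what stabilize the estimate.
- **Bootstrap correlation matrices are computed once** and re-thresholded at
  every grid point. Per threshold this is the same Monte-Carlo estimator as
  redrawing fresh resamples inside the threshold loop (each threshold still
  sees `B` honest replicates); it simply reuses the expensive step, making
  the profile `k` times cheaper on a `k`-point grid. A side effect is that
  the `S_obs` curve is smoother in `t` than under independent per-threshold
  resampling, which if anything helps the argmax.
- **Degenerate replicates** (a resample in which some variable is constant,
  leaving its correlations undefined) are redrawn with a warning, capped at
  `10 B` redraws; with continuous data at realistic `N` this effectively
  never triggers, but it makes small-`N` behavior defined rather than
  accidental.
- **Seeding**: one master seed; the bootstrap stream, the per-threshold
  null-graph streams, and (in simulations) the data-generation stream are
  drawn as separate substreams, so changing `m` never perturbs the bootstrap
  draws and results are reproducible bit-for-bit.
- **Edgeless thresholds are legal**: detection returns the all-singleton
  partition (flagged in the profile diagnostics) instead of erroring, so a
  grid may extend into the empty regime.

Community detection is `igraph::cluster_fast_greedy`, the standard CNM
agglomeration with the dendrogram cut at maximal modularity; it is
deterministic for a fixed graph, which the tests assert. One quirk worth
knowing: igraph's cut never considers the final all-merged state, so on a
*complete* graph it returns a two-community cut with `Q` slightly below
zero rather than the single all-inclusive module with `Q = 0`. This does
not affect stability (the cut is the same in every replicate, so the
fully-connected limit is still perfectly stable) and only manifests where
there is no structure to find. The modularity function itself
(`graph_modularity`) is implemented directly from the `e_ij`/`s_i`
definition and cross-checked against both a from-scratch evaluation and
igraph's in the tests; isolated nodes touch no edges and contribute
nothing to either term.

## Defaults and what they mean

| parameter | default | meaning / rationale |
|---|---|---|
| `B` | 100 | bootstrap replicates; 100 is the conventional desk-scale choice for bootstrap stability, and the profile's Monte-Carlo error scales as `1/sqrt(B)` |
| `m` | 50 | null graphs per threshold; 50 graphs give 1,225 pairwise agreements, plenty to pin `E[S_null]` |
| `thresholds` | 0.30–0.90 step 0.05 | the simulation-scale grid; observational data with weaker signal warrant extending down to 0.20 |
| swap count | `10 |E|` | attempted double-edge swaps per null graph, the common mixing heuristic |
| p-value baseline `level` | 0.05 | Bonferroni-adjusted two-sided correlation test, adjusting by the `p(p-1)/2` tested pairs, capped at 1 |

## What the simulator emulates — and what it does not

`block_correlation(p, n_modules, alpha, beta)` builds the ground-truth
model: unit diagonal, within-block correlation `alpha`, between-block
`beta`, with `0 <= beta < alpha < 1` so that any threshold in
`[beta, alpha)` separates the blocks exactly. Positive definiteness is
checked by the smallest eigenvalue (for equal blocks the spectrum is known
in closed form and the tests compare against it). When `p` is not divisible
by the block count the remainder is spread one node per leading block.
`sample_gaussian` draws exact multivariate-normal samples;
`ggm_sample` is the generic graph-Markov sampler (precision matrix with the
graph's sparsity pattern, diagonally dominant by construction) for studies
whose truth is a graph rather than a block matrix.

This emulates equal-sized, non-overlapping, equicorrelated modules under
Gaussian sampling. Real omics data differ in ways the generator
deliberately omits: heavy tails and skew (metabolite intensities), missing
values (rejected, not imputed, by this package), unequal and nested module
sizes, hub-dominated within-module structure, and overlapping membership.
Passing the simulation suite therefore demonstrates that the machinery is
correct and that the selector recovers separable structure — not that any
particular biological dataset has such structure. On real data the
stability values themselves are typically far lower, and the *relative*
profile across thresholds is the informative output.

The package's experiments run at deliberate desk scale: the recovery checks
use `p = 100`, 10 blocks, `B = 50`, `m = 20` and 5 datasets per cell, which
keeps a full three-cell sweep around a minute of CPU while leaving the
Monte-Carlo error of a 5-seed mean ARI near 0.005; the test suite's smaller
fixtures (`p` 12–60) are sized so every oracle comparison is exact and
fast.

## Behavior on structureless data

On independent variables the selector must not invent a threshold, and it
does not — but the *shape* of the null-data profile is instructive. At
thresholds where the empirical graph retains a few dozen noise edges,
`S_delta` is strongly **negative**, not zero: a near-empty graph is almost
rigid under degree-preserving rewiring (its randomizations, hence their
partitions, are nearly identical, so `E[S_null]` approaches 1), while
bootstrap resampling changes *which* noise correlations clear the threshold
at all, so `S_obs` stays low. The gap statistic thus actively penalizes
noise-edge regimes rather than merely ignoring them; what it never does on
such data is rise meaningfully above zero, which is the property the
trivial-solution guard needs and the one the tests assert.

## Known limitations

- Pearson correlation only is tested; the correlation step is a hook, and
  any association measure yielding a valid correlation-like matrix can be
  substituted upstream, but rank-based or partial-correlation graphs are
  not validated here.
- Fast-greedy modularity inherits the resolution limit of modularity
  optimization; very small modules attached to large ones may be absorbed,
  and single nodes that lose their edges at a high threshold come back as
  low-stability singletons (visible, by design, in the module report).
- `E[S_null]` is Monte-Carlo, not analytic; on very sparse graphs the
  rewiring chain has little to mix and the null collapses toward 1, which
  is correct but means `S_delta` comparisons across very different edge
  densities should be read qualitatively.
- The bootstrap treats subjects as exchangeable; repeated-measures or
  time-series designs would need a block bootstrap upstream of this
  package.
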