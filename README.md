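# netstab

Bootstrap stability of module detection in correlation networks.

## The problem

Correlation networks are a workhorse of systems biology: measure *p*
variables (metabolites, transcripts, proteins) on *N* subjects, compute the
*p* × *p* Pearson correlation matrix *C*, and connect nodes *i* and *j*
whenever |*C*(*i*, *j*)| > *t* for some threshold *t*. Communities
("modules") detected in that graph are then read as functional groups. Two
things make this fragile: the graph is *estimated* from finite data, so the
module structure inherits the sampling noise of the correlations; and the
threshold *t* is a free parameter that silently decides how many modules
exist. `netstab` quantifies the first problem and uses it to solve the
second.

## The method

Modules are detected by fast-greedy modularity optimization
(Clauset–Newman–Moore), maximizing

> Q = Σᵢ (eᵢᵢ − sᵢ²)

where *e*ᵢⱼ is the fraction of edges joining modules *i* and *j* and
*s*ᵢ = Σⱼ *e*ᵢⱼ.

Stability is estimated by the nonparametric bootstrap. The *N* subjects are
resampled with replacement *B* times; each resample yields its own
correlation matrix, graph (at the same *t*), and module set ℳᵇ. Writing
A(n, ℳ⁰, ℳᵇ) for the Jaccard similarity between the module containing node
*n* in the reference partition ℳ⁰ and in ℳᵇ:

- **node stability** S_node(n) = (1/B) Σᵦ A(n, ℳ⁰, ℳᵇ) — how reliably a
  node keeps its neighborhood;
- **module stability** S_module(M) = mean of S_node over M's members;
- **overall stability** S_over = mean of S_node over all *p* nodes,
  identically the mean agreement of the bootstrap partitions with ℳ⁰.

For threshold selection, raw stability is useless on its own: a complete
graph (*t* = 0) and an edgeless one (*t* ≥ 1) are both perfectly stable and
perfectly uninformative. `netstab` therefore computes the *unconditional*
observed stability S_obs(*t*) — the mean pairwise agreement among all
*B* + 1 partitions — and subtracts the stability expected with no module
structure at all, estimated from *m* degree-preserving randomizations
(double-edge-swap) of the reference graph:

> S^Δ(t) = S_obs(t) − Ê[S_null(t)]

The selected threshold **t_opt maximizes S^Δ** over a grid (ties go to the
smaller *t*, the cheaper mistake). This is a gap-statistic-style correction:
structure only counts when it is more stable than a degree-matched random
graph.

## Worked example

Six blocks of 10 variables with within-block correlation 0.7, between-block
0.1, observed on 50 subjects:

```r
library(netstab)
C   <- block_correlation(p = 60, n_modules = 6, alpha = 0.7, beta = 0.1)
x   <- sample_gaussian(C, N = 50, seed = 1)
fit <- stability_profile(x, thresholds = seq(0.3, 0.9, by = 0.1),
                         B = 30, m = 10, seed = 1)
fit
```

```
Bootstrap stability profile of a correlation network
  N = 50 observations, p = 60 variables, B = 30 bootstraps, m = 10 null graphs
 threshold  s_obs s_null  s_delta n_edges n_modules edgeless
       0.3 0.4266 0.1590  0.26760     300         6    FALSE
       0.4 0.6531 0.1499  0.50314     271         6    FALSE
       0.5 0.9001 0.1506  0.74957     262         6    FALSE
       0.6 0.9330 0.1590  0.77400     202         7    FALSE
       0.7 0.6886 0.3529  0.33567      83        21    FALSE
       0.8 0.7089 0.8732 -0.16429       9        53    FALSE
       0.9 0.9754 1.0000 -0.02458       0        60     TRUE
Selected threshold t_opt = 0.6 (max S_delta), 7 modules there
```

The profile peaks at *t* = 0.6, inside the separating band [0.1, 0.7): low
thresholds drown the blocks in noise edges, high ones shatter them, and both
extremes are exposed by the null correction (S^Δ ≤ 0 once the graph is
nearly empty). `summary(fit)` adds the conditional report at t_opt:

```
t_opt = 0.6: S_obs = 0.9330, E[S_null] = 0.1590, S_delta = 0.7740
7 modules at t_opt; edge count 202
...
    module 5 (n = 10): 1.0000
    module 6 (n = 9): 0.8957
    module 7 (n = 1): 0.4004
```

Six stable modules are the six true blocks; the seventh is a single node
that fell out of its block at this threshold, and its low stability (0.40)
flags exactly that. `plot(fit)` draws the observed/null curves and the S^Δ
profile; `coef(fit)` returns t_opt.

`run_block_experiment()` scores recovery of the true partition by adjusted
Rand index and runs the conventional Bonferroni p-value graph as a baseline;
`simulation_sweep()` crosses parameter cells and seeds into a tidy table.

## Command line

A thin wrapper over the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "netstab.R", package = "netstab"))')" \
    profile --input data.csv --t-min 0.3 --t-max 0.9 --t-step 0.05 \
    --B 100 --null-m 50 --seed 1 --out results/
```

Verbs: `profile` (threshold selection pipeline; writes profile CSV/JSON,
per-threshold stability reports, module TSV and edge list at t_opt, run
metadata), `stability` (report at one fixed *t*), `simulate` (block-model
sweep).

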