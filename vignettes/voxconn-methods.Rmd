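---
title: "Methods: voxel-wise correlation networks and their graph-theoretic analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-wise correlation networks and their graph-theoretic analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxconn)
```

## The problem

Resting-state functional MRI yields one time series per voxel. Treating every
gray-matter voxel as a network node (typically tens of thousands of nodes,
hence ~10^9 candidate edges) gives a functional connectome at the finest
spatial grain the data support, avoiding the arbitrariness of region-based
parcellations. `voxconn` implements the full desk-scale analysis chain for
such networks: correlation-based construction, thresholding into sparse
binary graphs, all-pairs shortest paths, clustering, spectral modularity,
degree-preserving null ensembles, and the derived small-world, hub and
degree-distribution statistics. Everything runs on a single CPU; the
algorithms are organized in blocks so that the dense intermediates never
need to be held in full when that matters.

## Network construction

Each column (node) of the time-series matrix is centered and scaled to unit
norm, giving `U` with the property that `t(U) %*% U` is exactly the Pearson
correlation matrix `R`. `blocked_correlation()` evaluates that product block
by block — only the upper block triangle, since `R` is symmetric — so peak
dense storage is one `block_size`-wide block (default 2048 columns, a
comfortable CPU memory budget). Multi-subject studies average per-subject
`R`s element-wise (`group_average()`; a Fisher-z variant is available but
off by default, the plain mean of r being the conventional group matrix).

A correlation threshold turns `R` into a simple binary graph: edge iff
`R[i, j] > r` (strict). The admissible threshold range is bracketed
analytically:

* lower sparsity bound `S1 = log(N) / (N - 1)`, from the requirement that
  the mean degree exceed `log(N)` for estimable small-world statistics
  (natural logarithm: at N = 58523 this gives 0.019%, which decimal base
  does not);
* upper bound via `bonferroni_threshold(N, L)`: the critical r solving the
  two-tailed t relation `t = r * sqrt(df / (1 - r^2))` with `df = L - 2` at
  per-test level `alpha / (N(N-1)/2)`. At N = 58523, L = 215 this is 0.43.
  No effective-df correction for temporal autocorrelation is applied; the
  threshold refers to the nominal Pearson null.

```{r bounds}
100 * sparsity_lower_bound(58523)
bonferroni_threshold(58523, 215)
```

## All-pairs shortest paths

Two engines produce identical hop-distance matrices:

* `apsp_bfs()` — one breadth-first search per source, O(N(N+M)), the right
  choice for sparse graphs. Sources are degree-sorted and dealt round-robin
  over `workers` queues; this is purely a load-balancing schedule and the
  result is bitwise independent of `workers`.
* `apsp_blocked_fw()` — the blocked Floyd–Warshall algorithm on an
  `r x r` grid of `block_n`-wide tiles of the cost matrix (0 diagonal, 1 on
  edges, Inf elsewhere). Each round processes a diagonal "primary" tile in
  three phases (primary; its row/column; all the rest) through the min-plus
  update `C[i,j] <- min(C[i,j], C[i,k] + C[k,j])`. Phase 1 applies the
  blocked algorithm to the primary tile recursively (classic triple loop at
  or below 16 nodes), and only the upper tile triangle is stored — the
  network is undirected, so a missing source tile is the transpose of its
  symmetric counterpart.

`select_apsp()` chooses between them at the 2% sparsity crossover (BFS cost
scales with edge count, blocked FW is sparsity-independent); ties go to BFS.

Numerical conventions: `Inf` is the unreachable sentinel (IEEE addition
saturates, so no overflow is possible); trailing tiles are ragged rather
than padded, so any `block_n` is exact; distances are returned in a blocked
upper-triangular store (`distance_matrix`) and densified on demand.

`characteristic_path_length()` averages finite distances over unordered
pairs. Whether disconnected pairs should enter Lp is genuinely open in the
thresholded-connectome literature; the package's documented policy is to
exclude them (with `strict = TRUE` available to refuse disconnected input),
and `global_efficiency()` — the mean of inverse distances with `1/Inf = 0` —
is provided as the disconnection-penalizing complement.

## Spectral modularity

Modularity `Q = (1/2m) * sum((A - k k'/2m) * same-module)` is maximized by
Newman's spectral bisection. The modularity matrix `B = A - k k' / 2m` is
never formed: `modularity_operator()` applies it as
`A x - k (k'x) / 2m` (sparse product plus dot products), with the
generalized diagonal correction `d` on restricted node sets so that
sub-division optimizes the true ΔQ. The leading eigenpair comes from
`power_method()`:

* pass 1: plain power iteration (seeded uniform start, orthogonalized
  against the all-ones null vector);
* pass 2 (only if the dominant-magnitude eigenvalue is negative): iterate on
  `B - beta I` and shift back, which makes the algebraically largest
  eigenvalue dominant;
* a norm-bound shift (`B + ||B|| I`, Gershgorin-style bound) is the fallback
  for the rare near-cancelling `+/-` dominant pair;
* convergence at relative residual 1e-8, cap 10^4 iterations per pass.

`spectral_divide()` drives a division queue: dequeue a module, compute the
leading eigenpair of its restricted operator, and if `beta > 0` split by the
eigenvector's sign pattern (exact zeros join the positive side — a
deterministic tie-break) and enqueue both halves. On top of the `beta > 0`
test, the split must also strictly increase Q, evaluated exactly as
`s' B s / 4m`; this guards against sign patterns whose split is marginally
detrimental. Kernighan–Lin fine-tuning is deliberately not implemented: the
method is plain recursive spectral bisection, and on some realizations of a
noisy planted partition it strands individual nodes (its known limitation).
Fixed seeds make partitions exactly reproducible.

## Null models and derived statistics

`maslov_rewire()` randomizes topology under an exactly preserved degree
sequence by double-edge swaps: draw two edges, randomize their orientation,
swap endpoints, reject self-loops and duplicates. The target is 10 accepted
swaps per edge (a convention, configurable — the literature rarely states
this number); after 100x that many proposals without reaching the target the
current graph is returned flagged `maslov_saturated` (a triangle, for
example, admits no legal swap). Connectivity is deliberately not enforced;
Lp on nulls uses the same finite-pairs policy. `ensemble_summary()` builds
n = 15 such nulls by default (seeds `base_seed + 0..n-1`) and reports
ensemble means and sample (n-1) standard deviations of Cp and Lp (and null
Q when requested).

The small-world indices are plain ratios: `gamma = Cp/Cp_rand`,
`lambda = Lp/Lp_rand`, `sigma = gamma/lambda`; across a threshold sweep they
are summarized by geometric means (the natural average of ratios).
`modularity_zscore()` is `(Q - mean(Q_null)) / sd(Q_null)`. Hubs are nodes
with degree above mean + 1 sample sd (isolated nodes counted in the mean and
sd, excluded from distribution support).

`fit_power_law()` fits `p(k) ~ c k^-gamma`. The default is OLS of
`log10 p(k)` on `log10 k` over occupied unit bins — the way exponents are
conventionally read off a log-log degree plot. That estimator is biased
shallow when the tail thins into singleton bins sitting on the `1/n` floor;
the package therefore also exposes `min_count` (fit only bins holding at
least that many nodes) and `method = "mle"`, the exact discrete
zeta-normalized maximum-likelihood estimator, which is essentially unbiased.
The divergence between the fitting routes is real and documented rather than
hidden: reported exponents always state their method.

## The synthetic-data generator

`planted_design()` + `gen_modular_timeseries()` stand in for multi-subject
resting-state data: zero-mean unit-variance Gaussian series with
block-constant correlation (`within_r` inside each of `n_modules` equal
modules, `between_r` across), realized exactly by a three-factor
construction (shared factor, module factor, idiosyncratic noise) that is
positive semi-definite precisely when `0 <= between_r <= within_r < 1`.
Optional AR(1) smoothing (`ar`) mimics the band-limited character of
hemodynamic signals without changing cross-node correlations; it is off by
default. Per-subject variation enters as a small random tilt of the
within-module loading (`subject_noise_sd`, default 0.05).

The default design — 100 nodes in 4 modules, L = 2000, `within_r = 0.9`,
`between_r = 0`, seed 1 — is the package's standard end-to-end fixture: it
thresholds into four near-cliques whose planted partition the spectral
divider recovers exactly, and which are strongly small-world against their
rewired nulls. What passing on this generator shows is that every algorithm
is correct on data satisfying its assumptions; it does not show robustness
to what real fMRI adds (hemodynamic autocorrelation beyond AR(1), motion and
physiological artifacts, global-signal structure, inhomogeneous module
sizes, negative correlations). Benchmark graphs (`gen_graph()`: cliques,
rings, lattices, planted partitions, barbells, ER) provide closed-form and
exhaustively enumerable oracles for the metric and modularity code.

## Problem sizes and test design

The test suite checks the engines against brute-force oracles (textbook
Floyd–Warshall, exhaustive double-sum modularity, enumeration of all set
partitions) on hundreds of random graphs up to 60 nodes, closed forms on
rings and lattices (`Lp = (N^2/4)/(N-1)` for even rings,
`Cp = 3(k-1)/(2(2k-1))` for ring lattices), and the end-to-end planted
design at N = 100, L = 2000 with 3-network null ensembles — sizes chosen so
the whole battery stays in the minutes range on one CPU while exercising
every code path, including ragged blocking and disconnected graphs. The
reference-scale quantities (the 58523-voxel sparsity window, the published
small-world table's summary arithmetic) are pure arithmetic at full scale.

## Known limitations

* Weighted networks, partial correlations and negative-edge conventions are
  out of scope; graphs are simple, undirected, unweighted.
* Recursive spectral bisection without KL refinement can under-partition
  noisy community structure (see above); module counts on real data should
  be read with that in mind.
* Lp's finite-pairs policy makes extremely sparse, fragmented thresholds
  look shorter-pathed than a disconnection-penalizing convention would;
  global efficiency is the cross-check.
* The Bonferroni threshold assumes nominally independent Gaussian samples;
  band-pass filtered series have fewer effective degrees of freedom, so the
  upper sparsity bound is optimistic for heavily filtered data.
* Dense correlation matrices persist as `.rds` files from the CLI; very
  large studies should stream blocks via `blocked_correlation(callback=)`
  instead of materializing `R`.
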