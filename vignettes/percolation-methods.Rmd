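---
title: "Edge-percolation clustering of association networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-percolation clustering of association networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(percolink)
```

## The problem

High-dimensional exploratory analyses — phenome-wide multimorbidity screens,
gene co-expression, microbial co-occurrence, topic similarity — end in a
matrix of pairwise association strengths over hundreds or thousands of
variables. Read as an undirected weighted network, the usual next step is to
pick a strength cutoff, keep the edges above it, and interpret the connected
components ("isolated subgraphs") as groups of mutually associated
variables. The cutoff, however, is arbitrary, and every choice hides the
rest of the structure.

percolink sidesteps the single-cutoff choice by computing the *entire*
clustering trajectory: the subgraph structure at every possible cutoff, in
one pass. Because components under a closed threshold are exactly the
connected components of the edges admitted so far, sweeping the threshold
from strongest to weakest is an incremental merge process, which a
disjoint-set forest (union-find) tracks in near-linear time.

## The algorithm

Edges are sorted by decreasing ordering key — the raw strength by default
(`rank_by = "value"`), or its absolute value for signed measures such as
correlations (`rank_by = "abs_value"`). The only assumption placed on the
strength measure is monotonicity: any transformation preserving rank order
yields the same trajectory. Edges are then admitted in order; for each edge
exactly one of four merge events occurs:

* **new_pair** — both endpoints were unclustered: they form a new size-2
  subgraph;
* **absorb** — one endpoint was clustered: the other joins its subgraph;
* **merge** — the endpoints were in different subgraphs: the two merge;
* **intra** — both endpoints already share a subgraph: the partition is
  unchanged, but the subgraph's edge count, density and mean strength are
  updated.

Nodes that no admitted edge has touched are *unclustered* — deliberately
not "clusters of size one". This is where the procedure departs
philosophically from single-linkage clustering: a variable with no
sufficiently strong association is outside the clustering, and statistics
such as the average subgraph size are not diluted by singletons.

The union-find forest uses path compression and union by size, so the sweep
is `O(E α(N))` after an `O(E log E)` sort. It is implemented in C++
(`src/percolate.cpp`) and written from first principles rather than calling
a graph library — which also keeps the test suite honest: the correctness
oracle (breadth-first connected components via igraph) shares no code with
the implementation.

### Ties

Edges with exactly equal ordering keys are admitted as a single step.
Per-edge steps under ties would make intermediate snapshots depend on an
arbitrary processing order; per-distinct-key steps make every snapshot the
component structure of a well-defined edge set, hence invariant to input
row order (a property the suite asserts). Key equality is exact on the
parsed double values — no epsilon — so results do not depend on the
precision a file happens to be written with. Whether the original
interactive implementation steps per edge or per distinct strength under
ties is not something we claim to match byte-for-byte.

### Threshold semantics

A snapshot at cutoff `t` contains exactly the edges with ordering key
`>= t` (closed cutoff). `subgraphs_at(traj, t)` therefore equals
`subgraphs_at_step(traj, k)` for the last step `k` whose threshold is
`>= t`, and a cutoff above the strongest edge returns an empty snapshot
with every node unclustered. Under `rank_by = "abs_value"` the step
threshold is the ordering key (`|strength|`), so the closed-cutoff rule
stays coherent; per-subgraph mean strengths are always computed on raw
strengths.

## Per-step statistics

`tidy()` on a trajectory returns one row per step with the six line-plot
statistics used for threshold selection, plus supporting counts:
`n_subgraphs`, `n_triples` (subgraphs with at least three members),
`avg_size`, `avg_density`, `rel_max_size` and `threshold`, together with
`n_edges`, `max_size` and `n_clustered`. Definitions:

* a subgraph's **density** is `m / (n (n - 1) / 2)` — admitted internal
  edges over the maximum possible among its members; a size-2 subgraph
  always has density 1;
* **avg_density** is the unweighted mean of per-subgraph densities (the
  plain reading of "average density of the subgraphs" — not edge-weighted);
* **rel_max_size** is `max_size / max(1, n_clustered - max_size)`: the size
  of the largest subgraph relative to all other subgraphs combined.

All per-step aggregates are maintained incrementally inside the C++ sweep
(constant work per edge), so the full statistics table for a complete graph
on 1000 nodes (~500,000 steps) takes about a second.

## The smallest–largest optimal threshold

In an Erdos–Renyi random graph the largest component undergoes a sharp
phase transition in the number of admitted edges `e`: for `e < n` the
largest component is of order `log(n)`; around `e = n` it is of order
`n^(2/3)`; for `e > n` a giant component absorbs almost everything (these
are the reference regimes `phase_transition_reference()` reports; the
classical critical window actually sits at `e ≈ n/2`, and the package
reproduces the `e = n` labelling of its source tradition — the
order-of-magnitude bands used in testing are insensitive to the
distinction). Real association networks deviate: informative edges arrive
first and build many moderate, dense subgraphs; only once they are
exhausted do the remaining, essentially random edges glue everything into
a giant component.

The smallest–largest rule exploits that deviation: the optimal cutoff is
*just before the giant component starts to form* — where `rel_max_size`
bottoms out and begins its terminal rise. Three details are deliberate
design choices:

* **Terminal rise, not global minimum.** For a declining-then-rising curve
  the two coincide. But the curve need not be unimodal: early in the
  assembly, transiently *balanced* states (several subgraphs of similar
  size) can produce dips below the value the curve settles at once the
  real structure has assembled. On a three-module planted network, four
  disjoint within-module pairs give `rel_max_size = 2/6 ≈ 0.33`, below the
  `5/10 = 0.5` of the three completed modules — yet nobody would call that
  half-assembled state the point "just before the giant component forms";
  the giant component's onset is the *terminal* rise. The selection
  therefore restricts the curve to its maximal non-decreasing suffix and
  minimises there. A raw global minimum would land mid-assembly on such
  networks (and recovers planted modules in barely half of seeded runs,
  versus always for the terminal-rise form, as the recovery checks
  exercise).
* Steps with fewer than two subgraphs are ineligible — "largest relative
  to the others" is undefined with no others, and the denominator guard
  `max(1, ...)` only exists so the statistic is printable for such rows.
  If no step ever has two subgraphs the selection fails with an
  informative error rather than returning a degenerate answer; if no
  eligible step falls inside the terminal suffix, the search falls back to
  all eligible steps.
* On a plateau of equal minima the *last* (lowest-threshold) step wins:
  "just before the rise" means the most inclusive state before the giant
  component. The raw curve is used — no smoothing — since it is piecewise
  constant between merge events, not noisy in the smoothing sense.

The ratio form `max/(rest)` and the fraction form `max/(max + rest)` are
monotone transforms of each other, so they share the argmin; the choice
between them is cosmetic, and the suite asserts the agreement on random
trajectories.

## Null models and the synthetic generators

`random_complete_network(n, seed)` draws i.i.d. uniform(0,1) strengths on
the complete graph: admitting its edges strongest-first is exactly the
edge-addition view of the Erdos–Renyi process, the naive reference against
which structure is judged. The edge-addition view (rather than node
removal) matches how the trajectory is actually built.
`permute_strengths()` provides the complementary topology-preserving null
for sparse networks. `null_stats_ensemble()` aggregates per-step largest
component summaries over seeded replicates; replicates are aligned by step
index, which with continuous strengths equals the cumulative edge count
almost surely.

`synthetic_modular_network()` emulates the block structure of real
multimorbidity matrices: `k` planted modules of equal size on a complete
graph, within-module strengths `Normal(within_mean, sd)`, between-module
`Normal(between_mean, sd)`. The defaults (10 / 0 / 1) give a
ten-standard-deviation separation — a high-signal regime in which the
smallest–largest optimum recovers the planted partition essentially always,
which is the regime used for the recovery checks. What these generators
do *not* emulate is worth stating: real association matrices have heavy-tailed
and correlated strengths, unequal module sizes, hierarchical and
overlapping structure, and strengths estimated with error from finite
samples. Passing the recovery test shows the machinery finds clean planted
structure; it is not evidence about statistical power on noisy estimates,
which the method deliberately does not model (it consumes strengths, it
does not infer them).

## Numerical and interface choices

* **Matrix ingestion** reads the strictly-upper triangle and rejects
  asymmetry beyond `tolerance` (default `1e-8`) instead of averaging —
  silent averaging hides upstream bugs. Empty, `NA` and `NaN` cells mean
  "no edge", never "strength 0"; zero-strength edges are kept unless
  `drop_zeros = TRUE`.
* **Identifiers** are opaque case-sensitive strings; all orderings use
  C-locale radix sorting, so results do not depend on the session locale.
* **Determinism**: every generator takes an explicit seed and restores the
  RNG state afterwards; edge sorting breaks ties lexicographically by the
  identifier pair; subgraphs are numbered by decreasing size, then by the
  smallest member identifier. Identical inputs give byte-identical outputs.
* **Serialisation**: delimited writers emit the shortest decimal strings
  that parse back to the identical doubles, and the JSON payload is written
  at full precision, so write→read round-trips are bit-exact — a property
  the suite asserts, because re-deriving the statistics from a reloaded
  payload must reproduce them exactly.
* **Degenerate inputs**: an empty network yields a zero-step trajectory,
  exportable and plottable; a single-edge network percolates but has no
  smallest–largest optimum; nodes present in the node set but in no edge
  stay unclustered at every step and survive round-trips through the
  companion node file.

## Problem sizes used in the checks

The bundled verification uses: 200 random networks of up to 40 nodes
(mixed densities, with forced ties) compared per-threshold against an
independent components oracle; 50 replicates of complete 1000-node random
networks for the phase-transition bands (mean largest component below
`10 log n` at `e = n/4`, above `n/2` at `e = 2n`); and 100 seeded runs of
the 3×5 modular generator for recovery at the optimum. These sizes give
stable stochastic bands while keeping a full run comfortably on a laptop
core; the trajectory machinery itself scales to the `~10^3`-node,
`~10^6`-pair matrices the method is aimed at.

## Known limitations

* The tool consumes association strengths; it does not estimate them, and
  no significance is attached to subgraphs (no permutation p-values).
* Directed networks, multi-edges and post-hoc edge insertion are out of
  scope; the trajectory is immutable once built.
* The interactive force-directed front-end of the original visualization
  is replaced by a documented JSON payload (schema in
  `inst/schema/viz-payload.schema.json`) plus a static PDF report; every
  quantity the interactive display shows is derivable from the payload.
* `rel_max_size` is undefined (guarded) when a single subgraph exists;
  trajectories that jump straight to one subgraph have no optimum.
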