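# percolink

Percolation clustering trajectories for association networks.

## What it does, and for whom

Exploratory analyses of high-dimensional data — phenome-wide multimorbidity
screens from electronic health records, gene co-expression panels, microbial
co-occurrence, topic similarity — commonly end in an *association matrix*:
pairwise strengths over hundreds or thousands of variables. Read as a
weighted undirected network, the classical move is to pick a strength cutoff
and interpret the connected components ("isolated subgraphs") above it. The
cutoff is arbitrary, and each choice hides the rest of the structure.

percolink computes the **entire clustering trajectory** instead: admitting
edges in decreasing strength order through a bespoke union-find merge
process, it records the subgraph structure at *every* possible cutoff in one
`O(E log E)` pass (the sweep itself is C++). Nodes untouched by any admitted
edge are treated as **unclustered**, never as singleton clusters. For each
step (distinct strength) it reports the statistics used to read the
trajectory: number of subgraphs, number of triples (≥3 members), average
subgraph size and density (a subgraph's density is `m / (n(n-1)/2)`), and
`rel_max_size` — the size of the largest subgraph relative to all other
subgraphs combined,

```
rel_max_size = max_size / max(1, n_clustered − max_size).
```

Random-graph percolation theory says a giant component forms almost as soon
as the number of admitted edges passes the number of nodes; in structured
networks it forms later, once informative edges are exhausted. The
**smallest–largest rule** places the optimal cutoff just before the giant
component starts to form: the bottom of the terminal rise of
`rel_max_size`. Null-model generators (i.i.d.-uniform complete networks,
strength permutation, planted-module networks) support comparison against
that random baseline.

## Worked example

A five-node network small enough to trace by hand:

```r
library(percolink)

edges <- data.frame(
  a = c("A", "B", "D", "C", "A"),
  b = c("B", "C", "E", "D", "C"),
  strength = c(0.9, 0.8, 0.7, 0.5, 0.4)
)
traj <- percolate(edges)
tidy(traj)
#> # A tibble: 5 × 10
#>   step_index threshold n_edges n_subgraphs n_triples avg_size avg_density max_size n_clustered rel_max_size
#>        <int>     <dbl>   <int>       <int>     <int>    <dbl>       <dbl>    <int>       <int>        <dbl>
#> 1          1       0.9       1           1         0      2         1            2           2          2
#> 2          2       0.8       2           1         1      3         0.667        3           3          3
#> 3          3       0.7       3           2         1      2.5       0.833        3           5          1.5
#> 4          4       0.5       4           1         1      5         0.4          5           5          5
#> 5          5       0.4       5           1         1      5         0.5          5           5          5
```

Reading step 3 (cutoff 0.7): the three admitted edges split the network
into `{A,B,C}` (2 of 3 possible edges, density 0.667) and `{D,E}` (density
1), so 2 subgraphs, 1 triple, average size 2.5, and the largest subgraph is
1.5× the size of everything else clustered. One step later the 0.5 edge
merges everything into a giant component and `rel_max_size` jumps to 5 —
so the smallest–largest optimum sits at 0.7:

```r
optimal_threshold(traj)
#> <optimal_threshold> threshold 0.7 at step 3 (min rel_max_size 1.5 over 1 eligible steps)

subgraphs_at(traj, 0.7)
#> <subgraph_snapshot> threshold 0.7: 2 subgraphs, 5 clustered, 0 unclustered
#> # A tibble: 2 × 5
#>   subgraph  size n_edges density mean_strength
#>      <int> <int>   <int>   <dbl>         <dbl>
#> 1        1     3       2   0.667          0.85
#> 2        2     2       1   1              0.7
```

`autoplot(traj)` draws the trajectory line plots; `export_viz_payload()`
writes nodes, edges, per-step statistics, optimum and any snapshot as a
schema-validated JSON document (schema in `inst/schema/`);
`read_edge_list()` / `read_association_matrix()` / `attach_metadata()`
ingest the delimited formats. A thin command-line wrapper is installed at
`inst/scripts/percolink` (`run`, `optimal`, `snapshot`, `null`,
`generate` subcommands).

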