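# cbci: community-based collective influence for network immunization

Targeted immunization asks which nodes to vaccinate (remove) first so that
an epidemic — of disease, malware, or misinformation — loses its giant
connected component as quickly as possible. Finding the optimal removal set
is NP-hard, so practical work ranks nodes with adaptive heuristics. The
*collective influence* (CI) heuristic scores each node by

```
CI_l(i) = (k_i - 1) * sum_{j in dB(i, l)} (k_j - 1)
```

where `dB(i, l)` is the set of nodes at shortest-path distance exactly `l`
from `i`, removes the top node, rescores, and repeats. CI is derived from
non-backtracking/message-passing stability analysis and assumes the network
is locally tree-like — an assumption that community structure breaks.

This package implements the **community-based collective influence (CbCI)**
strategy: detect communities once, coarse-grain the network into a weighted
supernetwork `Ã` whose link weights count inter-community edges, run a
weighted CI on that supernetwork,

```
CI_l(I) = z_I * sum_{J in dB(I, l)} (s_J - Ã_{J,J-}),    z_I = s_I (1 - 1/kappa_I)
```

(`s_I` = strength, `kappa_I` = number of neighbouring communities, `J-` =
BFS predecessor of `J`), and allocate each community's score to its member
nodes in proportion to their inter-community degree:

```
CbCI(i) = (k_i^out / s_I) * CI_l(I).
```

Removal is adaptive (largest CbCI, ties by degree, then at random), stops
once the largest connected component (LCC) holds at most 1% of the nodes,
and is refined by greedy reinsertion that prefers nodes joining the fewest
communities. With a singleton partition CbCI collapses *exactly* to CI.

The package is aimed at network scientists and epidemic modellers. It also
ships the standard comparators (adaptive degree, adaptive betweenness,
community-based dynamical importance, Laplacian spectral partitioning),
percolation-style evaluation (`G(q)` curves, the critical fraction `q_c`,
the integrated LCC size `F ∈ [0, 1/2]`), partition diagnostics (entropy,
modularity, clustering), and synthetic generators with ground-truth
communities.

## Worked example

Generate a scale-free network with 20 planted communities of 50 nodes,
then compare CI and CbCI (ground-truth partition, `l = 2`, reinsertion on):

```r
library(cbci)

gen  <- community_sf_network(n_communities = 20, seed = 101)
g    <- preprocess_network(gen$graph)            # largest component
keep <- match(igraph::V(g)$name, igraph::V(gen$graph)$name)
truth <- node_partition(gen$partition$membership[keep])

s_ci   <- immunize(g, "ci",   ell = 2, seed = 1)
s_cbci <- immunize(g, "cbci", partition = truth, ell = 2, seed = 1)

compare_strategies(g, list(ci = s_ci, cbci = s_cbci),
                   theta = 0.05, reference = "ci")
#>   strategy   q_c        F q_c_ratio   F_ratio
#> 1       ci 0.388 0.244225 1.0000000 1.0000000
#> 2     cbci 0.267 0.146031 0.6881443 0.5979363
```

CbCI fragments this network (LCC down to 5% of nodes) after removing 26.7%
of the nodes where CI needs 38.8% — a ratio of 0.69 — and its integrated
LCC size is 40% smaller: exactly the regime community-aware targeting is
built for. `removal_curve()` gives the full `G(q)` trace and
`plot()` draws it; `partition_entropy(truth)` returns 2.996 (normalized 1.0,
an equal-size partition — the setting where CbCI is most effective).

The same analysis runs from a shell:

```sh
Rscript inst/cli/synthnet.R --model community --seed 1 --out net
Rscript inst/cli/immunize.R --edges net.edg --partition net_partition.tsv \
    --strategies ci,cbci --ell 2 --seed 1 --out results/run
```

which writes per-strategy schedules, `G(q)` curve CSVs, summary JSON, a
comparison table and a replayable manifest.

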