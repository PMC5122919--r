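---
title: "Community-based collective influence: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community-based collective influence: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbci)
```

## The problem

Immunization-by-removal treats a contact network as the substrate of an
epidemic and asks for a removal order of nodes that destroys the giant
connected component as early as possible. Performance is read off the
percolation curve $G(q)$ — the size of the largest connected component
(LCC) divided by $N$, after a fraction $q$ of nodes has been removed —
through two scalars: the critical fraction
$q_c = \min\{q : G(q) \le \theta\}$ (we use $\theta = 0.05$), and the
integrated size $F = \frac{1}{N}\sum_{n=1}^{N} G_{n}$, the area under
$G(q)$, which lies in $[0, \tfrac12]$ because
$G_n \le \min(1, (N-n)/N)$. Smaller is better for both.

## Collective influence and its community-based variant

The collective influence of node $i$ at radius $\ell$ is
$\mathrm{CI}_\ell(i) = (k_i-1) \sum_{j \in \partial B(i,\ell)} (k_j-1)$,
with $\partial B(i,\ell)$ the set of nodes at distance exactly $\ell$.
The adaptive CI strategy removes an argmax, rescores everything on the
residual graph, and repeats until the LCC first holds at most
$0.01\,N$ nodes; a greedy reinsertion pass then reorders the removals
(the node reconnecting the fewest components goes back first; the final
order is the reverse of the reinsertion sequence). CI's derivation
assumes a locally tree-like graph, which clustering and community
structure violate.

CbCI moves the CI computation to the mesoscopic scale. A partition, found
once on the intact graph and frozen thereafter, induces a coarse-grained
weighted network $\tilde A$ whose $(I, J)$ entry counts the edges between
communities $I$ and $J$ (diagonal zero). On this supernetwork:

* the root factor $z_I = s_I(1 - 1/\kappa_I)$ plays the role of
  $k_i - 1$: it vanishes when community $I$ has a single neighbour and
  reduces to $\kappa_I - 1$ on unit weights ($s_I$ = strength,
  $\kappa_I$ = number of neighbouring communities);
* a frontier community $J$, reached from $I$ through predecessor $J^-$,
  contributes $s_J - \tilde A_{J,J^-}$ — its outgoing strength excluding
  the link it was arrived by, the non-backtracking analogue of $k_j-1$;
* $\mathrm{CI}_\ell(I) = z_I \sum_{J\in\partial B(I,\ell)}
  (s_J - \tilde A_{J,J^-})$, with $\mathrm{CI}_0(I) := z_I$;
* each node inherits
  $\mathrm{CbCI}(i) = (k_i^{\mathrm{out}}/s_I)\,\mathrm{CI}_\ell(I)$,
  where $k_i^{\mathrm{out}}$ counts its surviving inter-community edges.

Removal is adaptive with the coarse graph recomputed on the residual
network each step (labels frozen); ties go to the larger residual degree,
then to a seeded uniform draw. Reinsertion is community-aware: the
candidate whose restored component would span the fewest distinct
communities returns first. When every community is a single node all of
this collapses to plain CI — the package tests assert that reduction
*exactly*, not approximately.

## Reconstructed forms

Several defining expressions of this family of scores admit minor
variants; the package pins one form per quantity, isolates each in a
single function, and exposes switches where reasonable:

* **Root factor** $z_I = s_I(1-1/\kappa_I)$, computed as
  $s_I - s_I/\kappa_I$. The subtraction form is exact in floating point
  whenever $s_I = \kappa_I$, which is what makes the singleton-partition
  equality with CI bit-exact. The alternative
  $s_I - \max_J \tilde A_{IJ}$ would satisfy the same limiting
  constraints; it is not used.
* **Predecessor convention.** On a tree the predecessor $J^-$ is unique;
  coarse graphs are not trees, so when several shortest paths exist the
  smallest-id predecessor is used (deterministic). A summation-over-
  predecessors variant is available via `predecessor = "sum"` in
  `community_ci()` and `cbci_schedule()`.
* **CbDI.** The community-based dynamical importance of node $i$ is
  pinned to $\tilde v_I \sum_{J \ne I} k_{iJ} \tilde v_J$ with
  $\tilde v$ the leading eigenvector of $\tilde A$ (non-negative by
  Perron–Frobenius; computed on the largest coarse component, zero
  elsewhere). Ranks are invariant to the eigenvector normalization.
* **LSP objective.** The bipartition score maximized over the Fiedler
  threshold cuts defaults to the two-group modularity
  $m_{\mathrm{in}}/M - (K_1^2+K_2^2)/(4M^2)$; `lsp_score_variants`
  registers alternates and `lsp_schedule(variant = ...)` accepts any
  function of $(m_{\mathrm{in}}, m_{\mathrm{out}}, K_1, K_2, M)$.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `ell` | ball radius (CI and coarse CbCI) | 2 | contributions from communities three or more hops away are ignored; configurable |
| `stop_frac` | LCC fraction that stops targeted removal | 0.01 | the conventional dismantling endpoint; the rest of the order only pads $G(q)$ |
| `theta` | fragmentation threshold defining $q_c$ | 0.05 | evaluation-side only; independent of `stop_frac` |
| LSP `theta` | final LCC fraction of the LSP loop | 0.01 | the LSP procedure's own stopping rule |
| `seed` | tie-break RNG | none | every stochastic choice is seed-addressable; `immunize()` derives schedule and reinsertion sub-seeds from one seed |

## Numerical and procedural choices

* **Tie-breaking is shared across strategies**: largest score, then the
  secondary key (residual degree for CI/CbCI/degree; intra-community
  links for CbDI), then one seeded uniform draw. Aligning CI's rule with
  CbCI's is a deliberate choice — the original CI prescription does not
  specify ties — and it is what lets the singleton-partition equivalence
  extend from scores to whole schedules.
* **Degenerate residual states.** $\mathrm{CI}_0$ of an isolated node is
  $k-1 = -1$ while its CbCI is 0; the degree tie-break makes both
  strategies still pick the same node, so the equivalence survives.
* **The tail.** Targeted removal stops at `stop_frac`; to define $G(q)$
  up to $q = 1$ the remaining nodes are appended by adaptive
  maximum-degree removal. The tail only affects the (tiny) terminal
  portion of the curve and is shared by every strategy.
* **CbCI fallback.** Once the coarse graph has no edges every CbCI score
  is zero and the schedule falls back to adaptive degree until the
  stopping point; the run records this in `params$fallback`. (The
  original prescription defines a second phase only for CbDI; for CbCI
  this choice is the package's own.)
* **Removal is a mask, never a mutation**: every step operates on the
  source adjacency plus an alive vector, so schedules replay exactly.
* **Curves by union-find.** $G(q)$ is computed by adding nodes back in
  reverse with a union-find; tests assert equality with naive per-step
  component recomputation.
* **LSP numerics.** The Fiedler vector comes from a dense symmetric
  eigendecomposition of the current LCC's Laplacian with the sign fixed
  (first non-zero entry positive); cuts between tied Fiedler values are
  skipped; components of $\le 2$ nodes count as fragmented. If every
  entry ties (no admissible cut) the loop peels one maximum-degree node
  to guarantee progress.
* **Clustering conventions.** Nodes (supernodes) with fewer than two
  neighbours contribute 0 to the mean (weighted) clustering coefficient
  rather than being excluded; the weighted form is the strength-
  normalized (Barrat-style) variant, over ordered neighbour pairs so
  unit weights reduce to the unweighted coefficient.
* **Entropy** uses the natural log; the normalized form
  $H/\ln N_C$ is base-free and set to 1 for $N_C = 1$.

## What the generators emulate

`ba_network()` is explicit preferential attachment: an $m_0$-clique seed,
$m$ distinct degree-proportional targets per new node (re-drawn until
distinct), hence exactly $m_0(m_0-1)/2 + (N-m_0)m$ edges.
`community_sf_network()` plants communities: a coarse BA topology
($N_C$ communities, $m_0 = m = 3$), an independent BA graph
($m_0 = m = 4$) inside each community of 50 nodes, and independent
cross links with probability $\langle k\rangle_g/(6N/N_C)$ per pair of
nodes in adjacent communities, giving each node about
$\langle k\rangle_g = 1$ inter-community neighbours at the defaults
($N_C = 100$, $N = 5000$). The literal constant 6 is the default coarse
mean degree; `literal_rate = FALSE` generalizes it to $2m$.

What the model does *not* emulate: degree–community correlations,
overlapping or nested communities, clustering beyond what BA produces,
and heterogeneous community sizes (the planted partition has maximal
entropy). Passing tests on this model therefore demonstrate correct
mechanics and the expected ordering of strategies *when communities are
egalitarian and well separated* — not performance on any particular
empirical network, where detected (not planted) partitions and skewed
community sizes change the picture.

## Problem sizes in the test suite

The suite checks the CbCI-beats-CI ordering on the community model at 20
communities of 50 nodes (N = 1000) over five seeds with full pipelines
(schedules plus reinsertion), and the generator statistics at the default
N = 5000. Oracle comparisons run on graphs of up to 60 nodes, where
brute-force recomputation (explicit BFS, path counting, exhaustive
bipartition scans) is itself trustworthy. These sizes were chosen so the
whole suite completes in about a minute while each claim is still
exercised at a scale where it could fail.

## Known limitations

* Scoring is full recomputation per step ($O(N^2\log N)$-style overall);
  the max-heap/incremental-update acceleration is not implemented. The
  compiled primitives keep N in the low tens of thousands practical.
* `betweenness_schedule()` recomputes exact betweenness each step and is
  only usable on small networks — the same reason it is usually excluded
  from large-scale comparisons.
* The LSP eigensolver is dense; very large LCCs would need a sparse
  Lanczos backend.
* The partition is never updated during removal (online re-partitioning
  is deliberately out of scope), and simulated-annealing modularity
  maximization is a recognised but unimplemented detection method.
* `community_sf_network()` can return a disconnected graph for small
  `k_inter`; callers are expected to `preprocess_network()` first, as
  `run_experiment()` does.
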