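#' Root factor of a community in the coarse-grained network
#'
#' Weighted analogue of \eqn{k_i - 1} for a supernode:
#' \deqn{z_I = s_I (1 - 1/\kappa_I),}
#' where \eqn{s_I} is the strength (summed link weight) of community
#' \eqn{I} and \eqn{\kappa_I} its number of neighbouring communities. The
#' factor is 0 when \eqn{I} has at most one neighbour, and reduces to
#' \eqn{\kappa_I - 1} on unit weights, so the community-level collective
#' influence inherits both limiting behaviours of the node-level score.
#'
#' @param cg A `coarse_graph` (see [coarse_grain()]).
#' @param I Community id (1-based), or missing for the full vector.
#' @return Numeric root factor(s).
#' @export
root_factor <- function(cg, I) {
  stopifnot(inherits(cg, "coarse_graph"))
  # s - s/kappa rather than s * (1 - 1/kappa): algebraically identical but
  # exact in floating point whenever s == kappa (unit weights), which is
  # what makes the singleton-partition reduction to CI exact.
  z <- ifelse(cg$n_neighbors >= 1L, cg$strength - cg$strength / cg$n_neighbors, 0)
  if (missing(I)) z else z[I]
}

#' Frontier factor of a community reached along a coarse BFS path
#'
#' Non-backtracking analogue of \eqn{k_j - 1} on the weighted coarse graph:
#' for a frontier community \eqn{J} reached from the root through its
#' predecessor \eqn{J^-},
#' \deqn{s_J - \tilde A_{J, J^-},}
#' i.e. the outgoing strength of \eqn{J} excluding the link it was arrived
#' by. Zero when \eqn{J^-} is the only neighbour of \eqn{J}; equal to
#' \eqn{\kappa_J - 1} on unit weights.
#'
#' @param cg A `coarse_graph`.
#' @param J Frontier community id.
#' @param J_minus Predecessor community id; must be adjacent to `J`.
#' @return Numeric factor.
#' @export
frontier_factor <- function(cg, J, J_minus) {
  stopifnot(inherits(cg, "coarse_graph"))
  if (cg$weights[J, J_minus] <= 0) {
    stop("communities ", J, " and ", J_minus, " are not adjacent",
         call. = FALSE)
  }
  cg$strength[J] - cg$weights[J, J_minus]
}

#' Collective influence of a community in the coarse-grained network
#'
#' \deqn{\mathrm{CI}_\ell(I) = z_I \sum_{J \in \partial B(I,\ell)}
#'   \left( s_J - \tilde A_{J, J^-} \right),}
#' where the ball frontier \eqn{\partial B(I,\ell)} uses unweighted
#' shortest-path distance on the coarse graph and \eqn{J^-} is the
#' predecessor of \eqn{J} on a BFS path from \eqn{I}. When several shortest
#' paths exist the smallest-id predecessor is used
#' (`predecessor = "min"`); `predecessor = "sum"` instead sums the factor
#' over all predecessors. For \eqn{\ell = 0} the score is defined as
#' \eqn{z_I}, so it grows with the community's coarse degree.
#'
#' When every community holds a single node this equals [ci_score()] on the
#' original graph, for every radius.
#'
#' @param cg A `coarse_graph`.
#' @param I Community id.
#' @param ell Non-negative radius on the coarse graph (default 2).
#' @param predecessor `"min"` (default) or `"sum"`.
#' @return Numeric score.
#' @export
community_ci <- function(cg, I, ell = 2, predecessor = c("min", "sum")) {
  community_ci_values(cg, ell, match.arg(predecessor))[I]
}

# CI_ell for every community; plain R BFS, the coarse graph is small.
community_ci_values <- function(cg, ell, predecessor = "min") {
  W <- cg$weights
  nc <- cg$n_comm
  z <- root_factor(cg)
  if (ell == 0) return(z)
  nbrs <- lapply(seq_len(nc), function(I) which(W[I, ] > 0))
  out <- numeric(nc)
  for (I in seq_len(nc)) {
    if (z[I] == 0) next
    dist <- rep(-1L, nc)
    dist[I] <- 0L
    cur <- I
    d <- 0L
    while (d < ell && length(cur) > 0L) {
      nxt <- unique(unlist(nbrs[cur], use.names = FALSE))
      nxt <- nxt[dist[nxt] < 0L]
      dist[nxt] <- d + 1L
      cur <- nxt
      d <- d + 1L
    }
    if (d < ell || length(cur) == 0L) next
    acc <- 0
    for (J in cur) {
      preds <- nbrs[[J]][dist[nbrs[[J]]] == ell - 1L]
      acc <- acc + if (predecessor == "min") {
        cg$strength[J] - W[J, min(preds)]
      } else {
        sum(cg$strength[J] - W[J, preds])
      }
    }
    out[I] <- z[I] * acc
  }
  out
}

#' Community-based collective influence of a node
#'
#' The community-level score [community_ci()] of node `i`'s community
#' \eqn{I} is allocated to its members in proportion to their
#' inter-community degree:
#' \deqn{\mathrm{CbCI}(i) = \frac{k_i^{\mathrm{out}}}{s_I}\,
#'   \mathrm{CI}_\ell(I),}
#' where \eqn{k_i^{\mathrm{out}}} counts the surviving edges from `i` to
#' nodes outside \eqn{I}. Nodes in a community with no surviving
#' inter-community links (\eqn{s_I = 0}) score 0. The score is therefore
#' large when (a) the community has many inter-community links, (b) it sees
#' high-strength communities at distance \eqn{\ell} in the coarse graph, and
#' (c) the node carries a large share of its community's outgoing links.
#'
#' With a singleton partition (every node its own community)
#' \eqn{\mathrm{CbCI}(i) = \mathrm{CI}_\ell(i)} exactly.
#'
#' @param g An undirected simple igraph graph.
#' @param partition A [node_partition()] covering all nodes.
#' @param i Focal node (internal index or vertex name).
#' @param ell Coarse ball radius (default 2).
#' @param removed Removed nodes.
#' @param cg Optional precomputed `coarse_graph` for the same residual
#'   state (recomputed when `NULL`).
#' @param predecessor Predecessor convention, see [community_ci()].
#' @return Numeric score for `cbci_score`; a vector over all nodes for
#'   `cbci_scores`, `NA` at removed nodes.
#' @export
cbci_score <- function(g, partition, i, ell = 2, removed = integer(),
                       cg = NULL, predecessor = "min") {
  i <- resolve_vids(g, i)
  stopifnot(length(i) == 1L)
  cbci_scores(g, partition, ell, removed, cg, predecessor)[i]
}

#' @rdname cbci_score
#' @export
cbci_scores <- function(g, partition, ell = 2, removed = integer(),
                        cg = NULL, predecessor = "min") {
  check_graph(g)
  check_partition(g, partition)
  adj <- graph_adjlist(g)
  alive <- alive_mask(length(adj), resolve_vids(g, removed))
  if (is.null(cg)) {
    cg <- new_coarse_graph(
      cpp_coarse_counts(adj, alive, partition$membership, partition$n_comm))
  }
  sc <- cbci_scores_fast(adj, alive, partition$membership, cg, ell, predecessor)
  names(sc) <- graph_labels(g)
  sc
}

cbci_scores_fast <- function(adj, alive, memb, cg, ell, predecessor = "min") {
  cic <- community_ci_values(cg, ell, predecessor)
  kout <- cpp_cross_degrees(adj, alive, memb)$kout
  s_of <- cg$strength[memb]
  sc <- numeric(length(adj))
  pos <- s_of > 0
  sc[pos] <- kout[pos] / s_of[pos] * cic[memb][pos]
  sc[!alive] <- NA_real_
  sc
}

#' Adaptive CbCI removal schedule
#'
#' At every step the coarse graph is recomputed on the residual network
#' (community labels stay frozen), all CbCI scores are recomputed, and the
#' node with the largest score is removed. Ties are broken by largest
#' residual degree, then uniformly at random under `seed`. Removal stops
#' once the largest connected component holds at most `stop_frac * N`
#' nodes. If the coarse graph runs out of edges first (all communities
#' mutually disconnected), the remaining removals up to the stopping point
#' fall back to adaptive maximum-degree targeting. A degree-adaptive tail
#' is appended afterwards as in [ci_schedule()].
#'
#' Refine the result with [community_reinsert()].
#'
#' @param g A connected, undirected, simple igraph graph.
#' @param partition A [node_partition()] computed once on the intact graph.
#' @param ell Coarse ball radius (default 2).
#' @param stop_frac Stopping fraction for the LCC (default 0.01).
#' @param seed Tie-break seed.
#' @param predecessor Predecessor convention, see [community_ci()].
#' @return A [new_schedule()] object.
#' @export
cbci_schedule <- function(g, partition, ell = 2, stop_frac = 0.01,
                          seed = NULL, predecessor = "min") {
  check_graph(g)
  check_partition(g, partition)
  stopifnot(ell >= 0, stop_frac > 0, stop_frac < 1)
  adj <- graph_adjlist(g)
  n <- length(adj)
  memb <- partition$membership
  nc <- partition$n_comm
  thresh <- stop_frac * n
  with_seed(seed, {
    alive <- rep(TRUE, n)
    ord <- integer(n)
    k <- 0L
    fellback <- FALSE
    while (any(alive) && cpp_lcc_size(adj, alive) > thresh) {
      W <- cpp_coarse_counts(adj, alive, memb, nc)
      if (sum(W) == 0) {
        fb <- remove_by_degree(adj, alive, thresh)
        if (length(fb$order) > 0L) {
          ord[(k + 1L):(k + length(fb$order))] <- fb$order
          k <- k + length(fb$order)
        }
        alive <- fb$alive
        fellback <- TRUE
        break
      }
      cg <- new_coarse_graph(W)
      sc <- cbci_scores_fast(adj, alive, memb, cg, ell, predecessor)
      deg <- cpp_residual_degree(adj, alive)
      v <- pick_target(sc, deg, alive)
      k <- k + 1L
      ord[k] <- v
      alive[v] <- FALSE
    }
    nt <- k
    if (any(alive)) ord[(k + 1L):n] <- degree_tail(adj, alive)
    new_schedule(ord, nt, "cbci",
                 params = list(ell = ell, stop_frac = stop_frac,
                               partition = partition$method,
                               predecessor = predecessor,
                               fallback = fellback),
                 seed = seed, labels = graph_labels(g))
  })
}

#' Greedy community-count reinsertion
#'
#' Community-aware variant of [reinsert()]: each still-removed candidate is
#' scored by the number of distinct communities that would share its
#' component after reinsertion (its own community plus all communities
#' represented in the alive components adjacent to it), and the candidate
#' connecting the fewest communities is added back first. Ties are broken
#' at random under `seed`; the final removal order is the reverse of the
#' reinsertion sequence.
#'
#' @inheritParams reinsert
#' @param partition The frozen [node_partition()] used by the schedule.
#' @return A new `removal_schedule`.
#' @export
community_reinsert <- function(g, partition, schedule, seed = NULL) {
  check_partition(g, partition)
  memb <- partition$membership
  # Per iteration, the set of community labels present in each alive
  # component; candidates then just union a handful of small sets.
  prep <- function(alive, comp) {
    lapply(split(memb[alive], comp[alive]), unique)
  }
  counter <- function(r, adj, alive, comp, ctx) {
    nb <- adj[[r]]
    nb <- nb[alive[nb]]
    comps <- unique(comp[nb])
    if (length(comps) == 0L) return(1)
    labs <- unlist(ctx[as.character(comps)], use.names = FALSE)
    length(unique(c(memb[r], labs)))
  }
  reinsert_engine(g, schedule, counter, seed, tag = "community_count",
                  prep = prep)
}
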