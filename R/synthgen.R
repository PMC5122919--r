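#' Barabasi-Albert scale-free network
#'
#' Preferential attachment with an explicit construction: the initial
#' network is the complete graph on `m0` nodes; each subsequently added
#' node attaches `m` edges to distinct existing nodes, drawn with
#' probability proportional to their current degree (candidates are
#' re-drawn until `m` distinct targets are found). The result is a simple
#' graph with exactly `m0*(m0-1)/2 + (n-m0)*m` edges and a degree
#' distribution with tail exponent near 3 for large `n`.
#'
#' @param n Total number of nodes (`n = m0` returns the initial clique).
#' @param m0 Size of the initial clique (default 3).
#' @param m Edges added per new node; requires `m <= m0` (default `m0`).
#' @param seed RNG seed.
#' @return An undirected simple igraph graph with vertex names `"1".."n"`.
#' @export
ba_network <- function(n, m0 = 3, m = m0, seed = NULL) {
  stopifnot(n >= m0, m0 >= 1, m >= 1, m <= m0)
  n_edges <- m0 * (m0 - 1) / 2 + (n - m0) * m
  with_seed(seed, {
    ends_a <- integer(n_edges)
    ends_b <- integer(n_edges)
    e <- 0L
    if (m0 > 1L) {
      for (i in seq_len(m0 - 1L)) {
        for (j in seq.int(i + 1L, m0)) {
          e <- e + 1L
          ends_a[e] <- i
          ends_b[e] <- j
        }
      }
    }
    # flat multiset of edge endpoints: sampling it uniformly is sampling
    # nodes proportionally to degree
    stubs <- integer(2L * n_edges)
    stubs[seq_len(2L * e)] <- c(ends_a[seq_len(e)], ends_b[seq_len(e)])
    n_stubs <- 2L * e
    if (n > m0) {
      for (v in seq.int(m0 + 1L, n)) {
        chosen <- integer(m)
        got <- 0L
        while (got < m) {
          cand <- stubs[sample.int(n_stubs, 1L)]
          if (!cand %in% chosen[seq_len(got)]) {
            got <- got + 1L
            chosen[got] <- cand
          }
        }
        for (t in chosen) {
          e <- e + 1L
          ends_a[e] <- v
          ends_b[e] <- t
          stubs[n_stubs + 1L] <- v
          stubs[n_stubs + 2L] <- t
          n_stubs <- n_stubs + 2L
        }
      }
    }
    graph_from_pairs(ends_a, ends_b)
  })
}

#' Scale-free network with built-in community structure
#'
#' Three-stage construction with a known ground-truth partition:
#' \enumerate{
#'   \item a coarse community topology from [ba_network()] with
#'     `n_communities` nodes and `m0 = m = coarse_m` (mean coarse degree
#'     `2 * coarse_m`);
#'   \item inside each community, an independent [ba_network()] on
#'     `nodes_per_community` nodes with `m0 = m = intra_m`;
#'   \item for every pair of adjacent communities \eqn{(I, J)}, each cross
#'     pair \eqn{(i \in I, j \in J)} is linked independently with
#'     probability \eqn{p = \langle k \rangle_g / (6 N / N_C)}, so a node
#'     gains on average about \eqn{\langle k \rangle_g} inter-community
#'     neighbours (`k_inter`, default 1).
#' }
#' The constant 6 in \eqn{p} is the mean coarse degree at the default
#' `coarse_m = 3`; set `literal_rate = FALSE` to generalize it to
#' `2 * coarse_m` for other coarse densities.
#'
#' The generated graph can be (mildly) disconnected for small `k_inter`;
#' dismantling experiments preprocess it to its largest component.
#'
#' @param n_communities Number of communities \eqn{N_C} (default 100).
#' @param nodes_per_community Nodes per community (default 50), giving
#'   \eqn{N = 50 N_C = 5000} at the defaults.
#' @param coarse_m BA parameter of the coarse topology (default 3).
#' @param intra_m BA parameter of the intra-community networks (default 4).
#' @param k_inter Mean number of inter-community neighbours per node
#'   (default 1).
#' @param seed RNG seed.
#' @param literal_rate Keep the literal constant 6 in the cross-link
#'   probability (default `TRUE`).
#' @return List with elements `graph` (igraph) and `partition`
#'   (ground-truth [node_partition()]).
#' @export
community_sf_network <- function(n_communities = 100,
                                 nodes_per_community = 50,
                                 coarse_m = 3, intra_m = 4, k_inter = 1,
                                 seed = NULL, literal_rate = TRUE) {
  stopifnot(n_communities >= 1, nodes_per_community > intra_m,
            coarse_m >= 1, intra_m >= 1, k_inter >= 0)
  denom <- if (literal_rate) 6 else 2 * coarse_m
  p <- k_inter / (denom * nodes_per_community)
  stopifnot(p <= 1)
  with_seed(seed, {
    coarse <- if (n_communities >= coarse_m) {
      ba_network(n_communities, coarse_m, coarse_m)
    } else {
      igraph::make_full_graph(n_communities)
    }
    npc <- nodes_per_community
    n <- n_communities * npc
    ea <- list(); eb <- list()
    for (I in seq_len(n_communities)) {
      gi <- ba_network(npc, intra_m, intra_m)
      el <- igraph::as_edgelist(gi, names = FALSE)
      off <- (I - 1L) * npc
      ea[[I]] <- el[, 1] + off
      eb[[I]] <- el[, 2] + off
    }
    cel <- igraph::as_edgelist(coarse, names = FALSE)
    if (nrow(cel) > 0L && p > 0) {
      for (r in seq_len(nrow(cel))) {
        I <- cel[r, 1]; J <- cel[r, 2]
        hit <- which(stats::runif(npc * npc) < p)
        if (length(hit) > 0L) {
          i <- (I - 1L) * npc + ((hit - 1L) %% npc) + 1L
          j <- (J - 1L) * npc + ((hit - 1L) %/% npc) + 1L
          ea[[length(ea) + 1L]] <- i
          eb[[length(eb) + 1L]] <- j
        }
      }
    }
    a <- unlist(ea, use.names = FALSE)
    b <- unlist(eb, use.names = FALSE)
    # isolated nodes cannot appear: every node has intra-community edges
    g <- graph_from_pairs(a, b)
    memb <- rep(seq_len(n_communities), each = npc)
    list(graph = g,
         partition = node_partition(memb, method = "ground_truth"))
  })
}
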