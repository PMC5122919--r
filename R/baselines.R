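#' Adaptive high-degree removal schedule
#'
#' Sequentially removes a node of maximal residual degree (recomputed after
#' every removal; ties broken at random under `seed`) until the largest
#' connected component holds at most `stop_frac * N` nodes, then appends
#' the remaining nodes the same way.
#'
#' @param g A connected, undirected, simple igraph graph.
#' @param stop_frac Stopping fraction for the LCC (default 0.01).
#' @param seed Tie-break seed.
#' @return A [new_schedule()] object.
#' @export
degree_schedule <- function(g, stop_frac = 0.01, seed = NULL) {
  check_graph(g)
  stopifnot(stop_frac > 0, stop_frac < 1)
  adj <- graph_adjlist(g)
  n <- length(adj)
  with_seed(seed, {
    res <- remove_by_degree(adj, rep(TRUE, n), stop_frac * n)
    nt <- length(res$order)
    ord <- c(res$order, if (any(res$alive)) degree_tail(adj, res$alive))
    new_schedule(ord, nt, "degree", params = list(stop_frac = stop_frac),
                 seed = seed, labels = graph_labels(g))
  })
}

#' Adaptive high-betweenness removal schedule
#'
#' Removes the node with the largest betweenness centrality, recomputed on
#' the residual graph after every removal; ties are broken by largest
#' residual degree, then at random under `seed`. Betweenness costs
#' \eqn{O(NM)} per step, so this strategy is only practical on small
#' networks.
#'
#' @inheritParams degree_schedule
#' @return A [new_schedule()] object.
#' @export
betweenness_schedule <- function(g, stop_frac = 0.01, seed = NULL) {
  check_graph(g)
  stopifnot(stop_frac > 0, stop_frac < 1)
  adj <- graph_adjlist(g)
  n <- length(adj)
  thresh <- stop_frac * n
  with_seed(seed, {
    alive <- rep(TRUE, n)
    ord <- integer(n)
    k <- 0L
    while (any(alive) && cpp_lcc_size(adj, alive) > thresh) {
      idx <- which(alive)
      sub <- igraph::induced_subgraph(g, idx)
      bc <- numeric(n)
      bc[idx] <- igraph::betweenness(sub, directed = FALSE)
      deg <- cpp_residual_degree(adj, alive)
      v <- pick_target(bc, deg, alive)
      k <- k + 1L
      ord[k] <- v
      alive[v] <- FALSE
    }
    nt <- k
    if (any(alive)) ord[(k + 1L):n] <- degree_tail(adj, alive)
    new_schedule(ord, nt, "betweenness",
                 params = list(stop_frac = stop_frac),
                 seed = seed, labels = graph_labels(g))
  })
}

# Leading (Perron) eigenvector of the coarse weight matrix, computed on the
# largest connected coarse component; entries outside it are zero.
perron_vector <- function(W) {
  nc <- nrow(W)
  v <- numeric(nc)
  if (sum(W) == 0) return(v)
  # components of the coarse topology
  nbrs <- lapply(seq_len(nc), function(I) which(W[I, ] > 0))
  comp <- integer(nc)
  c_id <- 0L
  for (I in seq_len(nc)) {
    if (comp[I] != 0L || length(nbrs[[I]]) == 0L) next
    c_id <- c_id + 1L
    queue <- I
    comp[I] <- c_id
    while (length(queue) > 0L) {
      v0 <- queue[[1]]
      queue <- queue[-1]
      for (u in nbrs[[v0]]) if (comp[u] == 0L) { comp[u] <- c_id; queue <- c(queue, u) }
    }
  }
  sizes <- tabulate(comp[comp > 0L])
  big <- which(comp == which.max(sizes))
  e <- eigen(W[big, big, drop = FALSE], symmetric = TRUE)
  v1 <- e$vectors[, 1]
  if (sum(v1) < 0) v1 <- -v1
  v1[v1 < 0] <- 0  # numerical guard; the Perron vector is non-negative
  v[big] <- v1
  v
}

#' Community-based dynamical importance of a node
#'
#' Let \eqn{\tilde v} be the leading eigenvector of the coarse weight
#' matrix \eqn{\tilde A} (non-negative by Perron-Frobenius; computed on the
#' largest coarse component, zero elsewhere) and
#' \eqn{k_{iJ}} the number of surviving links between node \eqn{i} and
#' community \eqn{J}. Then
#' \deqn{\mathrm{CbDI}(i) = \tilde v_I \sum_{J \neq I} k_{iJ} \tilde v_J,}
#' the aggregated eigenvalue sensitivity (dynamical importance) of the
#' coarse links that node `i` carries. Nodes with no inter-community links
#' score 0. Ranks are invariant to the eigenvector's normalization.
#'
#' @inheritParams cbci_score
#' @return Numeric score(s); `NA` at removed nodes for `cbdi_scores`.
#' @export
cbdi_score <- function(g, partition, i, removed = integer()) {
  i <- resolve_vids(g, i)
  stopifnot(length(i) == 1L)
  cbdi_scores(g, partition, removed)[i]
}

#' @rdname cbdi_score
#' @export
cbdi_scores <- function(g, partition, removed = integer()) {
  check_graph(g)
  check_partition(g, partition)
  adj <- graph_adjlist(g)
  alive <- alive_mask(length(adj), resolve_vids(g, removed))
  memb <- partition$membership
  nc <- partition$n_comm
  W <- cpp_coarse_counts(adj, alive, memb, nc)
  sc <- cbdi_scores_fast(adj, alive, memb, nc, W)
  names(sc) <- graph_labels(g)
  sc
}

cbdi_scores_fast <- function(adj, alive, memb, nc, W) {
  v <- perron_vector(W)
  kiJ <- cpp_community_degree(adj, alive, memb, nc)
  n <- length(adj)
  proj <- as.numeric(kiJ %*% v)
  intra <- kiJ[cbind(seq_len(n), memb)]
  sc <- v[memb] * (proj - intra * v[memb])
  sc[!alive] <- NA_real_
  sc
}

#' Two-phase adaptive CbDI removal schedule
#'
#' Phase 1 removes nodes in descending order of [cbdi_score()]
#' (recomputed each step; ties broken by the largest number of
#' intra-community links, then at random). Once the residual coarse graph
#' has no edges left (all communities mutually disconnected), phase 2
#' removes nodes in descending order of their intra-community degree
#' \eqn{k_{iI}}, also recomputed adaptively. Removal stops when the LCC
#' holds at most `stop_frac * N` nodes; a degree-adaptive tail follows.
#'
#' @inheritParams cbci_schedule
#' @return A [new_schedule()] object.
#' @export
cbdi_schedule <- function(g, partition, stop_frac = 0.01, seed = NULL) {
  check_graph(g)
  check_partition(g, partition)
  stopifnot(stop_frac > 0, stop_frac < 1)
  adj <- graph_adjlist(g)
  n <- length(adj)
  memb <- partition$membership
  nc <- partition$n_comm
  thresh <- stop_frac * n
  with_seed(seed, {
    alive <- rep(TRUE, n)
    ord <- integer(n)
    k <- 0L
    phase2_at <- NA_integer_
    while (any(alive) && cpp_lcc_size(adj, alive) > thresh) {
      cross <- cpp_cross_degrees(adj, alive, memb)
      W <- cpp_coarse_counts(adj, alive, memb, nc)
      if (sum(W) > 0) {
        sc <- cbdi_scores_fast(adj, alive, memb, nc, W)
        v <- pick_target(sc, cross$kin, alive)
      } else {
        if (is.na(phase2_at)) phase2_at <- k + 1L
        v <- pick_target(cross$kin, cross$kin, alive)
      }
      k <- k + 1L
      ord[k] <- v
      alive[v] <- FALSE
    }
    nt <- k
    if (any(alive)) ord[(k + 1L):n] <- degree_tail(adj, alive)
    new_schedule(ord, nt, "cbdi",
                 params = list(stop_frac = stop_frac,
                               partition = partition$method,
                               phase2_start = phase2_at),
                 seed = seed, labels = graph_labels(g))
  })
}

#' Bipartition objectives for Laplacian spectral partitioning
#'
#' Named registry of the step-3 objective maximized over the Fiedler-vector
#' threshold cuts. `two_group_modularity` is
#' \eqn{m_{\mathrm{in}}/M - (K_1^2 + K_2^2)/(4M^2)} (the two-group
#' modularity); `cut_ratio` is \eqn{-m_{\mathrm{out}}/(K_1 K_2)}
#' (maximizing it minimizes the degree-normalized cut).
#'
#' @format Named list of functions `(m_in, m_out, K1, K2, M) -> score`.
#' @export
lsp_score_variants <- list(
  two_group_modularity = function(m_in, m_out, K1, K2, M) {
    m_in / M - (K1^2 + K2^2) / (4 * M^2)
  },
  cut_ratio = function(m_in, m_out, K1, K2, M) {
    -m_out / (K1 * K2)
  }
)

#' Laplacian spectral partitioning removal schedule
#'
#' Iterates: (1) compute the Fiedler vector (eigenvector of the second
#' smallest Laplacian eigenvalue) of the current largest connected
#' component; (2) scan all threshold bipartitions of the sorted Fiedler
#' values (cuts between tied values are skipped); (3) keep the bipartition
#' maximizing the chosen objective; (4) adaptively remove the node with the
#' most inter-group links (ties broken at random) until the two groups
#' disconnect; (5) repeat until the LCC drops below `theta * N`. Components
#' of one or two nodes are treated as fully fragmented. The Fiedler vector
#' sign is fixed so its first non-zero entry is positive, keeping runs
#' replayable.
#'
#' @param g A connected, undirected, simple igraph graph.
#' @param theta Final LCC fraction (default 0.01).
#' @param seed Tie-break seed.
#' @param variant Name in [lsp_score_variants] or a function
#'   `(m_in, m_out, K1, K2, M) -> score` to maximize.
#' @return A [new_schedule()] object.
#' @export
lsp_schedule <- function(g, theta = 0.01, seed = NULL,
                         variant = "two_group_modularity") {
  check_graph(g)
  stopifnot(theta > 0, theta < 1)
  score_fn <- if (is.function(variant)) variant else lsp_score_variants[[variant]]
  if (is.null(score_fn)) stop("unknown LSP score variant", call. = FALSE)
  adj <- graph_adjlist(g)
  n <- length(adj)
  with_seed(seed, {
    alive <- rep(TRUE, n)
    ord <- integer(n)
    k <- 0L
    repeat {
      if (!any(alive)) break
      comp <- cpp_components(adj, alive)
      sizes <- tabulate(comp[comp > 0L])
      lcc_id <- which.max(sizes)
      if (sizes[lcc_id] < theta * n || sizes[lcc_id] <= 2L) break
      nodes <- which(comp == lcc_id)
      cut <- lsp_best_cut(adj, alive, nodes, score_fn)
      if (is.null(cut)) {
        # all Fiedler entries tied: no admissible cut, peel a hub instead
        deg <- cpp_residual_degree(adj, alive)
        v <- pick_target(deg, deg, alive)
        k <- k + 1L; ord[k] <- v; alive[v] <- FALSE
        next
      }
      in1 <- cut  # logical over `nodes`
      repeat {
        crossdeg <- rep(NA_real_, n)
        total_cross <- 0L
        for (a in seq_along(nodes)) {
          v0 <- nodes[a]
          if (!alive[v0]) next
          nb <- adj[[v0]]
          cnt <- 0L
          for (u in nb) {
            b <- match(u, nodes)
            if (!is.na(b) && alive[u] && in1[b] != in1[a]) cnt <- cnt + 1L
          }
          crossdeg[v0] <- cnt
          total_cross <- total_cross + cnt
        }
        if (total_cross == 0L) break
        mask <- alive & !is.na(crossdeg)
        v <- pick_target(crossdeg, crossdeg, mask)
        k <- k + 1L; ord[k] <- v; alive[v] <- FALSE
      }
    }
    nt <- k
    if (any(alive)) ord[(k + 1L):n] <- degree_tail(adj, alive)
    new_schedule(ord, nt, "lsp",
                 params = list(theta = theta,
                               variant = if (is.function(variant)) "custom"
                                         else variant),
                 seed = seed, labels = graph_labels(g))
  })
}

# Fiedler-vector threshold scan on the subgraph induced by `nodes`.
# Returns the logical group-1 indicator over `nodes`, or NULL when no cut
# separates distinct Fiedler values.
lsp_best_cut <- function(adj, alive, nodes, score_fn) {
  nl <- length(nodes)
  pos <- integer(length(alive))
  pos[nodes] <- seq_len(nl)
  A <- matrix(0, nl, nl)
  for (a in seq_len(nl)) {
    for (u in adj[[nodes[a]]]) {
      b <- pos[u]
      if (b > 0L && alive[u]) A[a, b] <- 1
    }
  }
  degs <- rowSums(A)
  M <- sum(degs) / 2
  L <- diag(degs) - A
  ev <- eigen(L, symmetric = TRUE)
  fied <- ev$vectors[, nl - 1L]
  nz <- which(abs(fied) > 1e-12)
  if (length(nz) > 0L && fied[nz[1]] < 0) fied <- -fied
  o <- order(fied, decreasing = TRUE)
  in1 <- logical(nl)
  K1 <- 0; m11 <- 0; m12 <- 0
  best <- -Inf
  best_assign <- NULL
  for (r in seq_len(nl - 1L)) {
    v <- o[r]
    nb1 <- sum(A[v, ] * in1)          # edges from v into group 1
    m11 <- m11 + nb1
    m12 <- m12 + (degs[v] - nb1) - nb1
    K1 <- K1 + degs[v]
    in1[v] <- TRUE
    if (fied[o[r]] > fied[o[r + 1L]]) {  # skip cuts through tied values
      m_in <- m11 + (M - m11 - m12)      # m22 = M - m11 - m12
      sc <- score_fn(m_in = m_in, m_out = m12, K1 = K1, K2 = 2 * M - K1, M = M)
      if (sc > best) {
        best <- sc
        best_assign <- in1  # copied on assignment
      }
    }
  }
  best_assign
}
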