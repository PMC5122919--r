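# Independent brute-force oracles. These recompute scores and curves from
# first principles (distance matrices, explicit path counting, per-step
# component searches) and never share code with the package internals.

oracle_ci_score <- function(g, i, ell, removed = integer()) {
  keep <- setdiff(seq_len(igraph::vcount(g)), removed)
  sub <- igraph::induced_subgraph(g, keep)
  ii <- match(i, keep)
  deg <- unname(igraph::degree(sub))
  if (ell == 0) return(deg[ii] - 1)
  d <- as.numeric(igraph::distances(sub, v = ii))
  fr <- which(d == ell)
  (deg[ii] - 1) * sum(deg[fr] - 1)
}

# Naive betweenness via explicit shortest-path counting over all pairs.
oracle_betweenness <- function(g) {
  n <- igraph::vcount(g)
  D <- igraph::distances(g)
  S <- matrix(0, n, n)  # S[s, t] = number of shortest s-t paths
  nbrs <- lapply(seq_len(n), function(v) as.integer(igraph::neighbors(g, v)))
  for (s in seq_len(n)) {
    S[s, s] <- 1
    ds <- D[s, ]
    dist_vals <- sort(unique(ds[is.finite(ds) & ds > 0]))
    for (dd in dist_vals) {
      for (t in which(ds == dd)) {
        pre <- nbrs[[t]][ds[nbrs[[t]]] == dd - 1]
        S[s, t] <- sum(S[s, pre])
      }
    }
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq.int(s + 1, n)) {
      if (!is.finite(D[s, t]) || D[s, t] < 2) next
      mid <- which(D[s, ] + D[, t] == D[s, t])
      mid <- setdiff(mid, c(s, t))
      if (length(mid) > 0) {
        bc[mid] <- bc[mid] + S[s, mid] * S[mid, t] / S[s, t]
      }
    }
  }
  bc
}

# Per-step component search: LCC sizes along an order, recomputed naively.
oracle_curve <- function(g, ord) {
  n <- igraph::vcount(g)
  G <- numeric(n + 1)
  G[1] <- max(igraph::components(g)$csize)
  for (k in seq_len(n)) {
    keep <- setdiff(seq_len(n), ord[seq_len(k)])
    G[k + 1] <- if (length(keep) == 0) 0 else {
      max(igraph::components(igraph::induced_subgraph(g, keep))$csize)
    }
  }
  G / n
}

oracle_modularity <- function(g, memb) {
  M <- igraph::ecount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- igraph::degree(g)
  sum(vapply(unique(memb), function(cc) {
    m_c <- sum(memb[el[, 1]] == cc & memb[el[, 2]] == cc)
    K_c <- sum(deg[memb == cc])
    m_c / M - (K_c / (2 * M))^2
  }, numeric(1)))
}

# Community-level collective influence from the distance matrix of the
# coarse topology (smallest-id predecessor convention).
oracle_community_ci <- function(cg, I, ell) {
  W <- cg$weights
  s <- rowSums(W)
  kappa <- rowSums(W > 0)
  z <- if (kappa[I] >= 1) s[I] * (1 - 1 / kappa[I]) else 0
  if (ell == 0) return(z)
  if (z == 0) return(0)
  gW <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  d <- as.numeric(igraph::distances(gW, v = I))
  fr <- which(d == ell)
  acc <- 0
  for (J in fr) {
    preds <- which(W[J, ] > 0 & d == ell - 1)
    acc <- acc + s[J] - W[J, min(preds)]
  }
  z * acc
}

# Exhaustive modularity maximization over all bipartitions (n <= ~12).
oracle_best_bipartition <- function(g) {
  n <- igraph::vcount(g)
  best_q <- -Inf
  best <- NULL
  for (code in 0:(2^(n - 1) - 1)) {  # node 1 fixed in group 1
    memb <- c(1L, 1L + as.integer(intToBits(code))[seq_len(n - 1)])
    q <- oracle_modularity(g, memb)
    if (q > best_q) { best_q <- q; best <- memb }
  }
  list(membership = best, Q = best_q)
}

# Perron vector by power iteration (independent of eigen()). Iterates on
# W + cI so bipartite topologies (symmetric spectrum) still converge; the
# shift leaves the eigenvectors unchanged.
oracle_perron <- function(W, iters = 2000) {
  shift <- max(rowSums(W))
  Ws <- W + diag(shift, nrow(W))
  v <- rep(1, nrow(W))
  for (i in seq_len(iters)) {
    v2 <- as.numeric(Ws %*% v)
    nv <- sqrt(sum(v2^2))
    if (nv == 0) return(v2)
    v <- v2 / nv
  }
  v
}
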