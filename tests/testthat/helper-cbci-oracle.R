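# Brute-force CbCI: coarse matrix tabulated from the induced subgraph's
# edge list, community CI from the distance-matrix oracle, allocation by
# hand-counted inter-community degrees.
oracle_cbci_scores <- function(g, memb, ell, removed = integer()) {
  n <- igraph::vcount(g)
  keep <- setdiff(seq_len(n), removed)
  sub <- igraph::induced_subgraph(g, keep)
  el <- igraph::as_edgelist(sub, names = FALSE)
  mk <- memb[keep]
  nc <- max(memb)
  W <- matrix(0, nc, nc)
  for (r in seq_len(nrow(el))) {
    I <- mk[el[r, 1]]
    J <- mk[el[r, 2]]
    if (I != J) { W[I, J] <- W[I, J] + 1; W[J, I] <- W[J, I] + 1 }
  }
  cg <- structure(list(weights = W, strength = rowSums(W),
                       n_neighbors = as.integer(rowSums(W > 0)),
                       n_comm = nc),
                  class = "coarse_graph")
  cic <- vapply(seq_len(nc), function(I) oracle_community_ci(cg, I, ell),
                numeric(1))
  out <- rep(NA_real_, n)
  for (idx in seq_along(keep)) {
    i <- keep[idx]
    nb <- as.integer(igraph::neighbors(sub, idx))
    kout <- sum(mk[nb] != memb[i])
    sI <- sum(W[memb[i], ])
    out[i] <- if (sI > 0) kout / sI * cic[memb[i]] else 0
  }
  out
}
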