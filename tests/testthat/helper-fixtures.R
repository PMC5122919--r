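# Fixture graphs, built in code. All use integer labels 1..N.

make_net <- function(edges) {
  # edges: 2-column integer matrix of endpoint labels
  tf <- tempfile(fileext = ".edg")
  on.exit(unlink(tf))
  writeLines(paste(edges[, 1], edges[, 2]), tf)
  read_edge_list(tf)
}

# 8-node, 4-community worked example: intra edges 1-2, 3-4, 5-6, 7-8;
# inter edges 2-3, 1-3, 4-5, 5-7, 6-7, 6-8. Coarse path C1 -2- C2 -1- C3 -3- C4.
fx_8node <- function() {
  g <- make_net(rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8),
                      c(2, 3), c(1, 3), c(4, 5), c(5, 7), c(6, 7), c(6, 8)))
  list(g = g, partition = node_partition(c(1, 1, 2, 2, 3, 3, 4, 4)))
}

# Two k-cliques joined by a single bridge edge between node 1 and node k+1.
fx_two_cliques <- function(k) {
  cl <- function(off) t(utils::combn(off + seq_len(k), 2))
  make_net(rbind(cl(0), cl(k), c(1, k + 1)))
}

fx_path <- function(n) make_net(cbind(seq_len(n - 1), 2:n))

fx_star <- function(leaves) make_net(cbind(1, 1 + seq_len(leaves)))

fx_cycle <- function(n) make_net(cbind(seq_len(n), c(2:n, 1)))

# Two triangles joined through a dedicated bridge node 7.
fx_bridge_triangles <- function() {
  make_net(rbind(c(1, 2), c(2, 3), c(1, 3),
                 c(4, 5), c(5, 6), c(4, 6),
                 c(3, 7), c(7, 4)))
}

# Random connected graph: LCC of a G(n, m) draw.
fx_rand <- function(n, m, seed) {
  g <- with_test_seed(seed, igraph::sample_gnm(n, m))
  igraph::V(g)$name <- as.character(seq_len(n))
  preprocess_network(g)
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

singleton_partition <- function(g) node_partition(seq_len(igraph::vcount(g)))

# Ground-truth partition restricted to the preprocessed LCC of a
# community_sf_network() draw.
lcc_with_truth <- function(gen) {
  g <- preprocess_network(gen$graph)
  keep <- match(igraph::V(g)$name, igraph::V(gen$graph)$name)
  list(g = g, partition = node_partition(gen$partition$membership[keep],
                                         method = "ground_truth"))
}
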