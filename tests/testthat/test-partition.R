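test_that("coarse graining counts inter-community links", {
  fx <- fx_8node()
  cg <- coarse_grain(fx$g, fx$partition)
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 2
  W[2, 3] <- W[3, 2] <- 1
  W[3, 4] <- W[4, 3] <- 3
  expect_equal(cg$weights, W)
  expect_equal(cg$strength, c(2, 3, 4, 3))
  expect_equal(cg$n_neighbors, c(1L, 2L, 2L, 1L))

  # one community for everything -> 1x1 zero matrix
  cg1 <- coarse_grain(fx$g, node_partition(rep(1, 8)))
  expect_equal(cg1$weights, matrix(0, 1, 1))

  # removal empties rows but keeps community ids
  cg2 <- coarse_grain(fx$g, fx$partition, removed = c(1, 2))
  expect_equal(cg2$strength[1], 0)
  expect_equal(cg2$n_comm, 4)
})

test_that("singleton partitions reduce the coarse graph to the adjacency matrix", {
  g <- fx_rand(25, 45, seed = 4)
  cg <- coarse_grain(g, singleton_partition(g))
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  dimnames(A) <- NULL
  expect_equal(cg$weights, A)
})

test_that("strength accounting: inter plus intra edges equal M", {
  for (seed in 1:5) {
    g <- fx_rand(30, 60, seed = seed)
    memb <- with_test_seed(seed, sample(1:4, igraph::vcount(g), replace = TRUE))
    p <- node_partition(memb)
    cg <- coarse_grain(g, p)
    el <- igraph::as_edgelist(g, names = FALSE)
    intra <- sum(p$membership[el[, 1]] == p$membership[el[, 2]])
    expect_equal(sum(cg$strength) / 2 + intra, igraph::ecount(g))
  }
})

test_that("partition entropy matches the size-distribution formula", {
  e <- partition_entropy(node_partition(rep(1:4, each = 25)))
  expect_equal(e$entropy, log(4))
  expect_equal(e$normalized, 1)

  expect_equal(partition_entropy(node_partition(rep(1, 50)))$entropy, 0)

  e <- partition_entropy(node_partition(c(rep(1, 99), 2)))
  expect_equal(e$entropy, -0.99 * log(0.99) - 0.01 * log(0.01))

  # normalized entropy in [0, 1], 1 iff equipartition
  e <- partition_entropy(node_partition(c(rep(1, 30), rep(2, 10))))
  expect_true(e$normalized > 0 && e$normalized < 1)
})

test_that("mean clustering follows the per-node triangle definition", {
  expect_equal(mean_clustering(fx_cycle(3)), 1)
  expect_equal(mean_clustering(fx_star(5)), 0)
  # K4 minus one edge: two nodes see 2 of 3 neighbour pairs closed (2/3),
  # the two endpoints of the missing edge see their single pair closed (1)
  g <- make_net(rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4)))
  expect_equal(mean_clustering(g), (2 / 3 + 2 / 3 + 1 + 1) / 4)
})

test_that("weighted clustering of the coarse graph uses strength normalization", {
  tri <- function(w12, w13, w23) {
    W <- matrix(0, 3, 3)
    W[1, 2] <- W[2, 1] <- w12
    W[1, 3] <- W[3, 1] <- w13
    W[2, 3] <- W[3, 2] <- w23
    cbci:::new_coarse_graph(W)
  }
  expect_equal(mean_weighted_clustering(tri(1, 1, 1)), 1)
  expect_equal(mean_weighted_clustering(tri(2, 1, 1)), 1)

  # coarse star: no closed triangles
  W <- matrix(0, 4, 4)
  W[1, 2:4] <- W[2:4, 1] <- c(3, 1, 2)
  expect_equal(mean_weighted_clustering(cbci:::new_coarse_graph(W)), 0)

  # unit weights reduce to the unweighted clustering of the topology
  g <- fx_rand(20, 40, seed = 8)
  cg <- coarse_grain(g, singleton_partition(g))
  expect_equal(mean_weighted_clustering(cg), mean_clustering(g))
})

test_that("modularity matches the Newman-Girvan formula", {
  g <- fx_two_cliques(5)
  p <- node_partition(rep(1:2, each = 5))
  expect_equal(partition_modularity(g, p), 20 / 21 - 1 / 2)
  expect_equal(partition_modularity(g, node_partition(rep(1, 10))), 0)

  # singleton partition: -sum (k_i / 2M)^2, cross-checked with the oracle
  g <- fx_rand(20, 35, seed = 2)
  deg <- igraph::degree(g)
  M <- igraph::ecount(g)
  expect_equal(partition_modularity(g, singleton_partition(g)),
               -sum((deg / (2 * M))^2))
  memb <- with_test_seed(3, sample(1:3, igraph::vcount(g), replace = TRUE))
  expect_equal(partition_modularity(g, node_partition(memb)),
               oracle_modularity(g, memb))
})

test_that("community detection adapters recover planted structure", {
  g <- fx_two_cliques(5)
  truth <- oracle_best_bipartition(g)  # exhaustive modularity maximization
  expect_equal(sort(tabulate(truth$membership)), c(5, 5))
  for (m in c("infomap", "walktrap", "label_propagation",
              "fast_greedy", "louvain")) {
    p <- detect_communities(g, method = m, seed = 42)
    expect_equal(p$n_comm, 2)
    expect_equal(sort(p$sizes), c(5, 5))
    # same grouping as the exhaustive bipartition
    expect_true(all(p$membership[1:5] == p$membership[1]) &&
                  all(p$membership[6:10] == p$membership[6]))
  }
  # no structure: complete graph collapses to one community
  k5 <- fx_two_cliques(5)
  p <- detect_communities(make_net(t(utils::combn(1:5, 2))), "louvain",
                          seed = 1)
  expect_equal(p$n_comm, 1)
  expect_error(detect_communities(k5, method = "simulated_annealing"),
               "not implemented")
})

test_that("external partitions pass through files verbatim", {
  g <- fx_path(4)
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\t0", "2\t0", "3\t1", "4\t1"), tf)
  p <- detect_communities(g, method = "external", file = tf)
  expect_equal(p$membership, c(1L, 1L, 2L, 2L))
  expect_equal(p$n_comm, 2)

  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_partition(p, tf2, g)
  expect_equal(read_partition(tf2, g)$membership, p$membership)

  writeLines(c("1\t0", "2\t0", "3\t1", "99\t1"), tf)
  expect_error(read_partition(tf, g), "not in the graph")
  writeLines(c("1\t0", "2\t0"), tf)
  expect_error(read_partition(tf, g), "2 of 4")
})
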