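test_that("adaptive degree removal targets hubs and stays deterministic", {
  g <- fx_star(6)
  s <- degree_schedule(g, seed = 1)
  expect_equal(schedule_labels(s)[1], "1")

  # all-tie case: any node first, but replay is identical under the seed
  g <- fx_cycle(5)
  s1 <- degree_schedule(g, seed = 4)
  s2 <- degree_schedule(g, seed = 4)
  expect_identical(s1$order, s2$order)

  # path: the first removal is one of the degree-2 interior nodes
  g <- fx_path(5)
  s <- degree_schedule(g, seed = 2)
  expect_true(s$order[1] %in% 2:4)
})

test_that("adaptive betweenness matches the path-counting oracle per step", {
  g <- fx_bridge_triangles()
  s <- betweenness_schedule(g, seed = 1)
  expect_equal(schedule_labels(s)[1], "7")  # the bridge node

  # complete graph: all betweenness zero, schedule still valid
  g <- make_net(t(utils::combn(1:5, 2)))
  s <- betweenness_schedule(g, seed = 3)
  expect_false(anyDuplicated(s$order) > 0)

  # every targeted step removes an oracle argmax (betweenness, then degree)
  g <- fx_rand(22, 40, seed = 17)
  n <- igraph::vcount(g)
  s <- betweenness_schedule(g, stop_frac = 0.1, seed = 5)
  removed <- integer()
  for (k in seq_len(s$n_targeted)) {
    alive <- setdiff(seq_len(n), removed)
    sub <- igraph::induced_subgraph(g, alive)
    bc <- oracle_betweenness(sub)
    picked <- match(s$order[k], alive)
    expect_equal(bc[picked], max(bc), tolerance = 1e-10)
    removed <- c(removed, s$order[k])
  }
})

test_that("CbDI scores are eigenvector-weighted inter-community degrees", {
  # two communities, coarse matrix [[0, 2], [2, 0]]: v = (1, 1)/sqrt(2);
  # a node with two links into the other community scores 2 * 1/2 = 1
  g <- make_net(rbind(c(1, 2), c(3, 4), c(1, 3), c(1, 4)))
  p <- node_partition(c(1, 1, 2, 2))
  sc <- cbdi_scores(g, p)
  expect_equal(unname(sc[1]), 1)
  expect_equal(unname(sc[2]), 0)  # no inter-community links

  # ranks agree with a power-iteration Perron oracle
  fx <- fx_8node()
  cg <- coarse_grain(fx$g, fx$partition)
  v_orc <- oracle_perron(cg$weights)
  kiJ <- cbci:::cpp_community_degree(
    lapply(igraph::as_adj_list(fx$g, mode = "all"), as.integer),
    rep(TRUE, 8), fx$partition$membership, 4)
  memb <- fx$partition$membership
  orc <- vapply(1:8, function(i) {
    v_orc[memb[i]] * sum(kiJ[i, -memb[i]] * v_orc[-memb[i]])
  }, numeric(1))
  sc <- cbdi_scores(fx$g, fx$partition)
  expect_equal(order(-sc), order(-orc))
  expect_equal(unname(sc), orc, tolerance = 1e-6)
})

test_that("CbDI removal switches to intra-degree once communities disconnect", {
  # one community: no coarse edges at all -> pure phase 2 from the start
  g <- fx_two_cliques(4)
  s <- cbdi_schedule(g, node_partition(rep(1, 8)), seed = 1)
  expect_equal(s$params$phase2_start, 1L)
  # phase 2 is adaptive max intra-degree = max degree here
  deg <- unname(igraph::degree(g))
  expect_equal(deg[s$order[1]], max(deg))

  # two-community fixture: the phase switch happens exactly when the
  # last inter-community edge disappears
  fx <- fx_8node()
  s <- cbdi_schedule(fx$g, fx$partition, seed = 2)
  if (!is.na(s$params$phase2_start)) {
    k <- s$params$phase2_start - 1L
    cg_before <- coarse_grain(fx$g, fx$partition,
                              removed = s$order[seq_len(max(k - 1, 0))])
    cg_after <- coarse_grain(fx$g, fx$partition, removed = s$order[seq_len(k)])
    expect_gt(sum(cg_before$weights), 0)
    expect_equal(sum(cg_after$weights), 0)
  }

  s2 <- cbdi_schedule(fx$g, fx$partition, seed = 2)
  expect_identical(s$order, s2$order)
})

test_that("Laplacian spectral partitioning cuts along the Fiedler split", {
  # two 4-cliques + one bridge: the Fiedler split separates the cliques,
  # and only the bridge endpoints (1 and 5) carry inter-group links
  g <- fx_two_cliques(4)
  s <- lsp_schedule(g, seed = 1)
  expect_true(s$order[1] %in% c(1L, 5L))
  # one bridge-endpoint removal disconnects the groups
  expect_equal(lcc_size(g, removed = s$order[1]), 4)

  # tiny graphs are already fragmented
  g2 <- fx_path(2)
  s2 <- lsp_schedule(g2, seed = 1)
  expect_equal(s2$n_targeted, 0L)

  # replay determinism (eigenvector sign is pinned)
  g3 <- fx_rand(30, 55, seed = 21)
  a <- lsp_schedule(g3, seed = 7)
  b <- lsp_schedule(g3, seed = 7)
  expect_identical(a$order, b$order)

  # variant registry
  s4 <- lsp_schedule(g, seed = 1, variant = "cut_ratio")
  expect_true(s4$order[1] %in% c(1L, 5L))
  expect_error(lsp_schedule(g, variant = "nope"), "unknown")
})

test_that("all strategies emit valid schedules that reach their threshold", {
  g <- fx_rand(40, 90, seed = 31)
  n <- igraph::vcount(g)
  p <- detect_communities(g, "louvain", seed = 1)
  scheds <- list(
    degree = degree_schedule(g, seed = 1),
    betweenness = betweenness_schedule(g, seed = 1),
    ci = ci_schedule(g, seed = 1),
    cbci = cbci_schedule(g, p, seed = 1),
    cbdi = cbdi_schedule(g, p, seed = 1),
    lsp = lsp_schedule(g, seed = 1)
  )
  for (nm in names(scheds)) {
    s <- scheds[[nm]]
    expect_equal(sort(s$order), 1:n)
    lcc_at_stop <- lcc_size(g, removed = s$order[seq_len(s$n_targeted)])
    lim <- if (nm == "lsp") max(0.01 * n, 2) else 0.01 * n
    expect_lte(lcc_at_stop, lim)
  }
})
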