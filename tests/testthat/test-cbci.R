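test_that("root and frontier factors satisfy their limiting constraints", {
  fx <- fx_8node()
  cg <- coarse_grain(fx$g, fx$partition)

  # single-neighbour communities have zero root factor
  expect_equal(root_factor(cg, 1), 0)
  expect_equal(root_factor(cg, 4), 0)
  expect_equal(root_factor(cg, 2), 1.5)  # s = 3, kappa = 2
  expect_equal(root_factor(cg, 3), 2)    # s = 4, kappa = 2

  # unit weights: root factor reduces to kappa - 1
  g <- fx_star(5)
  cgu <- coarse_grain(g, singleton_partition(g))
  expect_equal(root_factor(cgu, 1), 4)

  # frontier factor: outgoing strength minus the arriving link
  expect_equal(frontier_factor(cg, J = 3, J_minus = 2), 3)  # s=4 minus 1
  expect_equal(frontier_factor(cg, J = 1, J_minus = 2), 0)  # sole neighbour
  expect_error(frontier_factor(cg, J = 1, J_minus = 4), "not adjacent")
})

test_that("community-level CI matches hand-derived fixture values", {
  fx <- fx_8node()
  cg <- coarse_grain(fx$g, fx$partition)
  expect_equal(community_ci(cg, 2, ell = 1), 4.5)  # 1.5 * (0 + 3)
  expect_equal(community_ci(cg, 3, ell = 1), 4)    # 2 * (2 + 0)
  expect_equal(community_ci(cg, 1, ell = 1), 0)    # kappa = 1
  expect_equal(community_ci(cg, 2, ell = 0), 1.5)  # z itself at ell = 0

  # independent oracle on random coarse graphs
  for (seed in 1:10) {
    g <- fx_rand(15, 30, seed = seed)
    memb <- with_test_seed(seed, sample(1:5, igraph::vcount(g), replace = TRUE))
    cgr <- coarse_grain(g, node_partition(memb))
    for (I in seq_len(cgr$n_comm)) {
      for (ell in 0:3) {
        expect_equal(community_ci(cgr, I, ell = ell),
                     oracle_community_ci(cgr, I, ell))
      }
    }
  }
})

test_that("unit-weight coarse graphs reduce community CI to node CI", {
  g <- fx_rand(25, 45, seed = 11)
  cg <- coarse_grain(g, singleton_partition(g))
  for (ell in 0:2) {
    sc <- ci_scores(g, ell = ell)
    for (I in seq_len(cg$n_comm)) {
      expect_equal(community_ci(cg, I, ell = ell), unname(sc[I]))
    }
  }
})

test_that("node-level CbCI allocates community CI by inter-community degree", {
  fx <- fx_8node()
  sc <- cbci_scores(fx$g, fx$partition, ell = 1)
  expect_equal(unname(sc[3]), 3.0)  # (2/3) * 4.5
  expect_equal(unname(sc[4]), 1.5)  # (1/3) * 4.5
  expect_equal(unname(sc[5]), 2.0)  # (2/4) * 4
  # nodes whose community has a single neighbouring community score 0
  expect_equal(unname(sc[c(1, 2, 7, 8)]), rep(0, 4))
  expect_true(all(sc >= 0, na.rm = TRUE))
})

test_that("singleton partitions make CbCI identical to CI", {
  for (seed in 1:20) {
    nn <- 10 + (seed * 11) %% 51
    g <- fx_rand(nn, nn + (seed * 5) %% nn + 2, seed = seed + 40)
    p <- singleton_partition(g)
    for (ell in 0:2) {
      expect_identical(as.numeric(cbci_scores(g, p, ell = ell)),
                       as.numeric(ci_scores(g, ell = ell)))
    }
    s_ci <- ci_schedule(g, ell = 2, seed = seed)
    s_cb <- cbci_schedule(g, p, ell = 2, seed = seed)
    expect_identical(s_cb$order, s_ci$order)
  }
})

test_that("adaptive CbCI removal follows scores, ties and the fallback", {
  fx <- fx_8node()
  s <- cbci_schedule(fx$g, fx$partition, ell = 1, seed = 2)
  expect_equal(schedule_labels(s)[1], "3")  # unique argmax 3.0

  # replay determinism
  s2 <- cbci_schedule(fx$g, fx$partition, ell = 1, seed = 2)
  expect_identical(s$order, s2$order)

  # one community: no coarse edges, immediate degree-adaptive fallback
  g <- fx_two_cliques(4)
  sf <- cbci_schedule(g, node_partition(rep(1, 8)), seed = 5)
  expect_true(sf$params$fallback)
  expect_false(anyDuplicated(sf$order) > 0)
  expect_lte(lcc_size(g, removed = sf$order[seq_len(sf$n_targeted)]),
             0.01 * 8)
})

test_that("community reinsertion minimizes the communities joined", {
  # candidate 7 would join communities {A, B} (2), candidate 8 joins
  # {A, B, C} (3): 7 is reinserted first, so 8 is removed first
  g <- make_net(rbind(c(1, 2), c(3, 4), c(5, 6),
                      c(7, 1), c(7, 3), c(8, 3), c(8, 5)))
  p <- node_partition(c(1, 1, 2, 2, 3, 3, 1, 1))
  sched <- new_schedule(c(7L, 8L, 1L, 2L, 3L, 4L, 5L, 6L), n_targeted = 2,
                        strategy = "cbci", labels = graph_labels(g))
  out <- community_reinsert(g, p, sched, seed = 1)
  expect_equal(out$order[1:2], c(8L, 7L))

  # a removed node with no alive neighbours counts only its own community
  sched2 <- new_schedule(c(7L, 8L, 3L, 1L, 2L, 4L, 5L, 6L), n_targeted = 3,
                         strategy = "cbci", labels = graph_labels(g))
  out2 <- community_reinsert(g, p, sched2, seed = 1)
  expect_false(anyDuplicated(out2$order) > 0)

  # singleton partition: both reinserters behave identically here
  gp <- fx_path(5)
  schedp <- new_schedule(c(2L, 4L, 1L, 3L, 5L), n_targeted = 2,
                         strategy = "x", labels = graph_labels(gp))
  for (seed in 1:5) {
    a <- reinsert(gp, schedp, seed = seed)
    b <- community_reinsert(gp, singleton_partition(gp), schedp, seed = seed)
    expect_identical(a$order, b$order)
  }
})
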