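test_that("edge-list reading builds simple undirected graphs", {
  tf <- withr::local_tempfile(fileext = ".edg")

  writeLines(c("1 2", "2 3", "3 1"), tf)
  g <- read_edge_list(tf)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)

  # self-loops and duplicates are dropped silently
  writeLines(c("1 1", "1 2", "2 1"), tf)
  g <- read_edge_list(tf)
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)

  # disconnected input is preserved
  writeLines(c("1 2", "3 4"), tf)
  g <- read_edge_list(tf)
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 2)
  expect_equal(igraph::components(g)$no, 2)

  # comments and blank lines are skipped; bad lines are named
  writeLines(c("# header", "", "1 2", "oops"), tf)
  expect_error(read_edge_list(tf), "line 4")
  writeLines(c("# only comments"), tf)
  expect_error(read_edge_list(tf), "empty")
})

test_that("edge lists round-trip through write_edge_list", {
  g <- fx_rand(30, 60, seed = 5)
  tf <- withr::local_tempfile(fileext = ".edg")
  write_edge_list(g, tf)
  g2 <- read_edge_list(tf)
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  canon <- function(gg) {
    el <- igraph::as_edgelist(gg, names = TRUE)
    sorted <- t(apply(el, 1, sort))
    paste(sorted[, 1], sorted[, 2])[order(paste(sorted[, 1], sorted[, 2]))]
  }
  expect_identical(canon(g2), canon(g))
})

test_that("preprocessing keeps the largest component with deterministic ties", {
  # triangle plus isolated edge -> triangle
  g <- make_net(rbind(c(1, 2), c(2, 3), c(3, 1), c(10, 11)))
  lcc <- preprocess_network(g)
  expect_setequal(igraph::V(lcc)$name, c("1", "2", "3"))

  # two equal components: the one containing the smallest id wins
  g <- make_net(rbind(c(5, 6), c(1, 9)))
  lcc <- preprocess_network(g)
  expect_setequal(igraph::V(lcc)$name, c("1", "9"))

  # connected graph is returned unchanged (same node set)
  g <- fx_cycle(7)
  expect_setequal(igraph::V(preprocess_network(g))$name, igraph::V(g)$name)
})

test_that("largest-component size respects removals and is monotone", {
  g <- fx_path(3)
  expect_equal(lcc_size(g, removed = "2"), 1)
  expect_equal(lcc_size(fx_cycle(5), removed = 3), 4)
  expect_equal(lcc_size(fx_two_cliques(3)), 6)
  expect_equal(lcc_size(g, removed = 1:3), 0)

  # non-increasing along any removal order
  g <- fx_rand(40, 70, seed = 9)
  ord <- degree_schedule(g, seed = 1)$order
  sizes <- vapply(0:length(ord), function(k) {
    lcc_size(g, removed = ord[seq_len(k)])
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("ball frontiers are exact-distance shells partitioning the ball", {
  g <- fx_path(5)
  expect_equal(ball_frontier(g, "1", ell = 2), 3L)
  g <- fx_star(6)
  expect_setequal(ball_frontier(g, "1", ell = 1), 2:7)
  expect_length(ball_frontier(g, "1", ell = 3), 0)  # beyond eccentricity
  expect_equal(ball_frontier(g, "1", ell = 0), 1L)

  # shells for ell = 0..L partition the distance-<=L ball
  g <- fx_rand(30, 55, seed = 3)
  d <- as.numeric(igraph::distances(g, v = 1))
  shells <- lapply(0:4, function(l) ball_frontier(g, 1, ell = l))
  expect_false(any(duplicated(unlist(shells))))
  expect_setequal(unlist(shells), which(d <= 4))
  for (l in 0:4) expect_setequal(shells[[l + 1]], which(d == l))

  # removals change the metric
  g <- fx_cycle(6)
  expect_setequal(ball_frontier(g, 1, ell = 2), c(3, 5))
  expect_equal(ball_frontier(g, 1, ell = 2, removed = 2), 5L)
})
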