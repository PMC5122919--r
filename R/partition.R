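#' Node partitions
#'
#' A `node_partition` is a fixed assignment of every node to exactly one
#' community. Community labels are normalized to `1..n_comm` (in order of
#' first appearance of the original labels, sorted); the original labels are
#' kept in `community_labels`.
#'
#' @param membership Vector of community labels, one per node (any atomic
#'   type with at least one node per community).
#' @param method Name of the algorithm or source that produced the
#'   partition.
#' @return An object of class `node_partition` with fields `membership`
#'   (integer `1..n_comm`), `sizes`, `n_comm`, `community_labels`, `method`.
#' @export
node_partition <- function(membership, method = "external") {
  if (length(membership) == 0L) stop("empty partition", call. = FALSE)
  if (anyNA(membership)) stop("membership contains NA", call. = FALSE)
  labs <- sort(unique(membership))
  memb <- match(membership, labs)
  structure(
    list(membership = as.integer(memb),
         sizes = tabulate(memb, nbins = length(labs)),
         n_comm = length(labs),
         community_labels = labs,
         method = method),
    class = "node_partition"
  )
}

#' @export
print.node_partition <- function(x, ...) {
  cat("Node partition (", x$method, "): ", length(x$membership), " nodes, ",
      x$n_comm, " communities\n", sep = "")
  cat("community sizes:",
      paste(utils::head(sort(x$sizes, decreasing = TRUE), 10), collapse = " "),
      if (x$n_comm > 10) "...\n" else "\n")
  invisible(x)
}

check_partition <- function(g, partition) {
  if (!inherits(partition, "node_partition")) {
    stop("`partition` must be a node_partition object", call. = FALSE)
  }
  if (length(partition$membership) != igraph::vcount(g)) {
    stop("partition labels ", length(partition$membership),
         " nodes but the graph has ", igraph::vcount(g), call. = FALSE)
  }
  invisible(partition)
}

#' Detect communities on the intact graph
#'
#' Thin adapters around the community-detection algorithms of \pkg{igraph},
#' behind a uniform interface. The partition is meant to be computed once on
#' the intact (preprocessed) graph and frozen for the whole removal process.
#' Stochastic algorithms (infomap, label propagation, louvain) are run under
#' the given seed. `method = "external"` loads a partition from a TSV file
#' (see [read_partition()]); `method = "simulated_annealing"` is a
#' recognised name but deliberately not implemented (it does not scale
#' beyond small networks).
#'
#' @param g A connected, undirected, simple igraph graph.
#' @param method One of `"infomap"`, `"walktrap"`, `"label_propagation"`,
#'   `"fast_greedy"`, `"louvain"`, `"simulated_annealing"`, `"external"`.
#' @param seed Seed for stochastic methods (ignored otherwise).
#' @param file Partition file, required for `method = "external"`.
#' @return A [node_partition()].
#' @export
detect_communities <- function(g,
                               method = c("infomap", "walktrap",
                                          "label_propagation", "fast_greedy",
                                          "louvain", "simulated_annealing",
                                          "external"),
                               seed = NULL, file = NULL) {
  check_graph(g)
  method <- match.arg(method)
  if (method == "external") {
    if (is.null(file)) stop("method = 'external' needs `file`", call. = FALSE)
    return(read_partition(file, g))
  }
  if (method == "simulated_annealing") {
    stop("simulated-annealing modularity maximization is not implemented",
         call. = FALSE)
  }
  if (!igraph::is_connected(g)) {
    stop("`g` must be connected; run preprocess_network() first",
         call. = FALSE)
  }
  cl <- with_seed(seed, switch(method,
    infomap = igraph::cluster_infomap(g),
    walktrap = igraph::cluster_walktrap(g),
    label_propagation = igraph::cluster_label_prop(g),
    fast_greedy = igraph::cluster_fast_greedy(g),
    louvain = igraph::cluster_louvain(g)
  ))
  node_partition(igraph::membership(cl), method = method)
}

#' Read / write a node partition as TSV
#'
#' File format: two tab- (or whitespace-) separated columns,
#' `node_id<TAB>community_id`, one line per node. Every node of `g` must be
#' labelled exactly once, and no unknown nodes may appear.
#'
#' @param path Partition file.
#' @param g The graph the partition refers to.
#' @return A [node_partition()] (for `read_partition`).
#' @export
read_partition <- function(path, g) {
  check_graph(g)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("partition file needs two columns", call. = FALSE)
  labs <- graph_labels(g)
  idx <- match(tab[[1]], labs)
  if (anyNA(idx)) {
    stop("partition labels nodes not in the graph: ",
         paste(utils::head(tab[[1]][is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(idx)) stop("node labelled twice in partition file",
                               call. = FALSE)
  if (length(idx) != length(labs)) {
    stop("partition file labels ", length(idx), " of ", length(labs),
         " nodes", call. = FALSE)
  }
  memb <- character(length(labs))
  memb[idx] <- tab[[2]]
  node_partition(memb, method = "external")
}

#' @rdname read_partition
#' @param partition A [node_partition()].
#' @export
write_partition <- function(partition, path, g) {
  check_partition(g, partition)
  labs <- graph_labels(g)
  comm <- partition$community_labels[partition$membership]
  writeLines(paste(labs, comm, sep = "\t"), path)
  invisible(path)
}

#' Coarse-grain a graph over a partition
#'
#' Builds the weighted community supernetwork: element \eqn{(I, J)} of the
#' coarse adjacency counts the surviving edges with one endpoint in
#' community \eqn{I} and the other in \eqn{J \neq I}. Intra-community edges
#' are ignored and the diagonal is zero. Communities keep their ids even if
#' all of their nodes are removed (their row simply becomes zero), so the
#' coarse graph can be recomputed along a removal schedule with frozen
#' labels.
#'
#' When every community holds exactly one node, the coarse adjacency equals
#' the adjacency matrix of the original (residual) graph.
#'
#' @param g An undirected simple igraph graph.
#' @param partition A [node_partition()] covering all nodes of `g`.
#' @param removed Removed nodes (internal indices or vertex names).
#' @return An object of class `coarse_graph` with fields `weights`
#'   (symmetric matrix), `strength` (\eqn{s_I}, row sums), `n_neighbors`
#'   (\eqn{\kappa_I}, number of adjacent communities) and `n_comm`.
#' @export
coarse_grain <- function(g, partition, removed = integer()) {
  check_graph(g)
  check_partition(g, partition)
  adj <- graph_adjlist(g)
  alive <- alive_mask(length(adj), resolve_vids(g, removed))
  W <- cpp_coarse_counts(adj, alive, partition$membership, partition$n_comm)
  new_coarse_graph(W)
}

new_coarse_graph <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  structure(
    list(weights = W,
         strength = rowSums(W),
         n_neighbors = as.integer(rowSums(W > 0)),
         n_comm = nrow(W)),
    class = "coarse_graph"
  )
}

#' @export
print.coarse_graph <- function(x, ...) {
  m <- sum(x$weights > 0) / 2
  cat("Coarse-grained community network: ", x$n_comm, " communities, ",
      m, " weighted links, total weight ", sum(x$strength) / 2, "\n", sep = "")
  invisible(x)
}

#' Export a coarse graph as a weighted edge list
#'
#' One `"I J weight"` line per community pair with positive weight.
#'
#' @param cg A `coarse_graph`.
#' @param path Output path.
#' @export
write_coarse_graph <- function(cg, path) {
  stopifnot(inherits(cg, "coarse_graph"))
  up <- which(upper.tri(cg$weights) & cg$weights > 0, arr.ind = TRUE)
  writeLines(paste(up[, 1], up[, 2], cg$weights[up]), path)
  invisible(path)
}

#' Entropy of the community-size distribution
#'
#' \deqn{H = -\sum_c (N_c/N) \ln(N_c/N)} ranges between 0 (one community
#' holds everything) and \eqn{\ln N_C} (all communities equal). The
#' normalized form divides by \eqn{\ln N_C} and is defined as 1 when
#' \eqn{N_C = 1}. High entropy means an egalitarian partition, the regime in
#' which community-based dismantling works best.
#'
#' @param partition A [node_partition()].
#' @return List with `entropy` and `normalized`.
#' @export
partition_entropy <- function(partition) {
  stopifnot(inherits(partition, "node_partition"))
  p <- partition$sizes / sum(partition$sizes)
  H <- -sum(p * log(p))
  norm <- if (partition$n_comm == 1L) 1 else H / log(partition$n_comm)
  list(entropy = H, normalized = norm)
}

#' Mean local clustering coefficient
#'
#' Number of triangles through node \eqn{i} divided by
#' \eqn{k_i(k_i-1)/2}, averaged over all nodes; nodes with degree below 2
#' contribute 0.
#'
#' @param g An undirected simple igraph graph.
#' @return Mean local clustering in `[0, 1]`.
#' @export
mean_clustering <- function(g) {
  check_graph(g)
  if (igraph::vcount(g) == 0L) return(NaN)
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Mean weighted clustering coefficient of a coarse graph
#'
#' Strength-normalized (Barrat-style) local weighted clustering of each
#' supernode,
#' \deqn{C^w_I = \frac{1}{s_I(\kappa_I - 1)} \sum_{J \neq K}
#'   \frac{\tilde A_{IJ} + \tilde A_{IK}}{2}
#'   \, 1\{\tilde A_{IJ} > 0\} 1\{\tilde A_{IK} > 0\} 1\{\tilde A_{JK} > 0\},}
#' averaged over all supernodes; supernodes with fewer than two neighbours
#' contribute 0. On a unit-weight coarse graph this reduces to the
#' unweighted [mean_clustering()] of the same topology.
#'
#' @param cg A `coarse_graph`.
#' @return Mean weighted clustering.
#' @export
mean_weighted_clustering <- function(cg) {
  stopifnot(inherits(cg, "coarse_graph"))
  W <- cg$weights
  nc <- cg$n_comm
  vals <- numeric(nc)
  for (I in seq_len(nc)) {
    nb <- which(W[I, ] > 0)
    if (length(nb) < 2L) next
    acc <- 0
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a == b) next
        J <- nb[a]; K <- nb[b]
        if (W[J, K] > 0) acc <- acc + (W[I, J] + W[I, K]) / 2
      }
    }
    vals[I] <- acc / (cg$strength[I] * (cg$n_neighbors[I] - 1))
  }
  mean(vals)
}

#' Newman-Girvan modularity of a partition
#'
#' \deqn{Q = \sum_c \left[ m_c/M - (K_c/2M)^2 \right]} where \eqn{m_c} is the
#' number of intra-community edges and \eqn{K_c} the total degree of
#' community \eqn{c}.
#'
#' @param g An undirected simple igraph graph.
#' @param partition A [node_partition()].
#' @return Modularity value Q.
#' @export
partition_modularity <- function(g, partition) {
  check_graph(g)
  check_partition(g, partition)
  igraph::modularity(g, partition$membership)
}
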