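# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. With seed = NULL the current RNG stream is used as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

check_graph <- function(g) {
  if (!igraph::is_igraph(g)) {
    stop("`g` must be an igraph object", call. = FALSE)
  }
  if (igraph::is_directed(g)) {
    stop("`g` must be undirected; see read_edge_list()", call. = FALSE)
  }
  if (!igraph::is_simple(g)) {
    stop("`g` must be simple (no self-loops or parallel edges); ",
         "use read_edge_list() or igraph::simplify()", call. = FALSE)
  }
  invisible(g)
}

graph_labels <- function(g) {
  nm <- igraph::vertex_attr(g, "name")
  if (is.null(nm)) as.character(seq_len(igraph::vcount(g))) else as.character(nm)
}

graph_adjlist <- function(g) {
  lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
}

# Map a vector of vertex identifiers (internal integer indices or vertex
# name strings) to internal indices 1..N.
resolve_vids <- function(g, v) {
  if (length(v) == 0L) return(integer(0))
  if (is.character(v)) {
    idx <- match(v, graph_labels(g))
    if (anyNA(idx)) {
      stop("unknown vertex name(s): ", paste(v[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    return(idx)
  }
  idx <- as.integer(v)
  if (anyNA(idx) || any(idx < 1L) || any(idx > igraph::vcount(g))) {
    stop("vertex index out of range", call. = FALSE)
  }
  idx
}

alive_mask <- function(n, removed) {
  alive <- rep(TRUE, n)
  alive[removed] <- FALSE
  alive
}

# Shared target selection for adaptive removal: largest score, then largest
# value of the secondary key (residual degree, intra-degree, ...), then a
# uniform random draw from the current RNG stream. Exact ties only.
pick_target <- function(score, key, alive) {
  idx <- which(alive)
  s <- score[idx]
  cand <- idx[s == max(s)]
  if (length(cand) > 1L) {
    k2 <- key[cand]
    cand <- cand[k2 == max(k2)]
  }
  if (length(cand) > 1L) cand <- cand[sample.int(length(cand), 1L)]
  cand
}

# Adaptive max-degree removal of every remaining alive node (used for the
# tail of every schedule so that G(q) is defined on all of [0, 1]).
degree_tail <- function(adj, alive) {
  ord <- integer(sum(alive))
  k <- 0L
  while (any(alive)) {
    deg <- cpp_residual_degree(adj, alive)
    v <- pick_target(deg, deg, alive)
    k <- k + 1L
    ord[k] <- v
    alive[v] <- FALSE
  }
  ord
}

# Adaptive max-degree removal until the residual LCC has at most `thresh`
# nodes (CbCI fallback phase once the coarse graph has no edges).
remove_by_degree <- function(adj, alive, thresh) {
  ord <- integer(0)
  while (any(alive) && cpp_lcc_size(adj, alive) > thresh) {
    deg <- cpp_residual_degree(adj, alive)
    v <- pick_target(deg, deg, alive)
    ord <- c(ord, v)
    alive[v] <- FALSE
  }
  list(order = ord, alive = alive)
}
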