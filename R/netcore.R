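#' Read an undirected simple graph from a plain edge list
#'
#' Each non-comment line must start with two integer node ids separated by
#' whitespace or tabs; anything after the second column is ignored. Lines
#' starting with `#` and blank lines are skipped. Self-loops and duplicate
#' edges are dropped silently, and edge direction is ignored. Original node
#' ids are preserved as vertex names; internal vertex indices are contiguous
#' `1..N` in increasing order of the input ids.
#'
#' @param path Path to the edge-list file.
#' @param one_based Declares the id dialect of the file. Ids are preserved
#'   verbatim as vertex names either way; the flag is only recorded so that
#'   downstream tooling can report it.
#' @return An undirected simple `igraph` graph with a `name` vertex attribute.
#' @export
read_edge_list <- function(path, one_based = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) {
    stop("empty edge list: ", path, call. = FALSE)
  }
  toks <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(toks, length, 0L) < 2L)
  ends <- suppressWarnings(
    vapply(toks, function(tk) as.integer(tk[1:2]), integer(2))
  )
  bad <- union(bad, which(colSums(is.na(ends)) > 0L))
  if (length(bad) > 0L) {
    stop("unparseable edge-list line ", line_no[min(bad)], ": '",
         lines[min(bad)], "'", call. = FALSE)
  }
  g <- graph_from_pairs(ends[1, ], ends[2, ])
  igraph::graph_attr(g, "one_based") <- isTRUE(one_based)
  g
}

# Build a simple undirected igraph from integer endpoint vectors, labelling
# vertices with the original ids (sorted numerically).
graph_from_pairs <- function(a, b) {
  labs <- sort(unique(c(a, b)))
  g <- igraph::make_empty_graph(n = length(labs), directed = FALSE)
  g <- igraph::add_edges(g, rbind(match(a, labs), match(b, labs)))
  igraph::V(g)$name <- as.character(labs)
  igraph::simplify(g)
}

#' Write a graph as a plain edge list
#'
#' Inverse of [read_edge_list()]: one `"a b"` line per edge, using the
#' original vertex names.
#'
#' @param g An undirected simple igraph graph.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  check_graph(g)
  el <- igraph::as_edgelist(g, names = TRUE)
  writeLines(paste(el[, 1], el[, 2]), path)
  invisible(path)
}

#' Restrict a graph to its largest connected component
#'
#' Mirrors the usual preprocessing of empirical networks before a
#' dismantling run: the graph is reduced to the subgraph induced by its
#' largest connected component. If several components tie for the largest
#' size, the one containing the smallest node id wins, which keeps the
#' operation deterministic.
#'
#' @param g An undirected simple igraph graph.
#' @return The induced subgraph of the largest component.
#' @export
preprocess_network <- function(g) {
  check_graph(g)
  if (igraph::vcount(g) == 0L) stop("empty graph", call. = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    labs <- graph_labels(g)
    key <- suppressWarnings(as.numeric(labs))
    if (anyNA(key)) key <- rank(labs)
    min_id <- vapply(best, function(cc) min(key[comp$membership == cc]), 0)
    best <- best[which.min(min_id)]
  }
  igraph::induced_subgraph(g, which(comp$membership == best))
}

#' Size of the largest connected component of a residual graph
#'
#' @param g An undirected simple igraph graph.
#' @param removed Removed nodes (internal indices or vertex names); the size
#'   is measured on the subgraph induced by the remaining nodes.
#' @return Integer count (0 if all nodes are removed).
#' @export
lcc_size <- function(g, removed = integer()) {
  check_graph(g)
  adj <- graph_adjlist(g)
  cpp_lcc_size(adj, alive_mask(length(adj), resolve_vids(g, removed)))
}

#' Ball frontier of a node
#'
#' The set of nodes at shortest-path distance exactly `ell` from `i` in the
#' residual graph (the frontier of the radius-`ell` ball used by collective
#' influence). `ell = 0` returns `i` itself.
#'
#' @param g An undirected simple igraph graph.
#' @param i Focal node (internal index or vertex name).
#' @param ell Non-negative integer radius.
#' @param removed Removed nodes, as in [lcc_size()].
#' @return Sorted integer vector of internal vertex indices.
#' @export
ball_frontier <- function(g, i, ell, removed = integer()) {
  check_graph(g)
  stopifnot(length(ell) == 1L, ell >= 0)
  i <- resolve_vids(g, i)
  stopifnot(length(i) == 1L)
  rem <- resolve_vids(g, removed)
  if (i %in% rem) stop("focal node is removed", call. = FALSE)
  adj <- graph_adjlist(g)
  as.integer(cpp_ball_frontier(adj, alive_mask(length(adj), rem), i,
                               as.integer(ell)))
}
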