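#' Collective influence score
#'
#' The collective influence of node \eqn{i} at radius \eqn{\ell} is
#' \deqn{\mathrm{CI}_\ell(i) = (k_i - 1) \sum_{j \in \partial B(i,\ell)} (k_j - 1),}
#' where \eqn{\partial B(i,\ell)} is the set of nodes at shortest-path
#' distance exactly \eqn{\ell} from \eqn{i} and degrees are taken on the
#' residual graph (removed nodes excluded). For \eqn{\ell = 0} the score is
#' \eqn{k_i - 1}, which is rank-equivalent to the degree. High-CI nodes are
#' the strongest contributors to the stability of the giant component, so
#' removing them first fragments the network quickly.
#'
#' @param g An undirected simple igraph graph.
#' @param i Focal node (internal index or vertex name).
#' @param ell Non-negative ball radius (default 2).
#' @param removed Removed nodes (internal indices or vertex names).
#' @return Numeric score for `ci_score`; for `ci_scores` a numeric vector
#'   over all nodes, `NA` at removed nodes.
#' @export
ci_score <- function(g, i, ell = 2, removed = integer()) {
  check_graph(g)
  i <- resolve_vids(g, i)
  stopifnot(length(i) == 1L)
  rem <- resolve_vids(g, removed)
  if (i %in% rem) stop("focal node is removed", call. = FALSE)
  adj <- graph_adjlist(g)
  alive <- alive_mask(length(adj), rem)
  cpp_ci_scores(adj, alive, as.integer(ell))[i]
}

#' @rdname ci_score
#' @export
ci_scores <- function(g, ell = 2, removed = integer()) {
  check_graph(g)
  adj <- graph_adjlist(g)
  alive <- alive_mask(length(adj), resolve_vids(g, removed))
  sc <- cpp_ci_scores(adj, alive, as.integer(ell))
  names(sc) <- graph_labels(g)
  sc
}

#' Adaptive collective-influence removal schedule
#'
#' Repeatedly removes an alive node of maximal \eqn{\mathrm{CI}_\ell}
#' (recomputing all scores on the residual graph after every removal) until
#' the largest connected component first contains at most
#' `stop_frac * N` nodes. Ties are broken by largest residual degree, then
#' uniformly at random under `seed`. After the stopping point the remaining
#' nodes are appended by adaptive maximum-degree removal so that the
#' percolation curve is defined up to \eqn{q = 1}.
#'
#' The returned order is the tentative (pre-reinsertion) schedule; pass it
#' through [reinsert()] to apply the greedy reinsertion refinement.
#'
#' @param g A connected, undirected, simple igraph graph (see
#'   [preprocess_network()]).
#' @param ell Ball radius (default 2).
#' @param stop_frac Stopping fraction for the LCC (default 0.01).
#' @param seed Tie-break seed.
#' @return A [new_schedule()] object.
#' @export
ci_schedule <- function(g, ell = 2, stop_frac = 0.01, seed = NULL) {
  check_graph(g)
  stopifnot(ell >= 0, stop_frac > 0, stop_frac < 1)
  adj <- graph_adjlist(g)
  n <- length(adj)
  thresh <- stop_frac * n
  with_seed(seed, {
    alive <- rep(TRUE, n)
    ord <- integer(n)
    k <- 0L
    while (any(alive) && cpp_lcc_size(adj, alive) > thresh) {
      sc <- cpp_ci_scores(adj, alive, as.integer(ell))
      deg <- cpp_residual_degree(adj, alive)
      v <- pick_target(sc, deg, alive)
      k <- k + 1L
      ord[k] <- v
      alive[v] <- FALSE
    }
    nt <- k
    if (any(alive)) ord[(k + 1L):n] <- degree_tail(adj, alive)
    new_schedule(ord, nt, "ci",
                 params = list(ell = ell, stop_frac = stop_frac),
                 seed = seed, labels = graph_labels(g))
  })
}

#' Greedy component-count reinsertion
#'
#' Refines a tentative removal order. Starting from the residual network at
#' the stopping point, each still-removed node is scored by the number of
#' distinct alive components among its neighbours (0 if it has none), the
#' node connecting the fewest components is added back (ties broken at
#' random under `seed`), and components are updated; this repeats until the
#' network is restored. The final removal order is the reverse of the
#' reinsertion sequence, with the schedule's tail left untouched.
#'
#' @param g The graph the schedule was computed on.
#' @param schedule A [new_schedule()] object produced by a schedule
#'   function.
#' @param seed Tie-break seed.
#' @return A new `removal_schedule` with reordered targeted removals.
#' @export
reinsert <- function(g, schedule, seed = NULL) {
  counter <- function(r, adj, alive, comp, ctx) {
    nb <- adj[[r]]
    nb <- nb[alive[nb]]
    length(unique(comp[nb]))
  }
  reinsert_engine(g, schedule, counter, seed, tag = "component_count")
}

# `prep(alive, comp)` builds per-iteration context handed to
# `counter(r, adj, alive, comp, ctx)`; lets counters precompute
# per-component summaries once instead of per candidate.
reinsert_engine <- function(g, schedule, counter, seed, tag, prep = NULL) {
  check_graph(g)
  stopifnot(inherits(schedule, "removal_schedule"))
  adj <- graph_adjlist(g)
  n <- length(adj)
  if (schedule$n != n) stop("schedule does not match graph", call. = FALSE)
  nt <- schedule$n_targeted
  if (nt <= 1L) return(schedule)
  removed <- schedule$order[seq_len(nt)]
  alive <- alive_mask(n, removed)
  with_seed(seed, {
    remaining <- removed
    reins <- integer(nt)
    k <- 0L
    while (length(remaining) > 0L) {
      comp <- cpp_components(adj, alive)
      ctx <- if (is.null(prep)) NULL else prep(alive, comp)
      counts <- vapply(remaining, counter, numeric(1),
                       adj = adj, alive = alive, comp = comp, ctx = ctx)
      cand <- remaining[counts == min(counts)]
      pick <- if (length(cand) > 1L) cand[sample.int(length(cand), 1L)] else cand
      alive[pick] <- TRUE
      k <- k + 1L
      reins[k] <- pick
      remaining <- remaining[remaining != pick]
    }
    ord <- c(rev(reins), schedule$order[seq.int(nt + 1L, length.out = n - nt)])
    params <- schedule$params
    params$reinsertion <- tag
    new_schedule(ord, nt, schedule$strategy, params = params,
                 seed = schedule$seed, labels = schedule$labels)
  })
}
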