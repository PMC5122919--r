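#' Run one immunization strategy end to end
#'
#' Dispatches to the requested schedule function and, for the CI and CbCI
#' strategies, applies the matching reinsertion refinement (component-count
#' for CI, community-count for CbCI). Community-based strategies require a
#' partition.
#'
#' @param g A connected, undirected, simple igraph graph.
#' @param strategy One of `"ci"`, `"cbci"`, `"degree"`, `"betweenness"`,
#'   `"cbdi"`, `"lsp"`.
#' @param partition A [node_partition()] (required for `"cbci"` and
#'   `"cbdi"`).
#' @param ell Ball radius for CI / CbCI (default 2).
#' @param stop_frac LCC stopping fraction for the adaptive strategies
#'   (default 0.01).
#' @param lsp_theta Final LCC fraction for LSP (default 0.01).
#' @param seed Seed; two sub-seeds are derived from it for the schedule and
#'   the reinsertion pass.
#' @param reinsertion Apply reinsertion for CI / CbCI (default `TRUE`).
#' @return A `removal_schedule`.
#' @export
immunize <- function(g, strategy = c("ci", "cbci", "degree", "betweenness",
                                     "cbdi", "lsp"),
                     partition = NULL, ell = 2, stop_frac = 0.01,
                     lsp_theta = 0.01, seed = NULL, reinsertion = TRUE) {
  strategy <- match.arg(strategy)
  if (strategy %in% c("cbci", "cbdi") && is.null(partition)) {
    stop("strategy '", strategy, "' needs a partition", call. = FALSE)
  }
  seeds <- if (is.null(seed)) list(NULL, NULL) else {
    as.list(with_seed(seed, sample.int(2^20, 2L)))
  }
  switch(strategy,
    ci = {
      s <- ci_schedule(g, ell = ell, stop_frac = stop_frac, seed = seeds[[1]])
      if (reinsertion) reinsert(g, s, seed = seeds[[2]]) else s
    },
    cbci = {
      s <- cbci_schedule(g, partition, ell = ell, stop_frac = stop_frac,
                         seed = seeds[[1]])
      if (reinsertion) community_reinsert(g, partition, s, seed = seeds[[2]])
      else s
    },
    degree = degree_schedule(g, stop_frac = stop_frac, seed = seeds[[1]]),
    betweenness = betweenness_schedule(g, stop_frac = stop_frac,
                                       seed = seeds[[1]]),
    cbdi = cbdi_schedule(g, partition, stop_frac = stop_frac,
                         seed = seeds[[1]]),
    lsp = lsp_schedule(g, theta = lsp_theta, seed = seeds[[1]])
  )
}

#' Run a full immunization experiment
#'
#' Orchestrates one experiment: load or generate a network, preprocess it
#' to its largest component, obtain a partition if any community-based
#' strategy is requested, run every strategy, and write per-strategy
#' artifacts (schedule + JSON metadata, percolation-curve CSV, summary
#' JSON), a comparison table and a manifest that allows byte-identical
#' replay.
#'
#' @param out_prefix Path prefix for all output files.
#' @param edges Path to an edge-list file (mutually exclusive with
#'   `synth`).
#' @param one_based Id dialect flag for `edges`, recorded in the manifest.
#' @param synth `NULL`, `"ba"` or `"community"`: generate the input
#'   network instead of reading it.
#' @param synth_args Named list of generator arguments (see
#'   [ba_network()] and [community_sf_network()]).
#' @param strategies Character vector of strategy names (see
#'   [immunize()]).
#' @param detect Community-detection method (see [detect_communities()]),
#'   `"truth"` for the generator's ground-truth partition, or `NULL`.
#' @param partition_file External partition TSV (mutually exclusive with
#'   `detect`).
#' @param ell,stop_frac,lsp_theta,reinsertion Passed to [immunize()].
#' @param theta Fragmentation threshold for the comparison table
#'   (default 0.05).
#' @param seed Global seed; per-strategy sub-seeds are derived from it.
#' @return Invisibly, a list with the graph, partition, schedules, curves
#'   and the comparison table.
#' @export
run_experiment <- function(out_prefix,
                           edges = NULL, one_based = FALSE,
                           synth = NULL, synth_args = list(),
                           strategies = "ci",
                           detect = NULL, partition_file = NULL,
                           ell = 2, theta = 0.05, stop_frac = 0.01,
                           lsp_theta = 0.01, reinsertion = TRUE,
                           seed = 1L) {
  if (is.null(edges) == is.null(synth)) {
    stop("give exactly one input: `edges` or `synth`", call. = FALSE)
  }
  if (!is.null(detect) && !is.null(partition_file)) {
    stop("`detect` and `partition_file` are mutually exclusive",
         call. = FALSE)
  }
  if (length(strategies) < 1L) stop("no strategies requested", call. = FALSE)

  sub_seeds <- with_seed(seed, sample.int(2^20, length(strategies) + 2L))
  truth <- NULL
  if (!is.null(synth)) {
    synth <- match.arg(synth, c("ba", "community"))
    if (synth == "ba") {
      g0 <- do.call(ba_network, c(synth_args, list(seed = sub_seeds[1])))
    } else {
      gen <- do.call(community_sf_network,
                     c(synth_args, list(seed = sub_seeds[1])))
      g0 <- gen$graph
      truth <- gen$partition
    }
  } else {
    g0 <- read_edge_list(edges, one_based = one_based)
  }
  g <- preprocess_network(g0)
  if (!is.null(truth)) {
    keep <- match(graph_labels(g), graph_labels(g0))
    truth <- node_partition(
      truth$community_labels[truth$membership][keep], method = "ground_truth")
  }

  partition <- NULL
  needs_partition <- any(strategies %in% c("cbci", "cbdi"))
  if (!is.null(partition_file)) {
    partition <- read_partition(partition_file, g)
  } else if (!is.null(detect)) {
    if (identical(detect, "truth")) {
      if (is.null(truth)) {
        stop("detect = 'truth' needs synth = 'community'", call. = FALSE)
      }
      partition <- truth
    } else {
      partition <- detect_communities(g, method = detect,
                                      seed = sub_seeds[2])
    }
  } else if (needs_partition) {
    stop("community-based strategies need `detect` or `partition_file`",
         call. = FALSE)
  }

  schedules <- list()
  curves <- list()
  for (si in seq_along(strategies)) {
    nm <- strategies[si]
    sched <- immunize(g, strategy = nm, partition = partition, ell = ell,
                      stop_frac = stop_frac, lsp_theta = lsp_theta,
                      seed = sub_seeds[si + 2L], reinsertion = reinsertion)
    schedules[[nm]] <- sched
    cv <- removal_curve(g, sched)
    curves[[nm]] <- cv
    write_schedule(sched, paste0(out_prefix, "_", nm, "_schedule.txt"))
    utils::write.csv(as.data.frame(cv),
                     paste0(out_prefix, "_", nm, "_curve.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(strategy = nm, q_c = q_critical(cv, theta),
           F = integrated_lcc(cv), theta = theta,
           seed = sub_seeds[si + 2L], params = sched$params),
      paste0(out_prefix, "_", nm, "_summary.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
  }

  reference <- if ("ci" %in% strategies) "ci" else NULL
  tab <- compare_strategies(g, schedules, theta = theta,
                            reference = reference)
  utils::write.csv(tab, paste0(out_prefix, "_comparison.csv"),
                   row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("cbci")),
    seed = seed, sub_seeds = sub_seeds,
    input = if (is.null(synth)) list(edges = edges, one_based = one_based)
            else list(synth = synth, synth_args = synth_args),
    n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
    strategies = strategies,
    partition = if (is.null(partition)) NULL else partition$method,
    params = list(ell = ell, theta = theta, stop_frac = stop_frac,
                  lsp_theta = lsp_theta, reinsertion = reinsertion))
  jsonlite::write_json(manifest, paste0(out_prefix, "_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(graph = g, partition = partition, schedules = schedules,
                 curves = curves, comparison = tab, manifest = manifest))
}
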