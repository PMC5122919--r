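#' Removal schedules
#'
#' A `removal_schedule` records the order in which an immunization strategy
#' removes nodes. The first `n_targeted` entries are the nodes removed by the
#' strategy proper, up to the point where the largest connected component
#' (LCC) first reaches its stopping size; the remaining entries are a
#' degree-adaptive tail appended so that the percolation curve \eqn{G(q)} is
#' defined on all of \eqn{[0, 1]}.
#'
#' @param order Integer vector: a permutation of the internal vertex indices
#'   `1..N` of the source graph.
#' @param n_targeted Number of leading entries removed before the stopping
#'   condition was met.
#' @param strategy Strategy name (e.g. `"ci"`, `"cbci"`).
#' @param params Named list of strategy parameters.
#' @param seed Seed used for tie-breaking, or `NULL`.
#' @param labels Character vector of original vertex labels, parallel to the
#'   internal indices.
#'
#' @return An object of class `removal_schedule` with fields `order`,
#'   `n_targeted`, `strategy`, `params`, `seed`, `labels` and `n`.
#' @export
new_schedule <- function(order, n_targeted, strategy, params = list(),
                         seed = NULL, labels = as.character(seq_along(order))) {
  order <- as.integer(order)
  n <- length(order)
  if (anyDuplicated(order) || any(order < 1L) || any(order > n)) {
    stop("`order` must be a permutation of 1..N", call. = FALSE)
  }
  stopifnot(n_targeted >= 0L, n_targeted <= n, length(labels) == n)
  structure(
    list(order = order, n_targeted = as.integer(n_targeted),
         strategy = strategy, params = params, seed = seed,
         labels = as.character(labels), n = n),
    class = "removal_schedule"
  )
}

#' @export
print.removal_schedule <- function(x, ...) {
  cat("Removal schedule (", x$strategy, "), N = ", x$n,
      ", targeted removals = ", x$n_targeted, "\n", sep = "")
  k <- min(10L, x$n)
  cat("first removals:", paste(x$labels[x$order[seq_len(k)]], collapse = " "),
      if (x$n > k) "...\n" else "\n")
  invisible(x)
}

#' Original node labels of a schedule, in removal order
#'
#' @param schedule A `removal_schedule`.
#' @param targeted_only If `TRUE`, return only the removals made before the
#'   stopping condition (i.e. drop the appended tail).
#' @return Character vector of node labels.
#' @export
schedule_labels <- function(schedule, targeted_only = FALSE) {
  stopifnot(inherits(schedule, "removal_schedule"))
  ord <- schedule$order
  if (targeted_only) ord <- ord[seq_len(schedule$n_targeted)]
  schedule$labels[ord]
}

#' Write / read a removal schedule
#'
#' The schedule is serialized as one node label per line at `path`, together
#' with a JSON metadata header at `paste0(path, ".json")` recording the
#' strategy, parameters, seed and stopping index.
#'
#' @param schedule A `removal_schedule`.
#' @param path Output file for the node order.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "removal_schedule"))
  writeLines(schedule$labels[schedule$order], path)
  meta <- list(strategy = schedule$strategy,
               params = schedule$params,
               seed = schedule$seed,
               n = schedule$n,
               n_targeted = schedule$n_targeted)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_schedule
#' @param g The graph the schedule refers to (labels must match).
#' @export
read_schedule <- function(path, g) {
  check_graph(g)
  labs <- graph_labels(g)
  lines <- readLines(path)
  ord <- match(lines, labs)
  if (anyNA(ord)) {
    stop("schedule labels not found in graph: ",
         paste(utils::head(lines[is.na(ord)], 5), collapse = ", "),
         call. = FALSE)
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(strategy = "external", params = list(), seed = NULL,
         n_targeted = length(ord))
  }
  new_schedule(ord, n_targeted = meta$n_targeted, strategy = meta$strategy,
               params = as.list(meta$params), seed = meta$seed, labels = labs)
}
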