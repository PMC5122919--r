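#' Percolation curve of a removal schedule
#'
#' Replays a schedule and records \eqn{G_n}, the size of the largest
#' connected component after the first \eqn{n} removals divided by
#' \eqn{N}, for \eqn{n = 0..N}. Computed with an incremental union-find on
#' the reversed order, which is exactly equivalent to recomputing
#' components from scratch at every step.
#'
#' @param g The graph the schedule was computed on.
#' @param schedule A `removal_schedule`, or an integer permutation of
#'   `1..N`.
#' @return An object of class `removal_curve`: a data frame with columns
#'   `n`, `q = n/N` and `G`, plus attributes `N` and `strategy`.
#' @export
removal_curve <- function(g, schedule) {
  check_graph(g)
  adj <- graph_adjlist(g)
  n <- length(adj)
  if (inherits(schedule, "removal_schedule")) {
    ord <- schedule$order
    strategy <- schedule$strategy
  } else {
    ord <- as.integer(schedule)
    strategy <- "order"
  }
  if (length(ord) != n || anyDuplicated(ord) ||
      any(ord < 1L) || any(ord > n)) {
    stop("schedule must cover every node of `g` exactly once", call. = FALSE)
  }
  counts <- cpp_removal_curve(adj, ord)
  out <- data.frame(n = 0:n, q = (0:n) / n, G = counts / n)
  attr(out, "N") <- n
  attr(out, "strategy") <- strategy
  class(out) <- c("removal_curve", "data.frame")
  out
}

#' @export
print.removal_curve <- function(x, ...) {
  cat("Removal curve (", attr(x, "strategy"), "), N = ", attr(x, "N"),
      ", q_c(0.05) = ", format(q_critical(x), digits = 4),
      ", F = ", format(integrated_lcc(x), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.removal_curve <- function(x, ..., theta = 0.05) {
  plot(x$q, x$G, type = "l", xlab = "q (fraction removed)",
       ylab = "G(q) (LCC fraction)", ylim = c(0, 1), ...)
  graphics::abline(h = theta, lty = 3)
  invisible(x)
}

#' Critical removal fraction
#'
#' The smallest fraction of removed nodes at which the LCC first holds at
#' most a fraction `theta` of the nodes:
#' \eqn{q_c = \min\{n/N : G_n \le \theta\}}. Always defined because
#' \eqn{G_N = 0}.
#'
#' @param curve A [removal_curve()].
#' @param theta Fragmentation threshold (default 0.05).
#' @return Fraction in `(0, 1]` (0 only if `theta >= 1`).
#' @export
q_critical <- function(curve, theta = 0.05) {
  stopifnot(inherits(curve, "removal_curve"), theta > 0)
  min(curve$q[curve$G <= theta])
}

#' Integrated LCC size
#'
#' The area under the percolation curve,
#' \deqn{F = \frac{1}{N} \sum_{n=1}^{N} G_n,} i.e. the left-excluded
#' Riemann sum of \eqn{G(q)} over \eqn{q \in [0, 1]}. Because
#' \eqn{G_n \le \min(1, (N-n)/N)}, \eqn{F} lies in \eqn{[0, 1/2]}; smaller
#' values mean faster fragmentation.
#'
#' @param curve A [removal_curve()].
#' @return Numeric value in `[0, 1/2]`.
#' @export
integrated_lcc <- function(curve) {
  stopifnot(inherits(curve, "removal_curve"))
  sum(curve$G[-1]) / attr(curve, "N")
}

#' Compare strategies on one network
#'
#' Computes \eqn{q_c} and the integrated LCC \eqn{F} for each schedule and,
#' when a `reference` strategy is named, the per-strategy ratios against
#' it (values below 1 mean the strategy fragments the network earlier than
#' the reference).
#'
#' @param g The common source graph.
#' @param schedules Named list of `removal_schedule` objects.
#' @param theta Threshold for [q_critical()] (default 0.05).
#' @param reference Name of the reference row for ratio columns (usually
#'   `"ci"`), or `NULL` for no ratios.
#' @return A data frame with one row per strategy.
#' @export
compare_strategies <- function(g, schedules, theta = 0.05, reference = NULL) {
  stopifnot(is.list(schedules), length(schedules) >= 1L,
            !is.null(names(schedules)))
  rows <- lapply(names(schedules), function(nm) {
    cv <- removal_curve(g, schedules[[nm]])
    data.frame(strategy = nm,
               q_c = q_critical(cv, theta),
               F = integrated_lcc(cv),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(reference)) {
    if (!reference %in% tab$strategy) {
      stop("reference strategy '", reference, "' not among the schedules",
           call. = FALSE)
    }
    ref <- tab[tab$strategy == reference, ]
    tab$q_c_ratio <- tab$q_c / ref$q_c
    tab$F_ratio <- tab$F / ref$F
  }
  tab
}

#' Pearson correlations between partition diagnostics and performance
#'
#' Generic helper for relating partition diagnostics (entropy, modularity,
#' coarse clustering, number of communities, ...) to dismantling
#' performance across a collection of runs: one row per run, diagnostic
#' columns plus a performance column (e.g. \eqn{q_c} normalized by the CI
#' value).
#'
#' @param runs Data frame of runs.
#' @param diagnostics Character vector of diagnostic column names.
#' @param measure Name of the performance column.
#' @return Data frame with columns `diagnostic` and `r`.
#' @export
correlate_diagnostics <- function(runs, diagnostics, measure) {
  stopifnot(is.data.frame(runs), measure %in% names(runs),
            all(diagnostics %in% names(runs)))
  r <- vapply(diagnostics,
              function(d) stats::cor(runs[[d]], runs[[measure]],
                                     method = "pearson"),
              numeric(1))
  data.frame(diagnostic = diagnostics, r = unname(r),
             stringsAsFactors = FALSE)
}
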