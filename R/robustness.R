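#' Local-extinction simulation by random node removal
#'
#' Removes `n_removed` nodes and measures fragmentation of the induced
#' subgraph: the proportion of replicates that stay fully connected, and
#' the size of the largest component as a fraction of the surviving node
#' count. When the number of distinct removal subsets is at most
#' `max_reps`, all subsets are enumerated (deterministic); otherwise
#' `max_reps` distinct subsets are sampled uniformly under `seed`. The 95%
#' confidence interval on the largest-component proportion is the normal
#' approximation mean +/- 1.96 SE (degenerate when all replicates agree).
#' A single surviving node counts as a connected graph of size 1.
#'
#' @param graph a `population_graph` or igraph, connected before removal
#' @param n_removed number of nodes to remove (1 to n-2)
#' @param max_reps replicate ceiling (default 100)
#' @param seed integer seed (sampled mode only)
#' @return list: `n_removed`, `n_reps`, `exhaustive`, `prop_connected`,
#'   `mean_lcp`, `ci_lo`, `ci_hi`, `seed`
#' @export
node_removal_simulation <- function(graph, n_removed, max_reps = 100L,
                                    seed = 1L) {
  g <- as_igraph(graph)
  n <- igraph::vcount(g)
  if (n_removed < 1L || n_removed > n - 2L)
    stop("n_removed must lie between 1 and n - 2")
  stopifnot(max_reps >= 1L)
  n_subsets <- choose(n, n_removed)
  if (n_subsets <= max_reps) {
    subsets <- utils::combn(n, n_removed, simplify = FALSE)
    exhaustive <- TRUE
  } else {
    set.seed(seed)
    seen <- new.env(hash = TRUE)
    subsets <- list()
    while (length(subsets) < max_reps) {
      s <- sort(sample.int(n, n_removed))
      key <- paste(s, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        subsets[[length(subsets) + 1L]] <- s
      }
    }
    exhaustive <- FALSE
  }
  n_kept <- n - n_removed
  res <- vapply(subsets, function(s) {
    sub <- igraph::delete_vertices(g, s)
    comp <- igraph::components(sub)
    c(connected = as.numeric(comp$no == 1L),
      lcp = max(comp$csize) / n_kept)
  }, numeric(2))
  lcp <- res["lcp", ]
  se <- if (length(lcp) > 1L) stats::sd(lcp) / sqrt(length(lcp)) else 0
  if (!is.finite(se)) se <- 0
  list(n_removed = n_removed, n_reps = length(subsets),
       exhaustive = exhaustive,
       prop_connected = mean(res["connected", ]),
       mean_lcp = mean(lcp),
       ci_lo = mean(lcp) - 1.96 * se,
       ci_hi = mean(lcp) + 1.96 * se,
       seed = seed)
}

#' Node-removal profile over all removal intensities
#'
#' Runs [node_removal_simulation()] for every `n_removed` from 1 to n-2
#' and assembles a plot-ready table.
#'
#' @param graph a `population_graph` or igraph
#' @param max_reps replicate ceiling per scenario
#' @param seed integer seed
#' @return data.frame: n_removed, n_reps, exhaustive, prop_connected,
#'   mean_lcp, ci_lo, ci_hi
#' @export
removal_profile <- function(graph, max_reps = 100L, seed = 1L) {
  g <- as_igraph(graph)
  n <- igraph::vcount(g)
  rows <- lapply(seq_len(n - 2L), function(k)
    as.data.frame(node_removal_simulation(g, k, max_reps = max_reps,
                                          seed = seed + k)[
      c("n_removed", "n_reps", "exhaustive", "prop_connected",
        "mean_lcp", "ci_lo", "ci_hi")]))
  do.call(rbind, rows)
}
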