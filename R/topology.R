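as_igraph <- function(graph) {
  if (inherits(graph, "population_graph")) graph$graph else graph
}

#' Node degree (unweighted)
#' @param graph a `population_graph` or igraph
#' @return named integer vector
#' @export
node_degree <- function(graph) {
  igraph::degree(as_igraph(graph))
}

#' Node strength (sum of incident flow weights)
#'
#' Uses the `flow` edge attribute (association index, 1 - D_PS) when
#' present, else the `weight` attribute, else falls back to degree.
#'
#' @param graph a `population_graph` or igraph
#' @return named numeric vector
#' @export
node_strength <- function(graph) {
  g <- as_igraph(graph)
  w <- if ("flow" %in% igraph::edge_attr_names(g)) igraph::E(g)$flow
       else if ("weight" %in% igraph::edge_attr_names(g)) igraph::E(g)$weight
       else rep(1, igraph::ecount(g))
  igraph::strength(g, weights = w)
}

#' Shortest-path betweenness with fractional tie credit
#'
#' Counts, for each node, the shortest paths between other node pairs that
#' run through it, crediting 1/k to each of k tied shortest paths.
#' Weighted mode uses the `weight` edge attribute as path length.
#'
#' @param graph a `population_graph` or igraph
#' @param use_weights logical; weighted shortest paths
#' @return named numeric vector
#' @export
node_betweenness <- function(graph, use_weights = FALSE) {
  g <- as_igraph(graph)
  if (use_weights) {
    w <- igraph::E(g)$weight
    if (any(w < 0)) stop("negative edge weights not allowed")
  } else {
    w <- rep(1, igraph::ecount(g))
  }
  igraph::betweenness(g, weights = w)
}

#' Modularity of a partition on the binary topology
#'
#' `Q = sum_c (e_cc - a_c^2)` over communities, with `e_cc` the fraction of
#' edges inside community c and `a_c` the fraction of edge ends attached
#' to it. Edge weights are ignored (the community analysis runs on the
#' binary pruned network).
#'
#' @param graph a `population_graph` or igraph
#' @param partition named membership vector (node -> community id)
#' @return Q
#' @export
graph_modularity <- function(graph, partition) {
  g <- as_igraph(graph)
  if (igraph::ecount(g) == 0L) stop("modularity undefined on an empty graph")
  memb <- partition[igraph::V(g)$name]
  if (anyNA(memb)) stop("partition must cover all nodes")
  igraph::modularity(g, membership = as.integer(factor(memb)),
                     weights = rep(1, igraph::ecount(g)))
}

#' Community detection by leading-eigenvector modularity optimisation
#'
#' Recursive spectral splits of the modularity matrix; reports the
#' partition and Q for each community count from 2 to `k_max` (obtained by
#' cutting the split hierarchy) and the best-Q partition. Ties in the
#' argmax are broken toward fewer clusters.
#'
#' @param graph a `population_graph` or igraph (binary topology)
#' @param k_max largest community count to report (>= 2)
#' @return list with `by_k` (list of k -> list(partition, Q)),
#'   `best` (list(partition, Q, k)), and the igraph communities object
#' @export
eigen_communities <- function(graph, k_max = 6L) {
  if (k_max < 2L) stop("k_max must be at least 2")
  g <- as_igraph(graph)
  cl <- igraph::cluster_leading_eigen(g, weights = NA)
  partition_candidates(g, cl, k_max)
}

#' Community detection by random-walk agglomeration (Walktrap)
#'
#' Agglomerative merging by random-walk distance; the reported partition is
#' the cut of the merge tree with maximal modularity (fewer clusters win
#' ties).
#'
#' @param graph a `population_graph` or igraph (binary topology)
#' @param walk_length random-walk length (default 4, minimum 2)
#' @param k_max largest community count to report
#' @return as [eigen_communities()]
#' @export
walktrap_communities <- function(graph, walk_length = 4L, k_max = 6L) {
  stopifnot(walk_length >= 2L)
  g <- as_igraph(graph)
  cl <- igraph::cluster_walktrap(g, weights = NA, steps = walk_length)
  partition_candidates(g, cl, k_max)
}

# Collect k = 2..k_max partitions from a communities object plus its own
# best split, score each by binary modularity, pick argmax (fewest
# clusters on ties).
partition_candidates <- function(g, cl, k_max) {
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(g)))
  grab <- function(memb) {
    memb <- stats::setNames(as.integer(factor(memb)), nodes)
    list(partition = memb,
         Q = igraph::modularity(g, membership = memb,
                                weights = rep(1, igraph::ecount(g))),
         k = length(unique(memb)))
  }
  cands <- list(grab(igraph::membership(cl)))
  if (!is.null(cl$merges) && nrow(cl$merges) > 0) {
    for (k in 2:min(k_max, igraph::vcount(g))) {
      memb <- tryCatch(suppressWarnings(igraph::cut_at(cl, no = k)),
                       error = function(e) NULL)
      if (!is.null(memb)) cands <- c(cands, list(grab(memb)))
    }
  }
  ks <- vapply(cands, `[[`, numeric(1), "k")
  cands <- cands[!duplicated(ks)]
  ks <- ks[!duplicated(ks)]
  by_k <- stats::setNames(cands, paste0("k", ks))
  qs <- vapply(cands, `[[`, numeric(1), "Q")
  ord <- order(-qs, ks)  # ties toward fewer clusters
  list(by_k = by_k, best = cands[[ord[1]]], communities = cl)
}

#' Discrete and continuous core-periphery analysis
#'
#' Fits the idealised core-periphery model: core nodes tied to everyone,
#' periphery nodes tied only to the core. For each core size k the core
#' set maximising the Pearson correlation between the off-diagonal
#' adjacency and the ideal pattern is found (exhaustively for n <= 20,
#' greedy with random restarts above); `concentration` is that maximal
#' correlation. Continuous coreness is the leading eigenvector of the
#' adjacency matrix (the least-squares `c_i c_j` fit), rescaled to [0, 1].
#'
#' @param graph a `population_graph` or igraph (binary topology)
#' @param seed seed for greedy restarts (large n only)
#' @param n_restarts greedy restarts when exhaustive search is infeasible
#' @return list: `by_size` data.frame (k, concentration), `best_size`,
#'   `concentration`, `core_set`, `coreness` (named, in [0,1])
#' @export
core_periphery <- function(graph, seed = 1L, n_restarts = 20L) {
  g <- as_igraph(graph)
  n <- igraph::vcount(g)
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  a <- (a > 0) + 0
  m <- sum(a) / 2
  npairs <- n * (n - 1) / 2
  if (m == 0 || m == npairs)
    stop("core-periphery concentration undefined on an empty or complete graph")

  # correlation between adjacency and ideal pattern given a periphery set,
  # from counts: pattern = 0 only on periphery-periphery pairs
  conc_for_periphery <- function(per) {
    np <- length(per)
    zero_pairs <- np * (np - 1) / 2
    one_pairs <- npairs - zero_pairs
    if (zero_pairs == 0 || one_pairs == 0) return(NA_real_)
    m_pp <- sum(a[per, per]) / 2      # edges inside periphery
    s_ap <- m - m_pp                  # sum A * P
    num <- s_ap - m * one_pairs / npairs
    den <- sqrt((m - m^2 / npairs) * (one_pairs - one_pairs^2 / npairs))
    num / den
  }

  best_core_for_k <- function(k) {
    if (n <= 20L) {
      combos <- utils::combn(n, n - k)  # enumerate periphery sets
      vals <- apply(combos, 2, conc_for_periphery)
      if (all(is.na(vals)))
        return(list(conc = NA_real_, core = setdiff(seq_len(n), combos[, 1])))
      i <- which.max(vals)
      list(conc = vals[i], core = setdiff(seq_len(n), combos[, i]))
    } else {
      best <- list(conc = -Inf, core = NULL)
      for (r in seq_len(n_restarts)) {
        core <- sample(n, k)
        repeat {
          improved <- FALSE
          for (ci in core) for (po in setdiff(seq_len(n), core)) {
            cand <- c(setdiff(core, ci), po)
            if (isTRUE(conc_for_periphery(setdiff(seq_len(n), cand)) >
                       conc_for_periphery(setdiff(seq_len(n), core)))) {
              core <- cand; improved <- TRUE
            }
          }
          if (!improved) break
        }
        v <- conc_for_periphery(setdiff(seq_len(n), core))
        if (isTRUE(v > best$conc)) best <- list(conc = v, core = core)
      }
      best
    }
  }

  set.seed(seed)
  ks <- seq_len(n - 1L)
  fits <- lapply(ks, best_core_for_k)
  conc <- vapply(fits, `[[`, numeric(1), "conc")
  by_size <- data.frame(k = ks, concentration = conc)
  ok <- which(is.finite(conc))
  ibest <- ok[which.max(conc[ok])]

  eig <- eigen(a, symmetric = TRUE)
  v1 <- eig$vectors[, 1]
  if (sum(v1) < 0) v1 <- -v1
  v1 <- abs(v1)
  coreness <- (v1 - min(v1)) / (max(v1) - min(v1))
  names(coreness) <- nodes

  list(by_size = by_size,
       best_size = ks[ibest],
       concentration = conc[ibest],
       core_set = nodes[fits[[ibest]]$core],
       coreness = coreness)
}

#' Full topology report for a population graph
#'
#' @param pg a `population_graph`
#' @param k_max community-count ceiling for both detection methods
#' @return list with per-node data.frame (`nodes`: degree, strength,
#'   betweenness, coreness, eigen/walktrap cluster), `eigen`, `walktrap`,
#'   and `core` analysis results
#' @export
topology_report <- function(pg, k_max = 6L) {
  eg <- eigen_communities(pg, k_max = k_max)
  wt <- walktrap_communities(pg, k_max = k_max)
  cp <- core_periphery(pg)
  nodes <- pg$nodes
  df <- data.frame(
    node = nodes,
    degree = node_degree(pg)[nodes],
    strength = node_strength(pg)[nodes],
    betweenness = node_betweenness(pg)[nodes],
    coreness = cp$coreness[nodes],
    cluster_eigen = eg$best$partition[nodes],
    cluster_walktrap = wt$best$partition[nodes],
    in_core = nodes %in% cp$core_set,
    row.names = NULL)
  list(nodes = df, eigen = eg, walktrap = wt, core = cp)
}

#' Write a topology report to per-node CSV plus JSON summary
#' @param report output of [topology_report()]
#' @param path base path; writes `<path>_nodes.csv` and `<path>.json`
#' @export
write_topology_report <- function(report, path) {
  utils::write.csv(report$nodes, paste0(path, "_nodes.csv"), row.names = FALSE)
  summary <- list(
    eigen = list(k = report$eigen$best$k, Q = report$eigen$best$Q),
    walktrap = list(k = report$walktrap$best$k, Q = report$walktrap$best$Q),
    core = list(best_size = report$core$best_size,
                concentration = report$core$concentration,
                core_set = report$core$core_set))
  jsonlite::write_json(summary, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
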