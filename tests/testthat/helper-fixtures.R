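# shared in-code fixtures for the test suite

# tiny genotype table: explicit allele pairs, optional missing entries
toy_genotypes <- function() {
  genotype_table(data.frame(
    individual = c("i1", "i2", "i3", "i4"),
    population = c("A", "A", "B", "B"),
    year = 2002L,
    locA.1 = c("1", "1", "2", "2"),
    locA.2 = c("1", "2", "2", "2"),
    locB.1 = c("3", "3", "4", NA),
    locB.2 = c("3", "3", "4", NA),
    stringsAsFactors = FALSE))
}

# genotype table where two pops are fixed for alternate alleles everywhere
fixed_pair_genotypes <- function(n = 10L, n_loci = 3L) {
  df <- data.frame(individual = sprintf("i%02d", seq_len(2 * n)),
                   population = rep(c("A", "B"), each = n),
                   year = 2002L)
  for (l in seq_len(n_loci)) {
    df[[sprintf("loc%d.1", l)]] <- rep(c("1", "2"), each = n)
    df[[sprintf("loc%d.2", l)]] <- rep(c("1", "2"), each = n)
  }
  genotype_table(df)
}

# unweighted igraph from an edge list given as a 2-column matrix of labels
graph_from_edges <- function(edges, nodes = NULL) {
  g <- igraph::graph_from_edgelist(as.matrix(edges), directed = FALSE)
  if (!is.null(nodes))
    g <- igraph::add_vertices(g, length(setdiff(nodes, igraph::V(g)$name)),
                              name = setdiff(nodes, igraph::V(g)$name))
  g
}

path_graph <- function(n) igraph::make_ring(n, circular = FALSE)

# idealised core-periphery graph: k core nodes tied to everyone,
# periphery tied only to the core
ideal_core_periphery <- function(k_core, n_periphery) {
  n <- k_core + n_periphery
  a <- matrix(0, n, n)
  a[seq_len(k_core), ] <- 1
  a[, seq_len(k_core)] <- 1
  diag(a) <- 0
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  igraph::V(g)$name <- c(paste0("core", seq_len(k_core)),
                         paste0("per", seq_len(n_periphery)))
  g
}

# brute-force all-pairs shortest paths by exhaustive path enumeration
brute_shortest_paths <- function(adj, weights) {
  n <- nrow(adj)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  recurse <- function(path, len) {
    tail <- path[length(path)]
    start <- path[1]
    if (len < best[start, tail]) best[start, tail] <<- len
    for (nxt in which(adj[tail, ] > 0)) {
      if (!(nxt %in% path)) recurse(c(path, nxt), len + weights[tail, nxt])
    }
  }
  for (s in seq_len(n)) recurse(s, 0)
  pmin(best, t(best))
}

# independent correlation-based concentration for a given core set
oracle_concentration <- function(a, core) {
  n <- nrow(a)
  ideal <- matrix(1, n, n)
  per <- setdiff(seq_len(n), core)
  ideal[per, per] <- 0
  lt <- lower.tri(a)
  suppressWarnings(stats::cor(a[lt], ideal[lt]))
}

# adjusted Rand index between two partitions (Hubert & Arabie)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  ex <- si * sj / choose(n, 2)
  (sij - ex) / ((si + sj) / 2 - ex)
}

# simple Gaussian kernel smoother for building smooth test surfaces
gaussian_smooth_for_test <- function(m, sigma) {
  n <- nrow(m)
  rad <- ceiling(3 * sigma)
  off <- -rad:rad
  kern <- exp(-off^2 / (2 * sigma^2))
  sm1 <- function(x) {
    acc <- matrix(0, nrow(x), ncol(x))
    for (i in seq_along(off)) {
      idx <- pmin(pmax(seq_len(nrow(x)) + off[i], 1L), nrow(x))
      acc <- acc + kern[i] * x[idx, , drop = FALSE]
    }
    acc / sum(kern)
  }
  t(sm1(t(sm1(m))))
}

expect_matrix_equal <- function(a, b, tol = 1e-10) {
  expect_true(max(abs(unclass(a) - unclass(b))) < tol)
}
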