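#' Population centroid allele-frequency vectors
#'
#' Stacks the per-locus allele-frequency vectors of each population into one
#' multivariate coding vector over a common allele namespace (dimension =
#' sum over loci of the allele count at that locus). These centroids are the
#' multivariate representation from which the genetic covariance structure
#' of the population network is derived.
#'
#' @param table a `genotype_table`
#' @return numeric matrix, populations x stacked alleles
#' @export
population_centroids <- function(table) {
  af <- allele_frequencies(table)
  mats <- lapply(names(af$freq), function(lc) {
    m <- af$freq[[lc]]
    colnames(m) <- paste(lc, colnames(m), sep = ".")
    m
  })
  do.call(cbind, mats)
}

#' Squared Euclidean distances between population centroids
#' @param centroids matrix from [population_centroids()]
#' @return symmetric matrix of squared distances, zero diagonal
#' @export
centroid_distances <- function(centroids) {
  as.matrix(stats::dist(centroids))^2
}

#' Covariance structure from a distance matrix (Gower double-centering)
#'
#' `C = -1/2 * J D J` applied to the squared-distance matrix, with
#' `J = I - (1/n) 11'`. Row and column sums of `C` are zero; if `D`
#' contains squared Euclidean distances, `C` is the centred inner-product
#' (covariance) matrix of the underlying configuration.
#'
#' @param d symmetric matrix of squared distances, zero diagonal
#' @return centred covariance matrix
#' @export
covariance_from_distances <- function(d) {
  d <- as.matrix(unclass(d))
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  cc <- -0.5 * j %*% d %*% j
  dimnames(cc) <- dimnames(d)
  (cc + t(cc)) / 2
}

#' Partial correlations from a (possibly rank-deficient) covariance matrix
#'
#' Gower centering leaves `C` with rank at most n-1, so the precision
#' matrix is computed on the leading principal subspace: eigenvectors with
#' eigenvalue > `tol * max(eigenvalue)` are retained (the top n-1 for a
#' centred matrix; everything for well-conditioned full-rank input), a
#' relative ridge is added for numerical safety, and the partial
#' correlation is `rho_ij = -omega_ij / sqrt(omega_ii * omega_jj)`.
#'
#' @param c_mat symmetric covariance matrix
#' @param ridge relative ridge added to retained eigenvalues (default 1e-8)
#' @param tol relative eigenvalue cutoff for the retained subspace
#' @return symmetric partial-correlation matrix with unit diagonal
#' @export
partial_correlations <- function(c_mat, ridge = 1e-8, tol = 1e-10) {
  c_mat <- (c_mat + t(c_mat)) / 2
  n <- nrow(c_mat)
  if (all(abs(c_mat[upper.tri(c_mat)]) < 1e-14)) {
    # diagonal covariance: nothing is conditionally associated
    rho <- diag(n)
    dimnames(rho) <- dimnames(c_mat)
    return(rho)
  }
  eig <- eigen(c_mat, symmetric = TRUE)
  lam_max <- max(eig$values)
  # Gower centering leaves one ~zero eigenvalue; the relative cutoff drops
  # it (and anything else numerically null) without touching full-rank input
  keep <- which(eig$values > tol * lam_max)
  if (length(keep) == 0L) stop("covariance matrix has no usable spectrum")
  lam <- eig$values[keep] + ridge * lam_max
  v <- eig$vectors[, keep, drop = FALSE]
  omega <- v %*% diag(1 / lam, length(keep)) %*% t(v)
  dsq <- sqrt(diag(omega))
  if (any(!is.finite(dsq)) || any(dsq == 0))
    stop("precision diagonal degenerate; condition number ",
         format(lam_max / min(lam)))
  rho <- -omega / tcrossprod(dsq)
  diag(rho) <- 1
  rho <- pmin(pmax(rho, -1), 1)
  dimnames(rho) <- dimnames(c_mat)
  (rho + t(rho)) / 2
}

#' Edge-exclusion deviance
#'
#' Likelihood-ratio statistic `-N * ln(1 - rho^2)` for dropping one edge
#' from a Gaussian graphical model; compared against the chi-squared
#' critical value on 1 df.
#'
#' @param rho partial correlation(s)
#' @param n_total effective sample size
#' @return deviance value(s)
#' @export
edge_exclusion_deviance <- function(rho, n_total) {
  -n_total * log(1 - rho^2)
}

#' Prune a saturated population graph by conditional independence
#'
#' Retains edge (i, j) iff its edge-exclusion deviance exceeds the
#' chi-squared(1) critical value at `alpha`. Retained edges carry
#' `weight` = the pairwise genetic distance used to build the covariance
#' structure, and optionally `flow` = 1 - D_PS for topology metrics.
#'
#' @param rho partial-correlation matrix
#' @param n_total total genotyped individuals across populations
#' @param alpha significance level in (0, 1)
#' @param weights symmetric matrix of edge weights (genetic distances)
#' @param flow optional symmetric matrix of flow weights (1 - D_PS)
#' @return a `population_graph`: list with `graph` (igraph), `nodes`,
#'   `alpha`, `n_total`, `pruned`, `n_edges_saturated`
#' @export
prune_graph <- function(rho, n_total, alpha = 0.05, weights, flow = NULL) {
  n <- nrow(rho)
  stopifnot(n_total >= n, alpha > 0, alpha < 1)
  labels <- rownames(rho)
  if (is.null(labels)) labels <- paste0("pop", seq_len(n))
  crit <- stats::qchisq(1 - alpha, df = 1)
  el <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[el]
  eed <- edge_exclusion_deviance(r, n_total)
  sat <- abs(r) > 1 - 1e-12
  if (any(sat)) {
    warning("partial correlation at |rho| = 1: infinite deviance, edge retained")
    eed[sat] <- Inf
  }
  keep <- eed > crit
  edges <- data.frame(from = labels[el[keep, 1]],
                      to = labels[el[keep, 2]],
                      rho = r[keep], eed = eed[keep],
                      weight = unclass(weights)[el][keep])
  if (!is.null(flow)) edges$flow <- unclass(flow)[el][keep]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = labels))
  structure(list(graph = g, nodes = labels, alpha = alpha,
                 n_total = n_total, pruned = TRUE,
                 n_edges_saturated = n * (n - 1) / 2),
            class = "population_graph")
}

#' Build a pruned population graph straight from genotypes
#'
#' Convenience wrapper running centroids -> squared-Euclidean distances ->
#' Gower covariance -> partial correlations -> EED pruning, with flow
#' weights 1 - D_PS attached for topology metrics.
#'
#' @param table a `genotype_table`
#' @param alpha edge-test significance level
#' @param ridge relative ridge for the precision computation
#' @return a `population_graph`
#' @export
build_population_graph <- function(table, alpha = 0.05, ridge = 1e-8) {
  cen <- population_centroids(table)
  d2 <- centroid_distances(cen)
  cc <- covariance_from_distances(d2)
  rho <- partial_correlations(cc, ridge = ridge)
  flow <- 1 - unclass(dps_matrix(table))
  diag(flow) <- 0
  prune_graph(rho, n_total = nrow(table), alpha = alpha,
              weights = d2, flow = flow)
}

#' @export
print.population_graph <- function(x, ...) {
  s <- graph_summary(x)
  cat(sprintf("population_graph: %d nodes, %d/%d edges (%d%% of saturated), alpha = %g\n",
              s$n_nodes, s$n_edges_pruned, s$n_edges_saturated,
              s$pct_saturated, x$alpha))
  invisible(x)
}

#' Conditional genetic distance matrix
#'
#' Shortest-path distance between every node pair over the retained edges,
#' using the genetic-distance edge weights. Pairs in different components
#' are infinite; component membership is attached as an attribute.
#'
#' @param pg a `population_graph`
#' @return a `dist_matrix` with metric `"cgd"` (may contain `Inf`)
#' @export
cgd_matrix <- function(pg) {
  d <- igraph::distances(pg$graph, weights = igraph::E(pg$graph)$weight)
  d <- d[pg$nodes, pg$nodes]
  out <- dist_matrix(d, pg$nodes, "cgd")
  comp <- igraph::components(pg$graph)$membership[pg$nodes]
  attr(out, "components") <- comp
  out
}

#' Summarise pruning intensity
#' @param pg a `population_graph` (or bare igraph with a `n_edges_saturated`)
#' @return list: `n_nodes`, `n_edges_pruned`, `n_edges_saturated`,
#'   `pct_saturated` (integer percent of the saturated edge count)
#' @export
graph_summary <- function(pg) {
  g <- if (inherits(pg, "population_graph")) pg$graph else pg
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  sat <- n * (n - 1) / 2
  list(n_nodes = n, n_edges_pruned = m, n_edges_saturated = sat,
       pct_saturated = as.integer(round(100 * m / sat)))
}

#' Export a population graph to GraphML and edge-list CSV
#' @param pg a `population_graph`
#' @param path base path; writes `<path>.graphml` and `<path>_edges.csv`
#' @param sites optional `site_table` supplying x/y node attributes
#' @export
write_population_graph <- function(pg, path, sites = NULL) {
  g <- pg$graph
  if (!is.null(sites)) {
    idx <- match(igraph::V(g)$name, sites$population)
    igraph::V(g)$x <- sites$x[idx]
    igraph::V(g)$y <- sites$y[idx]
  }
  igraph::write_graph(g, paste0(path, ".graphml"), format = "graphml")
  utils::write.csv(igraph::as_data_frame(g, what = "edges"),
                   paste0(path, "_edges.csv"), row.names = FALSE)
  invisible(path)
}
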