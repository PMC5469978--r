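#' Derive a named child seed from a root seed
#'
#' All generator stages draw their randomness from child streams derived
#' deterministically from one root seed, so stages can be regenerated
#' independently. Values stay below 2^31 - 1.
#'
#' @param seed integer root seed
#' @param stream stream name
#' @return integer seed
#' @export
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647 + 1)
}

#' Simulation configuration
#'
#' Bundles the study-design parameters the generator emulates. Defaults
#' follow the study conditions: 13 populations of ~24 individuals, 8
#' microsatellite loci, mean differentiation around F = 0.2 (pairwise
#' values spanning roughly 0.03-0.48 with the default hierarchy), and
#' gravity flows with distance decay beta_w = -0.8, origin SD 0.3,
#' residual SD 0.2.
#'
#' @param n_pops number of populations
#' @param n_ind_per_pop individuals per population
#' @param n_loci number of loci
#' @param n_alleles_per_locus alleles per locus namespace
#' @param fst_target divergence level for the flat (non-clustered) model
#' @param cluster_map optional integer vector (length `n_pops`) assigning
#'   populations to clusters; enables the two-level hierarchy
#' @param fst_between,fst_within cluster-level and within-cluster
#'   divergence (hierarchical model only)
#' @param extent raster grid dimension (cells, square)
#' @param cellsize raster cell size (m)
#' @param truth gravity generating parameters: list(beta0, beta_w, beta
#'   (named vector over covariates), sigma_u, sigma_e)
#' @param seed root seed
#' @return a `sim_config` list
#' @export
sim_config <- function(n_pops = 13L, n_ind_per_pop = 24L, n_loci = 8L,
                       n_alleles_per_locus = 10L, fst_target = 0.2,
                       cluster_map = NULL, fst_between = 0.25,
                       fst_within = 0.05, extent = 120L, cellsize = 30,
                       truth = list(beta0 = -0.5, beta_w = -0.8,
                                    beta = c(), sigma_u = 0.3,
                                    sigma_e = 0.2),
                       seed = 1L) {
  stopifnot(n_pops >= 1L, n_ind_per_pop >= 1L, n_loci >= 1L,
            n_alleles_per_locus >= 2L,
            fst_target > 0, fst_target < 1, extent >= 50L)
  if (!is.null(cluster_map)) stopifnot(length(cluster_map) == n_pops)
  structure(list(n_pops = n_pops, n_ind_per_pop = n_ind_per_pop,
                 n_loci = n_loci, n_alleles_per_locus = n_alleles_per_locus,
                 fst_target = fst_target, cluster_map = cluster_map,
                 fst_between = fst_between, fst_within = fst_within,
                 extent = extent, cellsize = cellsize, truth = truth,
                 seed = seed),
            class = "sim_config")
}

rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}

#' Simulate genotypes under the Balding-Nichols model
#'
#' Per-locus ancestral frequencies are drawn from a symmetric Dirichlet;
#' population frequencies from `Dirichlet(p * (1 - F) / F)`, which gives
#' allele-frequency variance `F p (1 - p)` around the ancestral values
#' (so F is the expected differentiation). With a `cluster_map`, a
#' two-level hierarchy is used: cluster frequencies at `fst_between`, then
#' populations around their cluster at `fst_within`. Genotypes are drawn
#' under Hardy-Weinberg within populations.
#'
#' @param config a `sim_config`
#' @return a `genotype_table`
#' @export
simulate_genotypes <- function(config) {
  set.seed(child_seed(config$seed, "genotypes"))
  k <- config$n_alleles_per_locus
  pops <- sprintf("P%02d", seq_len(config$n_pops))
  loci <- sprintf("loc%d", seq_len(config$n_loci))
  bn_draw <- function(p, f) rdirichlet(p * (1 - f) / f)
  rows <- vector("list", config$n_pops)
  pop_freqs <- vector("list", config$n_loci)
  for (l in seq_len(config$n_loci)) {
    anc <- rdirichlet(rep(1, k))
    pop_freqs[[l]] <- if (is.null(config$cluster_map)) {
      t(vapply(seq_len(config$n_pops),
               function(i) bn_draw(anc, config$fst_target), numeric(k)))
    } else {
      cl_ids <- sort(unique(config$cluster_map))
      cl_freq <- lapply(cl_ids, function(cl) bn_draw(anc, config$fst_between))
      names(cl_freq) <- as.character(cl_ids)
      t(vapply(seq_len(config$n_pops), function(i)
        bn_draw(cl_freq[[as.character(config$cluster_map[i])]],
                config$fst_within), numeric(k)))
    }
  }
  alleles <- sprintf("%03d", 100 + 2 * seq_len(k))  # microsat-style labels
  out <- vector("list", config$n_pops)
  for (i in seq_len(config$n_pops)) {
    df <- data.frame(
      individual = sprintf("%s_%03d", pops[i], seq_len(config$n_ind_per_pop)),
      population = pops[i], year = 2002L)
    for (l in seq_len(config$n_loci)) {
      f <- pop_freqs[[l]][i, ]
      a1 <- sample(alleles, config$n_ind_per_pop, replace = TRUE, prob = f)
      a2 <- sample(alleles, config$n_ind_per_pop, replace = TRUE, prob = f)
      df[[paste0(loci[l], ".1")]] <- a1
      df[[paste0(loci[l], ".2")]] <- a2
    }
    out[[i]] <- df
  }
  tab <- genotype_table(do.call(rbind, out))
  attr(tab, "pop_freqs") <- pop_freqs
  tab
}

gaussian_field <- function(n, sigma) {
  noise <- matrix(stats::rnorm(n * n), n, n)
  rad <- max(1L, ceiling(3 * sigma))
  off <- -rad:rad
  kern <- exp(-off^2 / (2 * sigma^2))
  # separable convolution with replicate padding
  smooth1 <- function(m) {
    acc <- matrix(0, n, n)
    for (i in seq_along(off)) {
      idx <- pmin(pmax(seq_len(n) + off[i], 1L), n)
      acc <- acc + kern[i] * m[idx, , drop = FALSE]
    }
    acc / sum(kern)
  }
  f <- t(smooth1(t(smooth1(noise))))
  (f - mean(f)) / stats::sd(f)
}

#' Simulate a landscape stack and matching site table
#'
#' DEM = base elevation plus two smoothed Gaussian random fields (broad
#' and fine scale); binary class masks (shrub, grass, agriculture,
#' impervious, streams) by thresholding independent smoothed fields at
#' fixed quantiles. Sites are placed by rejection sampling with a minimum
#' pairwise spacing.
#'
#' @param config a `sim_config`
#' @param n_sites number of sites (default `n_pops`)
#' @param min_spacing minimum site spacing (m); default 8 cells
#' @param smooth_broad,smooth_fine field smoothing radii (cells)
#' @return list: `stack` (a `landscape_stack`), `sites` (a `site_table`)
#' @export
simulate_landscape <- function(config, n_sites = config$n_pops,
                               min_spacing = 8 * config$cellsize,
                               smooth_broad = 12, smooth_fine = 2) {
  set.seed(child_seed(config$seed, "landscape"))
  n <- config$extent
  cs <- config$cellsize
  dem_field <- 1200 + 400 * gaussian_field(n, smooth_broad) +
    60 * gaussian_field(n, smooth_fine)
  mk <- function(q, sigma = 6) {
    f <- gaussian_field(n, sigma)
    (f > stats::quantile(f, q)) + 0
  }
  stack <- landscape_stack(list(
    dem = raster_grid(dem_field, 0, 0, cs),
    shrub = raster_grid(mk(0.55), 0, 0, cs),
    grass = raster_grid(mk(0.6), 0, 0, cs),
    agri = raster_grid(mk(0.85), 0, 0, cs),
    imperv = raster_grid(mk(0.93, sigma = 3), 0, 0, cs),
    eph_strm = raster_grid(mk(0.9, sigma = 3), 0, 0, cs),
    per_strm = raster_grid(mk(0.96, sigma = 4), 0, 0, cs)))
  lim <- n * cs
  margin <- 0.05 * lim
  pts <- matrix(NA_real_, 0, 2)
  tries <- 0L
  while (nrow(pts) < n_sites) {
    cand <- stats::runif(2, margin, lim - margin)
    if (nrow(pts) == 0L ||
        min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >=
        min_spacing) {
      pts <- rbind(pts, cand)
    }
    tries <- tries + 1L
    if (tries > 10000L)
      stop("cannot place ", n_sites, " sites at spacing ", min_spacing)
  }
  sites <- site_table(data.frame(
    population = sprintf("P%02d", seq_len(n_sites)),
    abbrev = sprintf("S%02d", seq_len(n_sites)),
    x = pts[, 1], y = pts[, 2],
    species = "synthetic", included = TRUE))
  list(stack = stack, sites = sites)
}

#' Simulate gravity flows with known generating parameters
#'
#' Draws directional flows `ln T_ij = beta0 + beta_w ln w_ij +
#' X beta + u_i + e_ij` over every ordered site pair, with
#' origin effects `u_i ~ N(0, sigma_u^2)` and residuals
#' `e_ij ~ N(0, sigma_e^2)`. Covariates are z-standardised before the
#' linear predictor is formed (so `beta` is in SD units). Flows above 1
#' are clipped into (0, 1] and the clipping count reported (warning above
#' 5% of rows).
#'
#' @param sites a `site_table`
#' @param truth list(beta0, beta_w, beta (named over covariate columns),
#'   sigma_u, sigma_e)
#' @param at_site optional data.frame: population + at-site columns
#' @param between optional data.frame: pop_i, pop_j + between-site columns
#' @param attach at-site attachment (`"destination"` or `"origin"`)
#' @param seed integer seed
#' @return a `flow_table` with attributes `truth`, `u` (origin effects),
#'   and `n_clipped`
#' @export
simulate_flows <- function(sites, truth, at_site = NULL, between = NULL,
                           attach = "destination", seed = 1L) {
  stopifnot(truth$sigma_u >= 0, truth$sigma_e >= 0,
            all(is.finite(unlist(truth[c("beta0", "beta_w")]))))
  geo <- geographic_matrix(sites)
  pops <- rownames(geo)
  n <- length(pops)
  # neutral dps placeholder so build_flow_table assembles the design
  zero <- dist_matrix(matrix(0, n, n, dimnames = list(pops, pops)),
                      pops, "dps")
  ft <- suppressWarnings(
    build_flow_table(zero, geo, at_site = at_site, between = between,
                     attach = attach))
  set.seed(seed)
  u <- stats::setNames(stats::rnorm(n, 0, truth$sigma_u), pops)
  eps <- stats::rnorm(nrow(ft), 0, truth$sigma_e)
  lp <- truth$beta0 + truth$beta_w * ft$ln_w
  for (nm in names(truth$beta)) {
    if (!nm %in% names(ft)) stop("truth names a missing covariate: ", nm)
    lp <- lp + truth$beta[[nm]] * ft[[nm]]
  }
  ln_t <- lp + u[ft$from] + eps
  flow <- exp(ln_t)
  n_clipped <- sum(flow > 1)
  if (n_clipped > 0.05 * nrow(ft))
    warning(sprintf("%d of %d flows clipped into (0, 1]", n_clipped, nrow(ft)))
  flow <- pmin(flow, 1)
  ft$flow <- flow
  ft$ln_flow <- log(flow)
  attr(ft, "truth") <- truth
  attr(ft, "u") <- u
  attr(ft, "n_clipped") <- n_clipped
  ft
}

#' Planted-partition (stochastic block model) binary graph
#'
#' Fixture generator for the community-detection and core-periphery
#' analyses: `k_clusters` groups of `n_per_cluster` nodes, within-group
#' edge probability `p_in`, between-group `p_out`, with known labels.
#'
#' @param n_per_cluster nodes per cluster
#' @param k_clusters number of clusters
#' @param p_in,p_out within/between edge probabilities (`p_out < p_in`)
#' @param seed integer seed
#' @param require_connected redraw until connected (up to `max_tries`)
#' @param max_tries redraw cap
#' @return igraph with a `truth` vertex attribute (planted labels)
#' @export
planted_cluster_graph <- function(n_per_cluster, k_clusters, p_in, p_out,
                                  seed = 1L, require_connected = TRUE,
                                  max_tries = 50L) {
  stopifnot(p_out >= 0, p_out < p_in, p_in <= 1)
  set.seed(seed)
  sizes <- rep(n_per_cluster, k_clusters)
  pm <- matrix(p_out, k_clusters, k_clusters)
  diag(pm) <- p_in
  for (try in seq_len(max_tries)) {
    g <- igraph::sample_sbm(sum(sizes), pref.matrix = pm, block.sizes = sizes)
    igraph::V(g)$name <- paste0("n", seq_len(sum(sizes)))
    igraph::V(g)$truth <- rep(seq_len(k_clusters), times = sizes)
    if (!require_connected || igraph::is_connected(g)) return(g)
  }
  stop("could not draw a connected planted-cluster graph in ",
       max_tries, " tries")
}

#' Emit the full synthetic fixture set to a directory
#'
#' Writes genotype CSV (+ Genepop), site CSV, ASCII-grid rasters, and a
#' truth JSON so every pipeline stage can be exercised from files.
#'
#' @param config a `sim_config`
#' @param dir output directory (created if needed)
#' @return invisible list of the generated objects
#' @export
simulate_fixture_set <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- simulate_genotypes(config)
  land <- simulate_landscape(config)
  write_genotypes(tab, file.path(dir, "genotypes.csv"), "csv")
  write_genotypes(tab, file.path(dir, "genotypes.gen"), "genepop")
  write_sites(land$sites, file.path(dir, "sites.csv"))
  for (nm in names(land$stack))
    write_ascii_grid(land$stack[[nm]], file.path(dir, paste0(nm, ".asc")))
  jsonlite::write_json(
    list(seed = config$seed, n_pops = config$n_pops,
         fst_target = config$fst_target,
         cluster_map = config$cluster_map, truth = config$truth),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(genotypes = tab, stack = land$stack, sites = land$sites))
}
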