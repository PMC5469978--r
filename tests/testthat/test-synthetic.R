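test_that("generator is fully reproducible from the root seed", {
  cfg <- sim_config(n_pops = 5, n_ind_per_pop = 8, seed = 404)
  expect_identical(as.data.frame(simulate_genotypes(cfg)),
                   as.data.frame(simulate_genotypes(cfg)))
  l1 <- simulate_landscape(cfg)
  l2 <- simulate_landscape(cfg)
  expect_identical(unclass(l1$stack$dem), unclass(l2$stack$dem))
  expect_identical(l1$sites$x, l2$sites$x)
  truth <- list(beta0 = -0.5, beta_w = -0.8, beta = c(), sigma_u = 0.3,
                sigma_e = 0.2)
  f1 <- simulate_flows(l1$sites, truth, seed = 2)
  f2 <- simulate_flows(l2$sites, truth, seed = 2)
  expect_identical(f1$flow, f2$flow)
  # child streams differ across stages
  expect_false(child_seed(1, "genotypes") == child_seed(1, "landscape"))
})

test_that("population frequencies converge to ancestral as F -> 0", {
  cfg <- sim_config(n_pops = 6, n_ind_per_pop = 5, n_loci = 4,
                    fst_target = 0.001, seed = 15)
  tab <- simulate_genotypes(cfg)
  pf <- attr(tab, "pop_freqs")
  for (l in seq_along(pf)) {
    anc <- colMeans(pf[[l]])
    expect_lt(max(abs(sweep(pf[[l]], 2, anc))), 0.05)
  }
})

test_that("estimated theta recovers the planted divergence level", {
  cfg <- sim_config(n_pops = 20, n_ind_per_pop = 50, n_loci = 20,
                    fst_target = 0.2, seed = 2024)
  tab <- simulate_genotypes(cfg)
  f <- fst_matrix(tab)
  expect_lt(abs(mean(f[lower.tri(f)]) - 0.2), 0.05)
})

test_that("landscape generator respects constraints", {
  cfg <- sim_config(n_pops = 8, extent = 60, seed = 5)
  land <- simulate_landscape(cfg, min_spacing = 200)
  expect_true(all(is.finite(unclass(land$stack$dem))))
  for (nm in setdiff(names(land$stack), "dem"))
    expect_true(all(unclass(land$stack[[nm]]) %in% c(0, 1)))
  d <- as.matrix(dist(cbind(land$sites$x, land$sites$y)))
  expect_gte(min(d[lower.tri(d)]), 200)
  expect_error(simulate_landscape(sim_config(n_pops = 8, extent = 60,
                                             seed = 5),
                                  n_sites = 50, min_spacing = 1e5),
               "cannot place")
})

test_that("transect variance falls as landscape smoothing rises", {
  vars <- vapply(c(1.5, 4, 10), function(sg) {
    set.seed(66)
    sm <- gaussian_smooth_for_test(matrix(rnorm(3600), 60, 60), sg)
    st <- landscape_stack(list(s = raster_grid(sm, cellsize = 30)))
    mean(vapply(1:5, function(k) {
      edge_transect_stats(st, c(100 + 40 * k, 150), c(1500, 1400 - 60 * k),
                          widths = 30)$var
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(vars) < 0))
})

test_that("simulated flows respect the deterministic and sign structure", {
  sites <- site_table(data.frame(population = sprintf("P%d", 1:6),
                                 abbrev = sprintf("S%d", 1:6),
                                 x = c(0, 5e3, 1e4, 2e4, 3e4, 4.5e4),
                                 y = c(0, 8e3, 2e3, 1.5e4, 5e3, 2e4)))
  truth0 <- list(beta0 = -0.5, beta_w = -0.8, beta = c(), sigma_u = 0,
                 sigma_e = 0)
  ft <- simulate_flows(sites, truth0, seed = 1)
  expect_equal(ft$ln_flow, -0.5 - 0.8 * ft$ln_w, tolerance = 1e-12)
  # beta_w < 0 implies negative sample correlation with ln distance
  truth <- modifyList(truth0, list(sigma_u = 0.2, sigma_e = 0.2))
  ft2 <- simulate_flows(sites, truth, seed = 8)
  expect_lt(cor(ft2$ln_flow, ft2$ln_w), 0)
  expect_identical(simulate_flows(sites, truth, seed = 8)$flow, ft2$flow)
})

test_that("planted-cluster graphs match SBM expectations", {
  g <- planted_cluster_graph(4, 3, p_in = 1, p_out = 0, seed = 1,
                             require_connected = FALSE)
  comp <- igraph::components(g)
  expect_equal(comp$no, 3L)
  expect_true(all(comp$csize == 4))

  # expected edge count vs empirical mean over draws
  p_in <- 0.8; p_out <- 0.1
  n_within <- 2 * choose(5, 2); n_between <- 25
  expected <- n_within * p_in + n_between * p_out
  counts <- vapply(1:500, function(s)
    igraph::ecount(planted_cluster_graph(5, 2, p_in, p_out, seed = s,
                                         require_connected = FALSE)),
    numeric(1))
  se <- sqrt(n_within * p_in * (1 - p_in) + n_between * p_out * (1 - p_out)) /
    sqrt(500)
  expect_lt(abs(mean(counts) - expected), 4 * se)

  # planted labels beat a random partition on modularity
  g2 <- planted_cluster_graph(6, 2, 0.9, 0.05, seed = 3)
  truth_part <- setNames(igraph::V(g2)$truth, igraph::V(g2)$name)
  set.seed(4)
  rand_part <- setNames(sample(1:2, 12, replace = TRUE), igraph::V(g2)$name)
  expect_gt(graph_modularity(g2, truth_part), graph_modularity(g2, rand_part))
})

test_that("planted genetic clusters leave a clear footprint through the graph pipeline", {
  # Planted three-cluster genotypes, run through distances -> pruned graph
  # -> community detection. Because the conditional-independence pruning
  # keeps systematic between-cluster edges (the partial-correlation
  # structure of clumped configurations), small planted clusters sit near
  # the modularity resolution limit and exact label recovery is not a
  # stable property; agreement far above chance is.
  n_seeds <- 40
  aris <- q_truth <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_pops = 12, n_ind_per_pop = 24, n_loci = 8,
                      cluster_map = rep(1:3, each = 4),
                      fst_between = 0.25, fst_within = 0.05,
                      seed = 9100 + s)
    tab <- simulate_genotypes(cfg)
    pg <- build_population_graph(tab)
    truth <- stats::setNames(rep(1:3, each = 4), sprintf("P%02d", 1:12))
    part <- eigen_communities(pg, k_max = 5)$best$partition
    aris[s] <- adjusted_rand(part[names(truth)], truth)
    q_truth[s] <- graph_modularity(pg, truth)
  }
  # detected communities agree with the planted partition well above the
  # chance level of ARI = 0
  expect_gt(mean(aris), 0.2)
  # the planted partition itself is modular in the pruned graph
  expect_gt(mean(q_truth), 0)
})

test_that("planted gravity effects are recovered in sign by selection", {
  hits <- 0
  n_seeds <- 25
  sites <- site_table(data.frame(population = sprintf("P%02d", 1:15),
                                 abbrev = sprintf("S%02d", 1:15),
                                 x = runif(15, 0, 5e4), y = runif(15, 0, 5e4)))
  set.seed(31)
  at <- data.frame(population = sites$population, hli = rnorm(15))
  pairs <- t(combn(sites$population, 2))
  bw <- data.frame(pop_i = pairs[, 1], pop_j = pairs[, 2],
                   srr = rnorm(nrow(pairs)),
                   imperv = rnorm(nrow(pairs)))
  for (s in seq_len(n_seeds)) {
    truth <- list(beta0 = -0.4, beta_w = -0.6,
                  beta = c(hli = 0.35, srr = -0.35, imperv = -0.35),
                  sigma_u = 0.2, sigma_e = 0.2)
    ft <- simulate_flows(sites, truth, at_site = at, between = bw,
                         seed = 5000 + s)
    sel <- model_selection(ft, list("hli", "srr", "imperv",
                                    c("hli", "srr", "imperv")),
                           at_site_vars = "hli",
                           between_site_vars = c("srr", "imperv"))
    fits <- attr(sel, "fits")
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "AICc"))]]
    co <- best$coefficients
    ok <- all(c("hli", "srr", "imperv") %in% names(co)) &&
      co["hli"] > 0 && co["srr"] < 0 && co["imperv"] < 0
    if (ok) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.8)
})
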