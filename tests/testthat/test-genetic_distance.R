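test_that("allele frequencies count alleles over non-missing calls", {
  tab <- toy_genotypes()
  af <- allele_frequencies(tab)
  # pop A at locA: genotypes 1/1 and 1/2 -> f(1) = 0.75, f(2) = 0.25
  expect_equal(unname(af$freq$locA["A", c("1", "2")]), c(0.75, 0.25))
  # pop B at locB: one missing individual excluded from the denominator
  expect_equal(unname(af$n_typed$locB["B"]), 1L)
  expect_equal(unname(af$freq$locB["B", "4"]), 1)
  # every frequency vector sums to 1
  for (lc in names(af$freq))
    expect_equal(unname(rowSums(af$freq[[lc]], na.rm = TRUE)),
                 rep(1, nrow(af$freq[[lc]])))
})

test_that("frequencies match a brute-force tally on synthetic data", {
  cfg <- sim_config(n_pops = 13, n_ind_per_pop = 8, seed = 17)
  tab <- simulate_genotypes(cfg)
  af <- allele_frequencies(tab)
  lc <- "loc3"; pop <- "P05"
  sub <- tab[tab$population == pop, ]
  tall <- table(c(sub[[paste0(lc, ".1")]], sub[[paste0(lc, ".2")]]))
  expected <- as.numeric(tall / sum(tall))
  got <- af$freq[[lc]][pop, names(tall)]
  expect_equal(unname(got), expected)
})

test_that("D_PS has the right identities and hand values", {
  # identical populations -> 0; fully disjoint support -> 1
  tab <- fixed_pair_genotypes()
  d <- dps_matrix(tab)
  expect_equal(unname(d["A", "B"]), 1)
  dup <- genotype_table(data.frame(
    individual = c("a1", "a2", "b1", "b2"),
    population = c("A", "A", "B", "B"),
    loc1.1 = c("1", "2", "1", "2"), loc1.2 = c("1", "2", "1", "2")))
  expect_equal(unname(dps_matrix(dup)["A", "B"]), 0)

  # one locus, pop1 {A: .5, B: .5}, pop2 {A: 1} -> shared 0.5, D_PS 0.5
  half <- genotype_table(data.frame(
    individual = c("a1", "b1"), population = c("p1", "p2"),
    loc1.1 = c("A", "A"), loc1.2 = c("B", "A")))
  expect_equal(unname(dps_matrix(half)["p1", "p2"]), 0.5)
})

test_that("D_PS matches a flat Sum-min oracle and is order invariant", {
  cfg <- sim_config(n_pops = 6, n_ind_per_pop = 10, seed = 8)
  tab <- simulate_genotypes(cfg)
  d <- dps_matrix(tab)
  af <- allele_frequencies(tab)
  # independent oracle: direct double loop over loci and alleles
  oracle <- function(p1, p2) {
    tot <- 0
    for (lc in names(af$freq))
      tot <- tot + sum(pmin(af$freq[[lc]][p1, ], af$freq[[lc]][p2, ]))
    1 - tot / length(af$freq)
  }
  expect_equal(unname(d["P02", "P05"]), oracle("P02", "P05"))
  expect_equal(unname(d["P01", "P06"]), oracle("P01", "P06"))
  # input order invariance
  perm <- tab[rev(seq_len(nrow(tab))), ]
  d2 <- dps_matrix(genotype_table(as.data.frame(perm)))
  expect_equal(unclass(d)[rownames(d2), colnames(d2)],
               unclass(d2)[rownames(d2), colnames(d2)],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Weir-Cockerham theta: fixed alternate alleles give theta = 1", {
  tab <- fixed_pair_genotypes(n = 10, n_loci = 3)
  f <- fst_matrix(tab)
  expect_equal(unname(f["A", "B"]), 1)
})

test_that("theta is near zero for samples from identical frequencies", {
  set.seed(21)
  n <- 200
  draw <- function(pop) {
    alle <- sample(c("1", "2", "3", "4"), 2 * n, replace = TRUE,
                   prob = c(0.4, 0.3, 0.2, 0.1))
    data.frame(individual = sprintf("%s%03d", pop, 1:n), population = pop,
               loc1.1 = alle[1:n], loc1.2 = alle[(n + 1):(2 * n)])
  }
  tab <- genotype_table(rbind(draw("A"), draw("B")))
  f <- fst_matrix(tab)
  expect_lt(abs(f["A", "B"]), 0.02)
})

test_that("theta is invariant to allele relabeling", {
  cfg <- sim_config(n_pops = 4, n_ind_per_pop = 15, n_loci = 4, seed = 33)
  tab <- simulate_genotypes(cfg)
  f1 <- fst_matrix(tab)
  relab <- as.data.frame(tab)
  for (lc in loci_names(tab)) for (s in c(".1", ".2"))
    relab[[paste0(lc, s)]] <- paste0("x", relab[[paste0(lc, s)]])
  f2 <- fst_matrix(genotype_table(relab))
  expect_matrix_equal(f1, f2)
})

test_that("geographic distances are Euclidean and translation invariant", {
  s <- site_table(data.frame(population = c("a", "b"), abbrev = c("a", "b"),
                             x = c(1000, 1003), y = c(2000, 2004)))
  g <- geographic_matrix(s)
  expect_equal(unname(g["a", "b"]), 5)
  s2 <- s; s2$x <- s2$x + 5e4; s2$y <- s2$y - 1e4
  expect_matrix_equal(g, geographic_matrix(s2))
  # lon/lat input is rejected with advice to project
  ll <- site_table(data.frame(population = c("a", "b"), abbrev = c("a", "b"),
                              x = c(-116.1, -116.3), y = c(44.5, 44.9)))
  expect_error(geographic_matrix(ll), "project")
})

test_that("equirectangular projection tracks haversine within 0.5%", {
  set.seed(4)
  lon <- -116 + runif(8, -0.3, 0.3)
  lat <- 44.5 + runif(8, -0.3, 0.3)
  xy <- equirectangular(lon, lat, lat0 = 44.5)
  s <- site_table(data.frame(population = paste0("s", 1:8),
                             abbrev = paste0("s", 1:8), x = xy$x, y = xy$y))
  g <- unclass(geographic_matrix(s))
  hav <- function(i, j) {
    r <- 6371008.8
    dlat <- (lat[j] - lat[i]) * pi / 180
    dlon <- (lon[j] - lon[i]) * pi / 180
    a <- sin(dlat / 2)^2 +
      cos(lat[i] * pi / 180) * cos(lat[j] * pi / 180) * sin(dlon / 2)^2
    2 * r * asin(sqrt(a))
  }
  for (i in 1:7) for (j in (i + 1):8)
    expect_lt(abs(g[i, j] - hav(i, j)) / hav(i, j), 0.005)
})

test_that("matrix correlation matches a flat-vector oracle and affine limits", {
  set.seed(2)
  m <- matrix(runif(36), 6, 6); m <- m + t(m); diag(m) <- 0
  a <- dist_matrix(m, paste0("p", 1:6), "geographic")
  mb <- 2 * m + 3
  diag(mb) <- 0
  b <- dist_matrix(mb, paste0("p", 1:6), "geographic")
  expect_equal(matrix_correlation(a, b), 1, tolerance = 1e-12)
  m2 <- matrix(runif(36), 6, 6); m2 <- m2 + t(m2); diag(m2) <- 0
  b2 <- dist_matrix(m2, paste0("p", 1:6), "geographic")
  expect_equal(matrix_correlation(a, b2),
               cor(m[lower.tri(m)], m2[lower.tri(m2)]))
  cst <- dist_matrix(matrix(1, 6, 6) - diag(6), paste0("p", 1:6), "geographic")
  expect_error(matrix_correlation(a, cst), "constant")
})

test_that("Mantel test: maximal statistic, determinism, vegan agreement", {
  set.seed(11)
  m <- matrix(runif(49), 7, 7); m <- m + t(m); diag(m) <- 0
  a <- dist_matrix(m, paste0("p", 1:7), "geographic")
  res <- mantel_test(a, a, n_perm = 199, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 200)
  # determinism under fixed seed
  m2 <- matrix(runif(49), 7, 7); m2 <- m2 + t(m2); diag(m2) <- 0
  b <- dist_matrix(m2, paste0("p", 1:7), "geographic")
  r1 <- mantel_test(a, b, n_perm = 499, seed = 42)
  r2 <- mantel_test(a, b, n_perm = 499, seed = 42)
  expect_identical(r1, r2)
  # cross-check against vegan's implementation (Monte-Carlo tolerance)
  vg <- vegan::mantel(as.dist(unclass(a)), as.dist(unclass(b)),
                      permutations = 999)
  expect_equal(r1$r, unname(vg$statistic), tolerance = 1e-10)
  expect_lt(abs(r1$p - vg$signif), 0.12)
})

test_that("D_PS increases with simulated divergence level", {
  fs <- c(0.05, 0.1, 0.2, 0.4)
  means <- vapply(seq_along(fs), function(i) {
    cfg <- sim_config(n_pops = 8, n_ind_per_pop = 20, n_loci = 10,
                      fst_target = fs[i], seed = 100 + i)
    d <- dps_matrix(simulate_genotypes(cfg))
    mean(d[lower.tri(d)])
  }, numeric(1))
  expect_gt(cor(means, fs, method = "spearman"), 0.9)
})
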