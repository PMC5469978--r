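test_that("percent cover handles constants, checkerboards, and truncation", {
  ones <- raster_grid(matrix(1, 10, 10))
  expect_true(all(unclass(percent_cover(ones, 5)) == 100))
  # checkerboard with an even window fully interior: exactly 50
  cb <- raster_grid(outer(1:10, 1:10, function(i, j) (i + j) %% 2))
  pc <- unclass(percent_cover(cb, 2))
  expect_true(all(pc[2:9, 2:9] == 50))
  expect_error(percent_cover(ones, 11), "window exceeds")
  expect_error(percent_cover(raster_grid(matrix(2, 3, 3)), 3), "binary")
})

test_that("window operations match nested-loop oracles exactly", {
  set.seed(14)
  m <- matrix(rbinom(400, 1, 0.4), 20, 20)
  m[sample(400, 10)] <- NA
  r <- raster_grid(m)
  for (w in c(3L, 4L, 7L)) {
    got <- unclass(percent_cover(r, w))
    off <- (-((w - 1L) %/% 2L)):(w %/% 2L)
    for (i in c(1, 2, 10, 19, 20)) for (j in c(1, 3, 11, 20)) {
      rows <- intersect(i + off, 1:20)
      cols <- intersect(j + off, 1:20)
      vals <- m[rows, cols]
      expect_equal(got[i, j], 100 * mean(vals == 1, na.rm = TRUE),
                   tolerance = 1e-10)
    }
  }
  # srr against a nested-loop oracle on a random DEM
  dem <- raster_grid(matrix(runif(400, 1000, 1500), 20, 20))
  s <- unclass(surface_relief_ratio(dem, 3))
  off <- -1:1
  for (i in c(1, 5, 20)) for (j in c(1, 13, 20)) {
    vals <- unclass(dem)[intersect(i + off, 1:20), intersect(j + off, 1:20)]
    expect_equal(s[i, j], (mean(vals) - min(vals)) / (max(vals) - min(vals)),
                 tolerance = 1e-10)
  }
})

test_that("surface relief ratio: ramp is 0.5, flat is 0, range respected", {
  ramp <- raster_grid(matrix(rep(1:20, each = 20), 20, 20))
  s <- unclass(surface_relief_ratio(ramp, 3))
  expect_true(all(abs(s[2:19, 2:19] - 0.5) < 1e-12))
  flat <- raster_grid(matrix(7, 10, 10))
  expect_true(all(unclass(surface_relief_ratio(flat, 3)) == 0))
  rnd <- raster_grid(matrix(rnorm(900), 30, 30))
  s27 <- unclass(surface_relief_ratio(rnd, 27))
  expect_true(all(s27 >= 0 & s27 <= 1))
})

test_that("window operations are equivariant under transposition", {
  set.seed(25)
  m <- matrix(rbinom(300, 1, 0.5), 15, 20)
  expect_equal(unclass(percent_cover(raster_grid(t(m)), 5)),
               t(unclass(percent_cover(raster_grid(m), 5))))
  dem <- matrix(runif(300), 15, 20)
  expect_equal(unclass(surface_relief_ratio(raster_grid(t(dem)), 3)),
               t(unclass(surface_relief_ratio(raster_grid(dem), 3))))
})

test_that("heat load index follows slope, folded aspect, and elevation shift", {
  # flat terrain: constant hli regardless of position
  flat <- raster_grid(matrix(1000, 12, 12))
  h <- unclass(heat_load_index(flat, 45))
  expect_true(all(abs(h - h[1, 1]) < 1e-12))
  expect_true(all(h > 0))

  # tilted planes of equal slope: SW-facing beats NE-facing
  n <- 12; cs <- 30
  # rows run north->south, cols west->east: z = (col - row) rises to the
  # northeast, so the downslope face is southwest
  sw <- outer(seq_len(n), seq_len(n), function(r, c) (c - r) * cs * 0.2)
  ne <- outer(seq_len(n), seq_len(n), function(r, c) (r - c) * cs * 0.2)
  h_sw <- unclass(heat_load_index(raster_grid(sw, cellsize = cs), 45))[6, 6]
  h_ne <- unclass(heat_load_index(raster_grid(ne, cellsize = cs), 45))[6, 6]
  expect_gt(h_sw, h_ne)

  # invariant to adding a constant to the DEM
  d <- matrix(runif(144, 900, 1100), 12, 12)
  expect_equal(unclass(heat_load_index(raster_grid(d), 45)),
               unclass(heat_load_index(raster_grid(d + 500), 45)),
               tolerance = 1e-10)
})

test_that("ASCII grid round-trips values, geometry and missing cells", {
  set.seed(31)
  m <- matrix(round(runif(48, -5, 5), 4), 6, 8)
  m[2, 3] <- NA
  r <- raster_grid(m, xll = 1000, yll = 2000, cellsize = 25)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(r, path)
  back <- read_ascii_grid(path)
  expect_equal(unclass(back), unclass(r), tolerance = 1e-9)
  expect_equal(attr(back, "cellsize"), 25)
  expect_equal(attr(back, "xll"), 1000)
})

test_that("at-site extraction averages a disc and errors off-extent", {
  cs <- 30
  const <- landscape_stack(list(k = raster_grid(matrix(4.2, 40, 40),
                                                cellsize = cs)))
  sites <- site_table(data.frame(population = c("a", "b"),
                                 abbrev = c("a", "b"),
                                 x = c(600, 900), y = c(600, 300)))
  out <- at_site_covariates(const, sites, radius = 100)
  expect_equal(out$k, c(4.2, 4.2))
  # radius smaller than a cell: value of the containing cell
  grad <- landscape_stack(list(g = raster_grid(
    outer(1:40, 1:40, function(r, c) c), cellsize = cs)))
  out2 <- at_site_covariates(grad, sites, radius = 1)
  expect_equal(out2$g, c(ceiling(600 / cs), ceiling(900 / cs)))
  bad <- site_table(data.frame(population = "z", abbrev = "z",
                               x = 1e6, y = 1e6))
  expect_error(at_site_covariates(const, bad, 100), "outside raster")

  # disc mask oracle on a random layer
  set.seed(7)
  lay <- matrix(runif(1600), 40, 40)
  st <- landscape_stack(list(v = raster_grid(lay, cellsize = cs)))
  got <- at_site_covariates(st, sites[1, ], radius = 120)$v
  xs <- (seq_len(40) - 0.5) * cs
  ys <- (40 - seq_len(40) + 0.5) * cs
  dmat <- outer(ys - 600, xs - 600, function(a, b) sqrt(a^2 + b^2))
  expect_equal(got, mean(lay[dmat <= 120]))
})

test_that("edge transects: constants, corridor oracle, and width coherence", {
  cs <- 30
  const <- landscape_stack(list(k = raster_grid(matrix(2.5, 50, 50),
                                                cellsize = cs)))
  st <- edge_transect_stats(const, c(100, 100), c(1300, 1200),
                            widths = c(30, 150, 300))
  expect_equal(st$mean, rep(2.5, 3))
  expect_equal(st$var, rep(0, 3))
  expect_error(edge_transect_stats(const, c(1, 1), c(1, 1)), "differ")

  # corridor oracle: transect mean approximates the rasterised-corridor mean
  set.seed(44)
  smooth <- gaussian_smooth_for_test(matrix(rnorm(2500), 50, 50), 6)
  stack <- landscape_stack(list(s = raster_grid(smooth, cellsize = cs)))
  got <- edge_transect_stats(stack, c(150, 150), c(1350, 1050),
                             widths = 90, step = 10)
  # oracle: cells whose center lies within 45 m of the segment
  xs <- (seq_len(50) - 0.5) * cs
  ys <- (50 - seq_len(50) + 0.5) * cs
  p1 <- c(150, 150); p2 <- c(1350, 1050)
  v <- p2 - p1; len2 <- sum(v^2)
  inside <- matrix(FALSE, 50, 50)
  for (i in 1:50) for (j in 1:50) {
    w <- c(xs[j] - p1[1], ys[i] - p1[2])
    t0 <- min(max(sum(w * v) / len2, 0), 1)
    d <- sqrt(sum((w - t0 * v)^2))
    inside[i, j] <- d <= 45
  }
  oracle_mean <- mean(smooth[inside])
  expect_lt(abs(got$mean - oracle_mean), 0.05)

  # widths 30/150/300 on a smooth layer give tightly correlated means
  set.seed(45)
  sm2 <- gaussian_smooth_for_test(matrix(rnorm(2500), 50, 50), 8)
  st2 <- landscape_stack(list(s = raster_grid(sm2, cellsize = cs)))
  pts <- cbind(runif(12, 200, 1300), runif(12, 200, 1300))
  means <- t(sapply(seq_len(6), function(k) {
    st <- edge_transect_stats(st2, pts[2 * k - 1, ], pts[2 * k, ],
                              widths = c(30, 150, 300), step = 15)
    st$mean
  }))
  expect_gt(cor(means[, 1], means[, 3]), 0.8)
})
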