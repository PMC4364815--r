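test_that("Euclidean matrix reproduces printed-coordinate distances", {
  sites <- data.frame(id = c("Namakia", "Marambitsy"),
                      easting = c(585313, 569852),
                      northing = c(8242761, 8242662))
  d <- euclidean_matrix(sites)
  expect_equal(d["Namakia", "Marambitsy"], sqrt(15461^2 + 99^2),
               tolerance = 1e-9)
  expect_lt(abs(d["Namakia", "Marambitsy"] - 15461), 2)
  expect_equal(diag(unclass(d)), c(Namakia = 0, Marambitsy = 0))
  # identical coordinates
  sites2 <- data.frame(id = c("x", "y"), easting = c(1, 1), northing = c(2, 2))
  expect_equal(euclidean_matrix(sites2)["x", "y"], 0)
})

test_that("Bray-Curtis scalar dissimilarity follows |x-y|/(x+y)", {
  s <- data.frame(id = c("a", "b", "c", "d"),
                  easting = 1:4, northing = 1:4,
                  precipitation = c(400, 400, 100, 0))
  bc <- bray_curtis_matrix(s, "precipitation")
  expect_equal(bc["a", "b"], 0)
  expect_equal(bc["b", "c"], 300 / 500)
  expect_equal(bc["c", "d"], 1)  # x vs 0
  expect_equal(bray_curtis_matrix(
    data.frame(id = c("a", "b"), easting = 1:2, northing = 1:2,
               precipitation = c(100, 300)), "precipitation")["a", "b"], 0.5)
  expect_true(all(bc >= 0 & bc <= 1))
  s$precipitation[1] <- -5
  expect_error(bray_curtis_matrix(s, "precipitation"), "negative")
})

test_that("cost rasters honour buffers, saturation, and penalties", {
  # coastline along the left edge, 10 km buffer, 1 km cells: exactly the
  # 10 nearest columns are suitable
  coast <- cbind(x = 0, y = seq(0, 20000, by = 500))
  rule <- habitat_rule(list(coast = coast), buffer_km = 10, outside_penalty = 100)
  ras <- build_cost_raster(rule, extent = c(0, 20000, 0, 20000), resolution = 1000)
  expect_equal(ncol(ras$grid), 20L)
  expect_true(all(ras$grid[, 1:10] == 1))
  expect_true(all(ras$grid[, 11:20] == 100))
  # cell centre 10.5 km from the coast under a 10-km rule costs the penalty
  expect_equal(ras$grid[1, 11], 100)
  # saturation: 75 km buffer on a 50-km extent
  rule2 <- habitat_rule(list(coast = coast), buffer_km = 75, outside_penalty = 100)
  ras2 <- build_cost_raster(rule2, extent = c(0, 50000, 0, 20000), resolution = 1000)
  expect_true(all(ras2$grid == 1))
})

test_that("cost rasters are invariant to feature point order", {
  set.seed(3)
  pts <- cbind(x = runif(40, 0, 5e4), y = runif(40, 0, 5e4))
  r1 <- build_cost_raster(habitat_rule(list(f = pts), 10), c(0, 5e4, 0, 5e4), 2000)
  r2 <- build_cost_raster(habitat_rule(list(f = pts[sample(40), ]), 10),
                          c(0, 5e4, 0, 5e4), 2000)
  expect_identical(r1$grid, r2$grid)
})

test_that("least-cost distances reduce to path length on uniform rasters", {
  ras <- cost_raster(c(0, 0), 100, matrix(1, 1, 5))
  sites <- data.frame(id = c("a", "b"), easting = c(50, 450), northing = c(50, 50))
  expect_equal(least_cost_matrix(ras, sites)["a", "b"], 400)
  # middle cell cost 10: steps 100*(1+10)/2 twice plus two unit steps
  ras2 <- cost_raster(c(0, 0), 100, matrix(c(1, 1, 10, 1, 1), 1, 5))
  expect_equal(least_cost_matrix(ras2, sites)["a", "b"], 1300)
})

test_that("least-cost distances match Bellman relaxation on small grids", {
  set.seed(9)
  for (rep in 1:4) {
    g <- matrix(sample(c(1, 1, 2, 5, 10), 36, TRUE), 6, 6)
    ras <- cost_raster(c(0, 0), 50, g)
    sites <- data.frame(id = c("a", "b"),
                        easting = c(25, 275), northing = c(25, 275))
    snap <- popcompare:::snap_sites(ras, sites)
    got <- least_cost_matrix(ras, sites)["a", "b"]
    want <- oracle_least_cost(ras, snap["a", ], snap["b", ])
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("uniform-raster least-cost distances bracket the Euclidean distance", {
  ras <- cost_raster(c(0, 0), 100, matrix(1, 12, 12))
  sites <- data.frame(id = c("a", "b", "c"),
                      easting = c(50, 1150, 650), northing = c(50, 950, 50))
  lc <- least_cost_matrix(ras, sites)
  eu <- euclidean_matrix(sites)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_gte(lc[i, j], eu[i, j] - 1e-9)
    expect_lte(lc[i, j], eu[i, j] * 1.0824 + 1e-9)
  }
  # monotone in separation along a line
  s2 <- data.frame(id = c("a", "b", "c"),
                   easting = c(50, 450, 1050), northing = c(50, 50, 50))
  lc2 <- least_cost_matrix(ras, s2)
  expect_lt(lc2["a", "b"], lc2["a", "c"])
})

test_that("raising a cell cost never shortens any least-cost path", {
  set.seed(12)
  g <- matrix(sample(c(1, 2, 4), 25, TRUE), 5, 5)
  ras <- cost_raster(c(0, 0), 10, g)
  sites <- data.frame(id = c("a", "b"), easting = c(5, 45), northing = c(5, 45))
  base <- least_cost_matrix(ras, sites)["a", "b"]
  for (k in 1:5) {
    g2 <- g
    g2[sample(25, 1)] <- g2[sample(25, 1)] + 5
    expect_gte(least_cost_matrix(cost_raster(c(0, 0), 10, g2), sites)["a", "b"],
               base - 1e-9)
  }
})

test_that("nodata cells: unreachable pairs are NA, sites on nodata error", {
  g <- matrix(1, 3, 3)
  g[, 2] <- NA  # impassable wall
  ras <- cost_raster(c(0, 0), 10, g)
  sites <- data.frame(id = c("a", "b"), easting = c(5, 25), northing = c(15, 15))
  expect_warning(d <- least_cost_matrix(ras, sites), "barrier")
  expect_true(is.na(d["a", "b"]))
  s_bad <- data.frame(id = "w", easting = 15, northing = 15)
  expect_error(least_cost_matrix(ras, s_bad), "nodata")
  s_out <- data.frame(id = "o", easting = 500, northing = 15)
  expect_error(least_cost_matrix(ras, s_out), "extent")
})

test_that("ESRI ASCII grids round-trip through write and read", {
  g <- matrix(c(1, 2.5, NA, 4, 1, 1), 2, 3)
  ras <- cost_raster(c(1000, 2000), 250, g)
  f <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(ras, f)
  ras2 <- read_esri_ascii(f)
  expect_equal(ras2$grid, ras$grid, ignore_attr = TRUE)
  expect_equal(ras2$origin, ras$origin)
  expect_equal(ras2$resolution, ras$resolution)
  expect_error(cost_raster(c(0, 0), 10, matrix(0.5, 2, 2)), ">= 1")
})
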