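test_that("resistance transform hits its endpoints and is strictly monotone", {
  for (rmax in c(10, 100, 1000)) {
    s <- suitability_raster(matrix(c(0, 0.5, 1, 0.25), 2, 2), 10,
                            scale = "0-1")
    r <- suitability_to_resistance(s, r_max = rmax)
    expect_equal(r$grid[1, 1], rmax)          # h = 0
    expect_equal(r$grid[1, 2], 1)             # h = 1
    expect_equal(r$grid[2, 1], sqrt(rmax))    # h = 0.5
  }
  h <- seq(0, 1, by = 0.05)
  R <- suitability_to_resistance(
    suitability_raster(matrix(h, 1), 10, scale = "0-1"))$grid[1, ]
  expect_true(all(diff(R) < 0))
  expect_error(suitability_to_resistance(
    suitability_raster(matrix(0.5, 2, 2), 10, scale = "0-1"), r_max = 1),
    "r_max")
})

test_that("source selection follows the qualify / centroid / rarefy rules", {
  # 20 x 10 km of 100-m pixels, all below threshold
  low <- suitability_raster(matrix(0.3, 100, 200), 100, scale = "0-1")
  expect_equal(nrow(select_sources(low)), 0)

  # a single 0.6 pixel qualifies exactly its 1-km cell
  g <- matrix(0.3, 100, 200)
  g[25, 37] <- 0.6
  one <- select_sources(suitability_raster(g, 100, scale = "0-1"))
  expect_equal(nrow(one), 1)
  expect_equal(one$x, 3500)              # centroid of 1-km cell column 4
  expect_equal(one$y, 10000 - 2500)      # centroid of 1-km cell row 3
  expect_equal(one$source_cell_id, "g3_4")

  # a 10 km x 5 km fully suitable stratum rarefied at 5 km -> 2 sources
  g2 <- matrix(0.9, 50, 100)
  s2 <- suitability_raster(g2, 100, scale = "0-1")
  strata <- rep("north_massif", 50)
  src <- select_sources(s2, strata = strata,
                        rarefy_stratum = "north_massif",
                        rarefy_dist_m = 5000)
  expect_equal(nrow(src), 2)
  expect_equal(sort(unique(floor(src$x / 5000))), c(0, 1))
})

test_that("cost graph edge weights are mean resistance times step length", {
  r <- uniform_res(2, 2, value = 1, cell = 1)
  cg <- build_cost_graph(r)
  w <- igraph::as_data_frame(cg$graph, what = "edges")
  expect_equal(sort(unique(round(w$weight, 5))), c(1, round(sqrt(2), 5)))

  r2 <- resistance_raster(matrix(c(1, 3), 1, 2), 10)
  cg2 <- build_cost_graph(r2)
  expect_equal(igraph::E(cg2$graph)$weight, 20)  # 10 * (1+3)/2

  r4 <- build_cost_graph(uniform_res(3, 3), neighborhood = 4)
  expect_equal(igraph::ecount(r4$graph), 12)     # no diagonals
})

test_that("cost distances match hand-derived values on a uniform 3x3 grid", {
  cg <- build_cost_graph(uniform_res(3, 3, cell = 1))
  d <- cost_distance(cg, 1)  # top-left corner (linear index 1)
  expect_equal(d[1, 1], 0)
  expect_equal(d[3, 3], 2 * sqrt(2))   # corner to opposite corner
  expect_equal(d[1, 3], 2.0)           # corner to same-row far corner
  expect_error(cost_distance(build_cost_graph(resistance_raster(
    matrix(c(1, NA, 1, 1), 2, 2), 1)), 2), "untraversable")
})

test_that("least-cost paths agree with the brute-force relaxation oracle", {
  withr::local_seed(123)
  for (i in 1:100) {
    nr <- sample(4:10, 1)
    nc <- sample(4:10, 1)
    grid <- matrix(1 + 99 * runif(nr * nc)^2, nr, nc)
    res <- resistance_raster(grid, cell_size_m = sample(c(1, 10, 100), 1))
    cg <- build_cost_graph(res)
    src <- c(sample(nr, 1), sample(nc, 1))
    dst <- c(sample(nr, 1), sample(nc, 1))
    oracle <- oracle_dijkstra(grid, res$cell_size_m, src)
    lcp <- least_cost_path(cg, src[1] + (src[2] - 1) * nr,
                           dst[1] + (dst[2] - 1) * nr)
    expect_equal(lcp$cost, oracle[dst[1], dst[2]], tolerance = 1e-9)
    # the returned path realizes its stated cost
    if (length(lcp$path) > 1) {
      rc <- arrayInd(lcp$path, c(nr, nc))
      steps <- diff(rc)
      lens <- ifelse(abs(steps[, 1]) + abs(steps[, 2]) == 2, sqrt(2), 1)
      vals <- grid[lcp$path]
      expect_equal(sum(res$cell_size_m * lens *
                         (vals[-1] + vals[-length(vals)]) / 2),
                   lcp$cost, tolerance = 1e-9)
    }
  }
})

test_that("trivial path cases behave", {
  cg <- build_cost_graph(uniform_res(1, 5, value = 2, cell = 10))
  expect_equal(least_cost_path(cg, 3, 3), list(path = 3, cost = 0))
  lcp <- least_cost_path(cg, 1, 5)
  expect_equal(lcp$path, 1:5)
  expect_equal(lcp$cost, 4 * 10 * 2)  # 4 steps x cell x uniform R
})

test_that("cost distances are symmetric and satisfy the triangle inequality", {
  withr::local_seed(31)
  grid <- matrix(1 + 9 * runif(36), 6, 6)
  cg <- build_cost_graph(resistance_raster(grid, 10))
  cells <- sample(36, 4)
  d <- sapply(cells, function(s) cost_distance(cg, s)[cells])
  expect_equal(d, t(d), tolerance = 1e-12)
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-9)
  }
})

test_that("factorial least-cost paths honor the Euclidean pair filter", {
  res <- uniform_res(1, 5, value = 1, cell = 1000)
  src2 <- data.frame(x = c(500, 4500), y = c(500, 500),
                     source_cell_id = c("a", "b"), stratum = NA)
  class(src2) <- c("source_set", "data.frame")

  # both ends of the strip, within threshold: density 1 along the strip
  d <- factorial_lcp(res, src2, dispersal_scenario("low"))
  expect_equal(as.vector(d$grid), rep(1, 5))

  # beyond the threshold: all-zero
  far <- dispersal_scenario("tiny", threshold_km = 0.003)
  expect_true(all(factorial_lcp(res, src2, far)$grid == 0))

  # single source: all-zero
  s1 <- src2[1, , drop = FALSE]
  class(s1) <- c("source_set", "data.frame")
  expect_true(all(factorial_lcp(res, s1, dispersal_scenario("low"))$grid == 0))
  expect_error(factorial_lcp(res, s1[0, ], dispersal_scenario("low")),
               "empty source")
})

test_that("factorial density mass equals the sum of included path lengths", {
  withr::local_seed(77)
  grid <- matrix(1 + 20 * runif(64), 8, 8)
  res <- resistance_raster(grid, 100)
  pts <- expand.grid(r = c(1, 4, 8), c = c(2, 7))
  src <- data.frame(x = (pts$c - 0.5) * 100, y = (8 - pts$r + 0.5) * 100,
                    source_cell_id = paste0("s", seq_len(nrow(pts))),
                    stratum = NA)
  class(src) <- c("source_set", "data.frame")
  sc <- dispersal_scenario("low")
  dens <- factorial_lcp(res, src, sc)
  expect_true(all(dens$grid == floor(dens$grid)))  # integer counts
  cg <- build_cost_graph(res)
  cells <- corridorsdm:::source_cells(cg, src)
  total <- 0
  for (i in 1:(nrow(src) - 1)) for (j in (i + 1):nrow(src)) {
    total <- total + length(least_cost_path(cg, cells[i], cells[j])$path)
  }
  expect_equal(sum(dens$grid), total)
})

test_that("on uniform resistance the axis-aligned path is the straight row", {
  res <- uniform_res(7, 7, value = 2, cell = 10)
  cg <- build_cost_graph(res)
  lcp <- least_cost_path(cg, 4, 4 + 6 * 7)  # row 4, col 1 -> row 4, col 7
  rc <- arrayInd(lcp$path, c(7, 7))
  expect_true(all(rc[, 1] == 4))
  expect_equal(rc[, 2], 1:7)
})

test_that("resistant kernels peak at the source, truncate, and superpose", {
  res <- uniform_res(9, 9, value = 1, cell = 100)
  mk_src <- function(rows, cols) {
    df <- data.frame(x = (cols - 0.5) * 100, y = (9 - rows + 0.5) * 100,
                     source_cell_id = paste0("s", seq_along(rows)),
                     stratum = NA)
    class(df) <- c("source_set", "data.frame")
    df
  }
  one <- mk_src(5, 5)
  sc <- dispersal_scenario("near", threshold_km = 0.45)  # D = 450 m
  k <- resistant_kernel(res, one, sc)
  expect_equal(k$grid[5, 5], 1.0)  # Gaussian peak at zero cost distance

  # closed form at probed cells: exp(-(octile cost)^2 / (2 sigma^2))
  cg <- build_cost_graph(res)
  d <- cost_distance(cg, 5 + 4 * 9)
  sigma <- 450 / 3
  expect_equal(k$grid[5, 8], exp(-d[5, 8]^2 / (2 * sigma^2)))
  expect_equal(k$grid[2, 2], exp(-d[2, 2]^2 / (2 * sigma^2)))
  expect_true(all(k$grid[d > 450] == 0))  # truncation beyond D
  expect_true(any(d > 450))

  # source-union additivity: kernel(A union B) = kernel(A) + kernel(B)
  a <- mk_src(2, 2)
  b <- mk_src(8, 7)
  both <- mk_src(c(2, 8), c(2, 7))
  expect_equal(resistant_kernel(res, both, sc)$grid,
               resistant_kernel(res, a, sc)$grid +
                 resistant_kernel(res, b, sc)$grid,
               tolerance = 1e-12)
})

test_that("connectivity extent counts strictly positive density cells", {
  res <- uniform_res(5, 5, value = 1, cell = 1000)
  src <- data.frame(x = c(500, 4500), y = c(2500, 2500),
                    source_cell_id = c("a", "b"), stratum = NA)
  class(src) <- c("source_set", "data.frame")
  d <- factorial_lcp(res, src, dispersal_scenario("low"))
  expect_equal(connectivity_extent(d), 20)  # 5 of 25 cells on the strip
  zero <- density_raster(matrix(0, 3, 3), 10)
  expect_equal(connectivity_extent(zero), 0)
})

test_that("movement extent is non-decreasing in the dispersal threshold", {
  cfg <- landscape_config(width_cells = 64, height_cells = 64, seed = 12)
  lc <- generate_landscape(cfg)
  covers <- fractional_cover_stack(lc, 100)[, , "woodland"]
  suit <- suitability_raster(covers, lc$cell_size_m, lc$origin_xy,
                             scale = "0-1")
  res <- suitability_to_resistance(suit)
  src <- select_sources(suit, grid_size_m = 1000, threshold = 0.5)
  expect_gt(nrow(src), 2)
  cg <- build_cost_graph(res)
  ext <- vapply(c(2, 5, 100), function(km) {
    connectivity_extent(factorial_lcp(res, src,
                                      dispersal_scenario("s", km), cg = cg))
  }, 0)
  expect_true(all(diff(ext) >= 0))
})
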