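test_that("study-area grid indexing is row-major from the lower-left", {
  area <- make_study_area(4, 3, 1)
  expect_equal(area$n_cells, 12)
  expect_equal(unname(pedrecon:::cell_center(area, 1)[1, ]), c(0.5, 0.5))
  expect_equal(unname(pedrecon:::cell_center(area, 5)[1, ]), c(0.5, 1.5))
  expect_equal(unname(pedrecon:::cell_center(area, 12)[1, ]), c(3.5, 2.5))
  expect_error(make_study_area(-1, 3), "positive")
})

test_that("home ranges are reproducible and sex-scaled", {
  p <- hr_params()
  h1 <- generate_home_range(10, 10, "F", p, seed = 4)
  h2 <- generate_home_range(10, 10, "F", p, seed = 4)
  expect_identical(h1$cloud_annual, h2$cloud_annual)
  expect_identical(h1$hull_winter, h2$hull_winter)
  h3 <- generate_home_range(10, 10, "F", p, seed = 5)
  expect_false(identical(h1$cloud_annual, h3$cloud_annual))
  # winter cloud is tighter than annual
  spread <- function(m) mean(sqrt((m[, 1] - mean(m[, 1]))^2 + (m[, 2] - mean(m[, 2]))^2))
  expect_lt(spread(h1$cloud_winter), spread(h1$cloud_annual))
  expect_error(hr_params(annual_sd_f = 0), "positive")
})

test_that("far-apart home ranges never overlap at default spreads", {
  p <- hr_params()
  for (r in 1:200) {
    a <- generate_home_range(0, 0, "M", p, seed = r)
    b <- generate_home_range(50, 0, "M", p, seed = r + 1000)
    expect_false(mcp_overlap(a, b))
  }
})

test_that("hull overlap handles identity, disjunction, and shared vertices", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_true(mcp_overlap(sq, sq))
  expect_false(mcp_overlap(sq, sq + 5))
  # triangles sharing exactly one vertex: touching counts as overlap
  t1 <- cbind(c(0, 1, 0), c(0, 0, 1))
  t2 <- cbind(c(1, 2, 2), c(0, 0, 1))
  expect_true(mcp_overlap(t1, t2))
  # clearly nested
  expect_true(mcp_overlap(sq, sq / 4 + 0.3))
})

test_that("separating-axis overlap agrees with a brute-force geometric oracle", {
  set.seed(31)
  n_checked <- 0
  for (r in 1:300) {
    d <- runif(1, 0, 6) # centre separation spanning both regimes
    a <- pedrecon:::hull_of(cbind(rnorm(12, 0, 1.2), rnorm(12, 0, 1.2)))
    b <- pedrecon:::hull_of(cbind(rnorm(12, d, 1.2), rnorm(12, 0, 1.2)))
    got <- pedrecon:::convex_intersects(a, b)
    want <- brute_overlap(a, b)
    expect_equal(got, want, info = paste("pair", r, "sep", round(d, 2)))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 300)
})

test_that("geometry is translation-invariant", {
  p <- hr_params()
  area <- make_study_area(10, 10)
  set.seed(8)
  h <- list(
    generate_home_range(3, 3, "F", p, seed = 1),
    generate_home_range(5, 4, "M", p, seed = 2),
    generate_home_range(7, 7, "F", p, seed = 3)
  )
  shift <- function(hr, dx, dy) {
    hr$cloud_winter <- hr$cloud_winter + rep(c(dx, dy), each = nrow(hr$cloud_winter))
    hr$hull_annual <- hr$hull_annual + rep(c(dx, dy), each = nrow(hr$hull_annual))
    hr$hull_winter <- hr$hull_winter + rep(c(dx, dy), each = nrow(hr$hull_winter))
    hr$centroid <- hr$centroid + c(dx, dy)
    hr
  }
  area2 <- make_study_area(10, 10, origin = c(2, 1))
  hs <- lapply(h, shift, dx = 2, dy = 1)
  expect_equal(
    mcp_overlap(h[[1]], h[[2]]), mcp_overlap(hs[[1]], hs[[2]])
  )
  w1 <- cell_weights(lapply(h, function(x) x$hull_annual), area)
  w2 <- cell_weights(lapply(hs, function(x) x$hull_annual), area2)
  expect_equal(w1$count, w2$count)
  u1 <- utilization(h[[1]], area)
  u2 <- utilization(hs[[1]], area2)
  expect_equal(u1$u, u2$u)
})

test_that("yearling dispersal has the configured distance and uniform bearing", {
  rates <- moose_vital_rates()
  # zero spread: displacement is exactly the mean distance
  r0 <- rates
  r0$dispersal_sd_km[!is.na(r0$dispersal_sd_km)] <- 0
  set.seed(1)
  for (r in 1:20) {
    nc <- disperse_yearling(5, 5, "F", r0)
    expect_equal(sqrt((nc[1] - 5)^2 + (nc[2] - 5)^2), 2.3, tolerance = 1e-9)
  }
  # male mean dispersal distance 9.3 km (spread 3.1, truncation negligible)
  set.seed(2)
  d <- replicate(10000, {
    nc <- disperse_yearling(0, 0, "M", rates)
    sqrt(sum(nc^2))
  })
  expect_equal(mean(d), 9.3, tolerance = 0.1 / 9.3)
  # bearings uniform over 36 bins
  set.seed(3)
  b <- replicate(5000, {
    nc <- disperse_yearling(0, 0, "M", rates)
    atan2(nc[1], nc[2]) %% (2 * pi)
  })
  cs <- chisq.test(table(cut(b, breaks = seq(0, 2 * pi, length.out = 37))))
  expect_gt(cs$p.value, 0.001)
})

test_that("cell weights count overlapping ranges and scale by the busiest cell", {
  area <- make_study_area(2, 2, 1)
  # hand-placed square ranges on a 4-cell toy grid
  sq <- function(x0, y0, w) cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + w, y0 + w))
  hulls <- list(
    sq(0.1, 0.1, 0.7), # cell 1 only
    sq(0.2, 0.2, 1.2), # cells 1, 2, 3, 4
    sq(1.2, 0.2, 0.6) # cell 2 only
  )
  w <- cell_weights(hulls, area)
  expect_equal(w$count, c(2L, 2L, 1L, 1L))
  expect_equal(w$weight, c(1, 1, 0.5, 0.5))
  # single animal in one cell
  w1 <- cell_weights(hulls[1], area)
  expect_equal(w1$weight, c(1, 0, 0, 0))
  # no animals: all weights zero
  w0 <- cell_weights(list(), area)
  expect_true(all(w0$weight == 0))
})

test_that("utilization is a per-animal scaled kernel density over cells", {
  area <- make_study_area(10, 10, 1)
  set.seed(5)
  cloud <- cbind(rnorm(80, 4.5, 0.8), rnorm(80, 4.5, 0.8))
  u <- utilization(cloud, area)
  expect_true(all(u$u >= 0 & u$u <= 1))
  expect_equal(sum(u$u == 1), 1)
  # far-away cell: negligible kernel mass
  far <- utilization(cloud, area, cells = area$n_cells)
  expect_lt(far$u, 1e-6)
  # degenerate single-point cloud: all mass in the containing cell
  pt <- cbind(rep(2.3, 5), rep(7.6, 5))
  upt <- utilization(pt, area, cells = seq_len(area$n_cells))
  expect_equal(sum(upt$u), 1)
  expect_equal(upt$cell[upt$u == 1], 7 * 10 + 3)
})

test_that("a symmetric cloud on a cell boundary loads both flanking cells equally", {
  area <- make_study_area(10, 10, 1)
  set.seed(6)
  off <- rnorm(500, 0, 0.4)
  yy <- rnorm(500, 4.5, 0.4)
  cloud <- cbind(5 + c(off, -off), c(yy, yy)) # mirror-symmetric about x = 5
  u <- utilization(cloud, area)
  left <- u$u[u$cell == 4 * 10 + 5]
  right <- u$u[u$cell == 4 * 10 + 6]
  expect_equal(left, right, tolerance = 0.01)
})

test_that("the kernel density matches the classical 2-D KDE on an aligned grid", {
  area <- make_study_area(8, 8, 1)
  set.seed(9)
  cloud <- cbind(rnorm(60, 4, 0.7), rnorm(60, 4.2, 0.7))
  cells <- seq_len(area$n_cells)
  u <- utilization(cloud, area, cells = cells)
  k <- MASS::kde2d(cloud[, 1], cloud[, 2],
    n = c(8, 8), lims = c(0.5, 7.5, 0.5, 7.5)
  )
  ref <- as.vector(k$z) # column-major: x fastest, matching row-major cells
  ref <- ref / max(ref)
  # same scaled surface (modulo the one-cell tie-break nudge)
  expect_equal(u$u, ref, tolerance = 1e-8)
})
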