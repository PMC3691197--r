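test_that("base_plane is the minimum z over all landmarks", {
  s <- landmark_set(cbind(1:3, 1, c(0.0, 1.2, 3.4)))
  expect_equal(base_plane(s), 0)
  s2 <- landmark_set(cbind(1:4, 1, 7))
  expect_equal(base_plane(s2), 7)
  # documented sensitivity: removing an isolated low point shifts the plane
  s3 <- landmark_set(rbind(cbind(1:5, 1:5, 2), c(0, 0, -1.5)))
  s4 <- landmark_set(cbind(1:5, 1:5, 2))
  expect_equal(base_plane(s3), -1.5)
  expect_equal(base_plane(s4) - base_plane(s3), 3.5)
})

test_that("the interpolant reproduces constant and linear fields exactly", {
  set.seed(10)
  n <- 60
  x <- c(0, 6, 0, 6, runif(n, 0, 6)); y <- c(0, 0, 6, 6, runif(n, 0, 6))
  xo <- seq(0, 6, length.out = 25); yo <- seq(0, 6, length.out = 25)
  flat <- swellvol:::.interp_cubic(x, y, rep(2, n + 4), xo, yo)
  expect_lt(max(abs(flat - 2), na.rm = TRUE), 1e-6)
  expect_true(all(!is.na(flat)))        # grid spans the hull exactly
  lin <- swellvol:::.interp_cubic(x, y, 1 + 2 * x - 0.5 * y, xo, yo)
  expect_lt(max(abs(lin - outer(xo, yo, function(a, b) 1 + 2 * a - 0.5 * b)),
                na.rm = TRUE), 1e-6)
})

test_that("quadratic gradient estimation reproduces quadratic surfaces", {
  set.seed(11)
  n <- 150
  x <- runif(n, 0, 10); y <- runif(n, 0, 10)
  z <- 1 + 2 * x - y + 0.3 * x^2 - 0.2 * x * y + 0.1 * y^2
  xo <- seq(1, 9, length.out = 20); yo <- seq(1, 9, length.out = 20)
  h <- swellvol:::.interp_cubic(x, y, z, xo, yo, degree = 2)
  ex <- outer(xo, yo, function(a, b)
    1 + 2 * a - b + 0.3 * a^2 - 0.2 * a * b + 0.1 * b^2)
  expect_lt(max(abs(h - ex), na.rm = TRUE), 1e-9)
})

test_that("nodes outside the convex hull are undefined and duplicates merge", {
  # half-disc cloud: the bounding-box corner is far outside the hull
  t <- seq(0, pi, length.out = 40)
  x <- c(5 * cos(t), 0); y <- c(5 * sin(t), 1)
  h <- swellvol:::.interp_cubic(x, y, rep(1, 41), c(-5, 0), c(5, 1))
  expect_true(is.na(h[1, 1]))           # (-5, 5) lies outside the half disc
  expect_equal(h[2, 2], 1, tolerance = 1e-9)
  expect_warning(
    swellvol:::.interp_cubic(c(0, 0, 1, 2, 2), c(0, 0, 1, 0, 2),
                             c(1, 3, 1, 1, 1), 0:2, 0:2),
    "duplicate")
})

test_that("interpolate_heights builds a clamped, hull-limited height grid", {
  s <- plate_set(side = 4, z = 2)
  g <- interpolate_heights(s, nx = 10, ny = 10)
  expect_s3_class(g, "height_grid")
  expect_equal(g$base_z, 2)
  expect_equal(dim(g$heights), c(11, 11))
  expect_lt(max(abs(g$heights), na.rm = TRUE), 1e-6)  # heights above own base
  expect_equal(range(g$x_edges), range(s$coords[, 1]))
  expect_true(all(g$heights >= 0, na.rm = TRUE))
  expect_error(interpolate_heights(landmark_set(cbind(1:6, 2 * (1:6), 0))),
               "triangulation|collinear")
})

test_that("prism_volume matches the closed form on a uniform height field", {
  a <- 3; b <- 2; h <- 1.7
  grid <- structure(list(
    x_edges = seq(0, a, length.out = 13), y_edges = seq(0, b, length.out = 9),
    heights = matrix(h, 13, 9), base_z = 0, nx = 12L, ny = 8L,
    units = "cm", specimen_id = "slab", n_landmarks = 0L),
    class = "height_grid")
  v <- prism_volume(grid)
  expect_equal(v$volume, a * b * h, tolerance = 1e-9)
  expect_equal(v$n_cells_counted, 12 * 8)
  # linearity in height
  g2 <- grid; g2$heights <- grid$heights * 2.5
  expect_equal(prism_volume(g2)$volume, 2.5 * v$volume, tolerance = 1e-12)
  # undefined corners exclude their cells
  g3 <- grid; g3$heights[1, ] <- NA
  v3 <- prism_volume(g3)
  expect_equal(v3$n_cells_counted, 11 * 8)
  expect_equal(v3$volume, a * b * h * 11 / 12, tolerance = 1e-9)
  # zero-fill counts boundary cells at reduced height
  v4 <- prism_volume(g3, outside = "zero")
  expect_equal(v4$volume, a * b * h * (11 + 0.5) / 12, tolerance = 1e-9)
})

test_that("the pipeline recovers analytic volumes of dense synthetic shapes", {
  g <- generate_shape("hemisphere", radius = 5, n_secondary = 800,
                      sample_seed = 2)
  v <- estimate_volume(g$set, known_distance = g$scale_distance)
  expect_lt(abs(v$volume - g$analytic_volume) / g$analytic_volume, 0.05)
  expect_identical(v$units, "cm^3")
  expect_lte(v$n_cells_counted, 3600)

  gp <- generate_shape("step_pyramid", n_secondary = 1000, sample_seed = 2)
  vp <- estimate_volume(gp$set, known_distance = gp$scale_distance)
  expect_lt(abs(vp$volume - gp$analytic_volume) / gp$analytic_volume, 0.05)

  # center sampling is a near-equivalent estimator on smooth surfaces
  vc <- estimate_volume(g$set, known_distance = g$scale_distance,
                        cell_sample = "centers")
  expect_lt(abs(vc$volume - v$volume) / v$volume, 0.02)
})

test_that("volume converges with landmark count and grid resolution", {
  g <- generate_shape("hemisphere", radius = 5, n_secondary = 5000,
                      sample_seed = 2)
  v <- estimate_volume(g$set, known_distance = g$scale_distance,
                       nx = 200, ny = 200)
  expect_lt(abs(v$volume - g$analytic_volume) / g$analytic_volume, 0.02)
})

test_that("flat configurations have zero volume and runs are deterministic", {
  g <- generate_shape("flat_plate", n_secondary = 40)
  v <- estimate_volume(g$set, known_distance = g$scale_distance)
  expect_identical(v$volume, 0)
  ge <- generate_shape("half_ellipsoid", n_secondary = 150, sample_seed = 8)
  v1 <- estimate_volume(ge$set, known_distance = ge$scale_distance)
  v2 <- estimate_volume(ge$set, known_distance = ge$scale_distance)
  expect_identical(v1$volume, v2$volume)
})

test_that("volume is invariant under rigid motion of the input", {
  g <- generate_shape("half_ellipsoid", n_secondary = 200, sample_seed = 6)
  v0 <- estimate_volume(g$set, known_distance = g$scale_distance)$volume
  for (ps in c(5, 71)) {
    vp <- estimate_volume(apply_rigid(g$set, ps),
                          known_distance = g$scale_distance)$volume
    expect_equal(vp, v0, tolerance = 1e-6)
  }
  # pure xy-translation leaves the grid-following volume unchanged
  tr <- g$set; tr$coords[, 1] <- tr$coords[, 1] + 123.4
  expect_equal(estimate_volume(tr, known_distance = g$scale_distance)$volume,
               v0, tolerance = 1e-9)
})

test_that("estimate_volume tags errors with the failing stage", {
  line <- landmark_set(cbind(1:6, 2 * (1:6), 3 * (1:6)))
  expect_error(estimate_volume(line), "orient")
})
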