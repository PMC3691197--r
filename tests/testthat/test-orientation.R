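test_that("principal_frame recovers the primary principal axes under a known pose", {
  s0 <- tilted_fixture()
  # oracle: eigen-decomposition of the primary covariance of the aligned
  # configuration, computed directly here
  P <- s0$coords[s0$primary, ]
  ev <- eigen(cov(P), symmetric = TRUE)$values

  f0 <- principal_frame(s0)
  expect_equal(f0$axis_variances, ev, tolerance = 1e-12)
  expect_equal(unname(f0$translation), unname(colMeans(P)), tolerance = 1e-12)
  # already-aligned anisotropic plane configuration: frame is the identity
  expect_equal(f0$rotation, diag(3), tolerance = 1e-10)

  # frame invariants under an arbitrary known rigid motion
  s1 <- known_rigid(s0)
  f1 <- principal_frame(s1)
  expect_equal(t(f1$rotation) %*% f1$rotation, diag(3), tolerance = 1e-10)
  expect_equal(det(f1$rotation), 1, tolerance = 1e-10)
  expect_equal(f1$axis_variances, ev, tolerance = 1e-9)  # variances are pose-invariant
  expect_false(is.unsorted(rev(f1$axis_variances)))

  # orienting the moved copy restores the aligned coordinates
  expect_equal(orient(s1)$coords, orient(s0)$coords, tolerance = 1e-8)
})

test_that("degenerate primary configurations are rejected", {
  line <- landmark_set(cbind(1:6, 2 * (1:6), 0),
                       primary = TRUE)
  expect_error(principal_frame(line), "collinear|degenerate")
  two <- landmark_set(matrix(rnorm(9), 3, 3), primary = c(TRUE, TRUE, FALSE))
  expect_error(principal_frame(two), "at least 3")
})

test_that("orient centres, diagonalises and z-orders the primary covariance", {
  s <- known_rigid(tilted_fixture(secondary_z = 2), angles = c(1, 0.3, -2))
  o <- orient(s)
  P <- o$coords[o$primary, ]
  expect_lt(max(abs(colMeans(P))), 1e-9)
  C <- cov(P)
  expect_lt(max(abs(C[upper.tri(C)])) / max(diag(C)), 1e-9)
  expect_false(is.unsorted(rev(diag(C))))
  # trace (total variance) is conserved by the rotation
  expect_equal(sum(diag(C)), sum(diag(cov(s$coords[s$primary, ]))),
               tolerance = 1e-10)
  # the secondary bulge ends up at +z, and the primaries' z-variance is the
  # smallest covariance eigenvalue
  expect_gt(mean(o$coords[!o$primary, 3]), 0)
  expect_equal(var(P[, 3]), min(eigen(cov(s$coords[s$primary, ]))$values),
               tolerance = 1e-10)
  # idempotence
  expect_equal(orient(o)$coords, o$coords, tolerance = 1e-9)
})

test_that("secondary landmarks never influence the frame", {
  s <- tilted_fixture()
  f <- principal_frame(s)
  s2 <- s
  s2$coords[!s2$primary, 1:2] <- s2$coords[!s2$primary, 1:2] + 0.37
  expect_identical(principal_frame(s2)$rotation, f$rotation)
  expect_identical(principal_frame(s2)$translation, f$translation)
  # deleting a secondary point leaves the frame bit-identical
  keep <- s$primary | seq_len(n_landmarks(s)) != 8
  s3 <- landmark_set(s$coords[keep, ], labels = s$labels[keep],
                     primary = s$primary[keep])
  expect_identical(principal_frame(s3)$rotation, f$rotation)
})

test_that("two copies of one shape in different random poses orient identically", {
  g <- generate_shape("half_ellipsoid", n_secondary = 60, sample_seed = 4)
  o0 <- orient(g$set)
  for (ps in c(2, 17, 203)) {
    op <- orient(apply_rigid(g$set, ps))
    expect_equal(op$coords, o0$coords, tolerance = 1e-8)
  }
})

test_that("restore_scale rescales to the known distance and preserves shape", {
  s <- orient(tilted_fixture())
  d34 <- sqrt(sum((s$coords["P3", ] - s$coords["P4", ])^2))
  r <- restore_scale(s, known_distance = 5, pair = c("P3", "P4"))
  expect_equal(sqrt(sum((r$coords["P3", ] - r$coords["P4", ])^2)), 5,
               tolerance = 1e-9)
  expect_equal(r$scale_factor, 5 / d34, tolerance = 1e-12)
  expect_identical(r$units, "cm")
  # default pair is the 3rd and 4th primary landmarks
  rd <- restore_scale(s, known_distance = 5)
  expect_identical(rd$scale_pair, c("P3", "P4"))
  # rescaling changes no angles: all pairwise-distance ratios preserved
  D0 <- as.matrix(dist(s$coords)); D1 <- as.matrix(dist(r$coords))
  ratio <- D1[upper.tri(D1)] / D0[upper.tri(D0)]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-12)
})

test_that("restored coordinates are invariant to input pre-scaling", {
  s <- tilted_fixture()
  s_scaled <- s
  s_scaled$coords <- s$coords * 37.5
  a <- restore_scale(orient(s), 5)
  b <- restore_scale(orient(s_scaled), 5)
  expect_equal(a$coords, b$coords, tolerance = 1e-9)
})

test_that("restore_scale rejects bad pairs and distances", {
  s <- orient(tilted_fixture())
  expect_error(restore_scale(s, -1), "positive")
  expect_error(restore_scale(s, 5, pair = c("P1", "P1")), "distinct")
  expect_error(restore_scale(s, 5, pair = c("P1", "nope")), "unknown")
  dup <- s
  dup$coords["P2", ] <- dup$coords["P1", ]
  expect_error(restore_scale(dup, 5, pair = c("P1", "P2")), "coincident")
})
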