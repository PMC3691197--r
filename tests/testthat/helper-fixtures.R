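# Fixture builders shared across the suite. All randomness is seeded by the
# caller so every test is reproducible.

# random labelled cloud for I/O round trips
random_set <- function(seed, n = 10) {
  set.seed(seed)
  landmark_set(matrix(stats::rnorm(3 * n, sd = 10), ncol = 3),
               labels = paste0("L", seq_len(n)),
               specimen_id = paste0("rand", seed))
}

# 6 anisotropic primary points in the z = 0 plane with diagonal covariance
# (spread mostly along x, then y; P1 projects positively on both in-plane
# axes), plus optional secondary points bulging to +z
tilted_fixture <- function(secondary_z = 1) {
  prim <- cbind(c(4, -2, 0, 2, -4, 0), c(1, -1, 2, -1, 1, -2), 0)
  sec <- cbind(c(-1, 1, 0, 0.5), c(0.2, 0.4, -0.3, 1), secondary_z)
  landmark_set(rbind(prim, sec),
               labels = c(paste0("P", 1:6), paste0("S", 1:4)),
               primary = c(rep(TRUE, 6), rep(FALSE, 4)))
}

# rigid motion with known parameters, for frame-recovery oracles
known_rigid <- function(set, angles = c(0.4, -0.7, 1.1), t0 = c(3, -2, 5)) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  R <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE) %*%
       matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE) %*%
       matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  set$coords <- sweep(set$coords %*% t(R), 2, -t0)
  dimnames(set$coords) <- list(set$labels, c("x", "y", "z"))
  set
}

# dense coplanar cloud over a square at constant z (hull covers the square)
plate_set <- function(side = 4, z = 0, m = 8, seed = 5) {
  set.seed(seed)
  g <- expand.grid(x = seq(0, side, length.out = m),
                   y = seq(0, side, length.out = m))
  g$x <- g$x + c(0, stats::runif(m * m - 1, -0.01, 0.01))
  landmark_set(cbind(pmin(pmax(g$x, 0), side), g$y, z))
}
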