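#' Generate a synthetic landmark cloud on a surface of known volume
#'
#' Test fixtures standing in for physical reference models: landmark clouds
#' sampled on surfaces whose volume above the base plane is known in closed
#' form, so every pipeline stage can be validated against an analytic
#' oracle. Swelling-like shapes carry exactly 6 primary landmarks on the
#' base perimeter (coplanar by construction, mimicking the anatomical ring
#' of homologous points; the 3rd and 4th sit at a known separation for scale
#' tests) and `n_secondary` quasi-uniform points on the upper surface,
#' placed by a low-discrepancy spiral with seeded jitter.
#'
#' Kinds and their dimensions:
#' \describe{
#'   \item{hemisphere}{`radius`; volume `2/3 * pi * radius^3`.}
#'   \item{half_ellipsoid}{`semi_axes = c(a, b, c)` (base semi-axes a, b,
#'     height c); volume `2/3 * pi * a * b * c`.}
#'   \item{step_pyramid}{`sides` (level side lengths, largest first) and
#'     `step_height`; volume `step_height * sum(sides^2)`. Points are placed
#'     on the level plateaus and along both edges of each step riser.}
#'   \item{flat_plate}{`side`; a coplanar cloud, volume 0.}
#' }
#'
#' @param kind shape kind, see above.
#' @param radius,semi_axes,sides,step_height,side kind-specific dimensions
#'   (defaults: radius 5 cm; semi-axes 9, 7, 6 cm; the reference pyramid
#'   30/25/20/15/10 cm sides with 1.8 cm steps; plate side 10 cm).
#' @param n_secondary approximate number of secondary landmarks (>= 10).
#' @param noise_sd isotropic Gaussian coordinate noise, physical units
#'   (default 0: exact surface points).
#' @param sample_seed seed for surface sampling jitter and noise.
#' @param pose_seed if non-`NULL`, the cloud is put into a random rigid pose
#'   via [apply_rigid()] with this seed.
#' @param specimen_id identifier; defaults to `kind`.
#' @return list with `set` (a [landmark_set()], primaries designated),
#'   `analytic_volume`, and `scale_distance` (the true distance between the
#'   3rd and 4th primary landmarks, for [restore_scale()] round trips).
#' @export
generate_shape <- function(kind = c("hemisphere", "half_ellipsoid",
                                    "step_pyramid", "flat_plate"),
                           radius = 5, semi_axes = c(9, 7, 6),
                           sides = c(30, 25, 20, 15, 10), step_height = 1.8,
                           side = 10, n_secondary = 120, noise_sd = 0,
                           sample_seed = 1, pose_seed = NULL,
                           specimen_id = NULL) {
  kind <- match.arg(kind)
  if (n_secondary < 10) stop("n_secondary must be at least 10")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(sample_seed)

  # 6 primary landmarks on the base ring. The angles are deliberately
  # non-uniform, like an anatomical ring: a regular hexagon would make the
  # in-plane covariance isotropic and the PC1/PC2 axes numerically
  # arbitrary under rigid motion.
  ring6 <- function(fx, fy) {
    t <- c(-50, 0, 50, 130, 180, 230) * pi / 180
    cbind(fx(t), fy(t), 0)
  }
  spiral <- function(n) {                 # area-uniform low-discrepancy dome
    i <- seq_len(n) - 0.5
    zc <- i / n                           # z uniform on [0,1] <=> uniform cap area
    rho <- sqrt(pmax(1 - zc^2, 0))
    phi <- stats::runif(1, 0, 2 * pi) + i * pi * (3 - sqrt(5)) +
      stats::runif(n, -1, 1) * pi / n
    cbind(rho * cos(phi), rho * sin(phi), zc)
  }

  if (kind == "hemisphere") {
    stopifnot(radius > 0)
    prim <- ring6(function(t) radius * cos(t), function(t) radius * sin(t))
    sec <- spiral(n_secondary) * radius
    vol <- 2 / 3 * pi * radius^3
  } else if (kind == "half_ellipsoid") {
    stopifnot(length(semi_axes) == 3, all(semi_axes > 0))
    a <- semi_axes[1]; b <- semi_axes[2]; cc <- semi_axes[3]
    prim <- ring6(function(t) a * cos(t), function(t) b * sin(t))
    u <- spiral(n_secondary)
    sec <- cbind(a * u[, 1], b * u[, 2], cc * u[, 3])
    vol <- 2 / 3 * pi * a * b * cc
  } else if (kind == "step_pyramid") {
    stopifnot(all(diff(sides) < 0), all(sides > 0), step_height > 0)
    K <- length(sides); eps <- 0.03; delta <- 0.3
    n_rings <- 5L * K - 1L
    m <- max(4L, round(n_secondary / (4L * n_rings)))
    ring <- function(s, z, m) {           # square perimeter, jittered spacing
      tt <- seq(-s / 2, s / 2, length.out = m + 1L)[-(m + 1L)]
      tt <- tt + stats::runif(m, 0, (s / m) * 0.5)
      rbind(cbind(tt, -s / 2, z), cbind(s / 2, tt, z),
            cbind(-tt, s / 2, z), cbind(-s / 2, -tt, z))
    }
    # each riser gets a ring on its top edge and at its foot, plus "guard"
    # rings just beyond both: they keep the steep cross-riser gradients
    # confined to thin triangles so the cubic patches cannot balloon
    sec <- NULL
    for (k in seq_len(K)) {
      s <- sides[k]; ztop <- k * step_height; zbot <- (k - 1) * step_height
      sec <- rbind(sec,
                   ring(s, ztop, m),
                   ring(s - 2 * delta, ztop, m),
                   ring(s + 2 * eps, zbot, m),
                   ring(s + 2 * eps + 2 * delta, zbot, m))
      if (k < K) sec <- rbind(sec, ring((s + sides[k + 1]) / 2, ztop, m))
    }
    gg <- as.matrix(expand.grid(seq(-0.35, 0.35, length.out = 4) * sides[K],
                                seq(-0.35, 0.35, length.out = 4) * sides[K]))
    sec <- rbind(sec, cbind(gg, K * step_height))    # top plateau interior
    # 6 primaries on a square ring inside the lowest plateau annulus
    q <- if (K > 1) (sides[1] + sides[2]) / 4 else sides[1] / 4
    prim <- cbind(c(0, q, q, -q, -q, -q),
                  c(-q, -q, q, q, 0, -q / 2), step_height)
    vol <- step_height * sum(sides^2)
  } else {                                           # flat_plate
    stopifnot(side > 0)
    half <- side / 2
    prim <- cbind(c(-half, 0, half, half, 0, -half),
                  c(-half, -half, -half, half, half, half), 0)
    sec <- cbind(stats::runif(n_secondary, -half, half),
                 stats::runif(n_secondary, -half, half), 0)
    vol <- 0
  }

  coords <- rbind(prim, sec)
  labels <- c(paste0("P", 1:6), paste0("S", seq_len(nrow(sec))))
  if (noise_sd > 0)
    coords <- coords + matrix(stats::rnorm(length(coords), 0, noise_sd),
                              ncol = 3)
  scale_distance <- sqrt(sum((prim[3, ] - prim[4, ])^2))
  set <- landmark_set(coords, labels = labels,
                      primary = c(rep(TRUE, 6), rep(FALSE, nrow(sec))),
                      units = "cm",
                      specimen_id = if (is.null(specimen_id)) kind else specimen_id)
  if (!is.null(pose_seed)) set <- apply_rigid(set, pose_seed)
  list(set = set, analytic_volume = vol, scale_distance = scale_distance)
}

#' Apply a seeded random rigid motion to a landmark set
#'
#' Rotates the whole cloud by a rotation drawn uniformly from SO(3) and
#' translates it by a uniform offset in [-20, 20] per axis. Pairwise
#' distances are preserved exactly; used to test pose invariance of the
#' orientation and volume pipeline.
#'
#' @param set a [landmark_set()].
#' @param pose_seed integer seed; the same seed always yields the same pose.
#' @return the transformed set.
#' @export
apply_rigid <- function(set, pose_seed) {
  stopifnot(inherits(set, "landmark_set"))
  set.seed(pose_seed)
  qrd <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  tr <- stats::runif(3, -20, 20)
  set$coords <- sweep(set$coords %*% t(Q), 2, -tr)
  dimnames(set$coords) <- list(set$labels, c("x", "y", "z"))
  set
}

#' Labelled corner landmarks of an exact step pyramid
#'
#' Returns the corner points of a step pyramid as a landmark set labelled
#' `level{k}_{lower|upper}_corner{i}` (corners in ring order), the input
#' expected by [pyramid_edge_lengths()]. With `noise_sd > 0`, seeded
#' isotropic Gaussian noise emulates reconstruction error.
#'
#' @param sides level side lengths, largest first.
#' @param step_height step height.
#' @param noise_sd coordinate noise standard deviation (default 0).
#' @param seed noise seed.
#' @return a [landmark_set()] of `8 * length(sides)` labelled corners.
#' @export
pyramid_corners <- function(sides = c(30, 25, 20, 15, 10), step_height = 1.8,
                            noise_sd = 0, seed = 1) {
  stopifnot(all(sides > 0), step_height > 0)
  cx <- c(-1, 1, 1, -1) / 2; cy <- c(-1, -1, 1, 1) / 2
  coords <- NULL; labels <- character(0)
  for (k in seq_along(sides)) {
    for (ring in c("lower", "upper")) {
      z <- (k - 1L + (ring == "upper")) * step_height
      coords <- rbind(coords, cbind(cx * sides[k], cy * sides[k], z))
      labels <- c(labels, sprintf("level%d_%s_corner%d", k, ring, 1:4))
    }
  }
  if (noise_sd > 0) {
    set.seed(seed)
    coords <- coords + matrix(stats::rnorm(length(coords), 0, noise_sd),
                              ncol = 3)
  }
  landmark_set(coords, labels = labels, primary = TRUE, units = "cm",
               specimen_id = "step_pyramid_corners")
}
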