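#' Principal-axes orientation frame of the primary landmarks
#'
#' Computes the rigid frame that orients a configuration by the spatial
#' principal components of its primary landmarks: the translation is the
#' primary-landmark centroid, and the rotation columns are the unit
#' eigenvectors of the primary-point covariance in eigenvalue-descending
#' order. PC1 and PC2 then span the best-fitting (least-squares) plane
#' through the primary points and PC3 is its normal — the direction of
#' tissue swelling. For a single configuration the Procrustes superimposition
#' step is degenerate (an object needs no alignment with itself), so the
#' frame reduces to this centering and eigen-rotation.
#'
#' Axis signs are fixed deterministically (eigenvectors are defined only up
#' to sign) by an intrinsic, pose-independent convention: PC1 and PC2 are
#' directed so that the first primary landmark (in configuration order) with
#' a non-negligible projection projects positively onto them; PC3 = PC1 x
#' PC2 so the rotation is proper (det +1); finally, if the secondary
#' landmarks lie on average below the primary plane, PC2 and PC3 are both
#' negated so that the tissue bulge points to +z. Because every rule refers
#' to the configuration itself, differently-posed copies of one shape orient
#' to identical coordinates.
#'
#' @param set a [landmark_set()] with at least 3 non-collinear primary
#'   landmarks.
#' @return an object of class `rigid_frame`: list with `rotation` (3x3,
#'   orthogonal, det +1), `translation` (primary centroid in input
#'   coordinates) and `axis_variances` (covariance eigenvalues,
#'   non-increasing).
#' @export
principal_frame <- function(set) {
  stopifnot(inherits(set, "landmark_set"))
  P <- .primary_coords(set)
  if (nrow(P) < 3L)
    stop("orientation needs at least 3 primary landmarks, got ", nrow(P))
  ctr <- colMeans(P)
  C <- stats::cov(P)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  if (vals[2] <= 1e-12 * vals[1])
    stop("degenerate primary configuration: points are collinear or coincident")
  R <- e$vectors
  P0 <- sweep(P, 2, ctr)
  tol <- 1e-9 * sqrt(vals[1])
  for (j in 1:2) {
    pr <- P0 %*% R[, j]
    k <- which(abs(pr) > tol)[1]
    if (!is.na(k)) {
      if (pr[k] < 0) R[, j] <- -R[, j]
    } else {                              # all primaries on the axis plane
      k2 <- which.max(abs(R[, j]))
      if (R[k2, j] < 0) R[, j] <- -R[, j]
    }
  }
  R[, 3] <- c(R[2, 1] * R[3, 2] - R[3, 1] * R[2, 2],
              R[3, 1] * R[1, 2] - R[1, 1] * R[3, 2],
              R[1, 1] * R[2, 2] - R[2, 1] * R[1, 2])
  if (any(!set$primary)) {
    S <- set$coords[!set$primary, , drop = FALSE]
    zbar <- mean(sweep(S, 2, ctr) %*% R[, 3])
    if (zbar < 0) { R[, 2] <- -R[, 2]; R[, 3] <- -R[, 3] }
  }
  structure(list(rotation = R, translation = ctr, axis_variances = vals),
            class = "rigid_frame")
}

#' @export
print.rigid_frame <- function(x, ...) {
  cat("Rigid frame (principal axes of primary landmarks)\n")
  cat("  axis variances:", format(x$axis_variances, digits = 6), "\n")
  cat("  translation:   ", format(x$translation, digits = 6), "\n")
  print(round(x$rotation, 6))
  invisible(x)
}

#' Orient a landmark set by its primary principal axes
#'
#' Transforms every landmark — primary and secondary — by the frame computed
#' from the primary landmarks alone ([principal_frame()]). After orientation
#' the primary centroid is the origin, the primary covariance is diagonal
#' with variances non-increasing along x, y, z, and z (PC3) is the direction
#' of interest for volume computation. Secondary landmarks are affected by,
#' but never influence, the frame.
#'
#' @param set a [landmark_set()].
#' @return an `oriented_landmark_set` (also a `landmark_set`) carrying the
#'   frame; coordinates are still in input units until [restore_scale()].
#' @export
orient <- function(set) {
  frame <- principal_frame(set)
  out <- set
  out$coords <- sweep(set$coords, 2, frame$translation) %*% frame$rotation
  dimnames(out$coords) <- list(set$labels, c("x", "y", "z"))
  out$frame <- frame
  out$scale_factor <- 1
  out$scale_pair <- NULL
  out$known_distance <- NA_real_
  class(out) <- c("oriented_landmark_set", "landmark_set")
  out
}

#' Restore physical scale from one known distance
#'
#' Photogrammetric reconstructions are determined only up to scale. Scale is
#' restored by multiplying all coordinates by the ratio of a physically
#' measured distance between two primary landmarks to the same distance in
#' the reconstruction. The conventional pair is the 3rd and 4th primary
#' landmarks (the points where callosities, labia and swelling meet on
#' either side); for field recordings without a measured reference a
#' standardized distance of 5 cm between them is assumed.
#'
#' @param set an `oriented_landmark_set` from [orient()].
#' @param known_distance the measured physical distance (default 5).
#' @param pair labels of the two landmarks the distance refers to; default
#'   the 3rd and 4th primary landmarks in configuration order.
#' @param units unit tag of `known_distance` (default `"cm"`).
#' @return the set with all coordinates rescaled, `units` set, and
#'   `scale_factor`, `scale_pair`, `known_distance` recorded.
#' @export
restore_scale <- function(set, known_distance = 5, pair = NULL, units = "cm") {
  stopifnot(inherits(set, "landmark_set"))
  if (!is.numeric(known_distance) || known_distance <= 0)
    stop("known_distance must be a positive number")
  if (is.null(pair)) {
    pl <- primary_labels(set)
    if (length(pl) < 4L)
      stop("default scale pair needs at least 4 primary landmarks")
    pair <- pl[3:4]
  }
  if (length(pair) != 2L || pair[1] == pair[2])
    stop("pair must name two distinct landmarks")
  missing <- setdiff(pair, set$labels)
  if (length(missing))
    stop("unknown landmark label(s): ", paste(missing, collapse = ", "))
  d <- sqrt(sum((set$coords[pair[1], ] - set$coords[pair[2], ])^2))
  if (d <= 0) stop("scale pair landmarks are coincident (zero distance)")
  s <- known_distance / d
  set$coords <- set$coords * s
  set$units <- units
  set$scale_factor <- if (is.null(set$scale_factor)) s else s * set$scale_factor
  set$scale_pair <- pair
  set$known_distance <- known_distance
  set
}
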