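#' Bundle repeated measurements of one known quantity
#'
#' A measurement panel holds repeated reconstructed measurements of the same
#' physical quantity (e.g. the eight reconstructed side lengths of one
#' pyramid level) together with its true value, for accuracy statistics.
#'
#' @param measurements positive numeric vector.
#' @param true_value the known physical value (same units).
#' @param label description, e.g. `"plane 3 side lengths"`.
#' @return an object of class `measurement_panel`.
#' @export
measurement_panel <- function(measurements, true_value, label = "") {
  measurements <- as.numeric(measurements)
  if (!length(measurements)) stop("empty measurement panel")
  if (any(!is.finite(measurements)) || any(measurements <= 0))
    stop("measurements must be positive and finite")
  if (!is.numeric(true_value) || true_value <= 0)
    stop("true_value must be positive")
  structure(list(measurements = measurements, true_value = true_value,
                 label = label), class = "measurement_panel")
}

#' Average error percentage of a measurement panel
#'
#' The accuracy statistic of the pyramid validation: the absolute relative
#' error of the panel mean, `|mean(measurements) - true| / true * 100`.
#' (Error of the mean, not mean of per-measurement errors: this is the
#' formula that reproduces the published per-plane accuracy values.)
#'
#' @param panel a [measurement_panel()].
#' @return the error percentage (scalar).
#' @export
avg_error_percentage <- function(panel) {
  stopifnot(inherits(panel, "measurement_panel"))
  abs(mean(panel$measurements) - panel$true_value) / panel$true_value * 100
}

#' Pooled root-mean-square error percentage
#'
#' Root mean square of the per-measurement percentage errors, pooled across
#' panels. This is this package's documented aggregation; published aggregate
#' RMS figures may follow a different (unstated) pooling and are not asserted
#' against it.
#'
#' @param panels a list of [measurement_panel()] objects (a single panel is
#'   accepted).
#' @return the pooled RMS error percentage (scalar).
#' @export
rms_error_percentage <- function(panels) {
  if (inherits(panels, "measurement_panel")) panels <- list(panels)
  if (!length(panels)) stop("empty panel list")
  pct <- unlist(lapply(panels, function(p) {
    stopifnot(inherits(p, "measurement_panel"))
    (p$measurements - p$true_value) / p$true_value * 100
  }))
  sqrt(mean(pct^2))
}

#' Mean and sample standard deviation of replicate volumes
#'
#' Summarises repeated, independent volume analyses of the same specimen.
#' The standard deviation uses the sample (n-1) denominator.
#'
#' @param volumes numeric vector of at least 2 replicate volumes.
#' @return list with `mean` and `sd`.
#' @export
replicate_summary <- function(volumes) {
  volumes <- as.numeric(volumes)
  if (length(volumes) < 2L)
    stop("need at least 2 replicate volumes for a standard deviation")
  list(mean = mean(volumes), sd = stats::sd(volumes))
}

#' Volume ratio as a percentage
#'
#' @param numerator,denominator volumes in the same units; `denominator > 0`.
#' @return `numerator / denominator * 100`.
#' @export
volume_ratio <- function(numerator, denominator) {
  if (!is.numeric(denominator) || denominator <= 0)
    stop("denominator must be positive")
  numerator / denominator * 100
}

#' Volume increase between two swelling states
#'
#' @param swollen,unswollen `volume_estimate` objects for the same specimen
#'   in the two states (or bare numbers, taken to share units).
#' @return the difference `swollen - unswollen`; negative values are allowed
#'   but reported with a warning.
#' @export
swelling_change <- function(swollen, unswollen) {
  vol <- function(v) if (inherits(v, "volume_estimate")) v$volume else as.numeric(v)
  if (inherits(swollen, "volume_estimate") &&
      inherits(unswollen, "volume_estimate") &&
      !identical(swollen$units, unswollen$units))
    stop("unit mismatch: ", swollen$units, " vs ", unswollen$units)
  d <- vol(swollen) - vol(unswollen)
  if (d < 0) warning("negative volume change (swollen < unswollen)")
  d
}

#' Edge-length panels of a labelled step-pyramid corner set
#'
#' Consumes a landmark set whose labels follow the scheme
#' `level{k}_{lower|upper}_corner{i}` (k = 1..n levels, i = 1..4, corners in
#' ring order) and returns, per level, one panel of the 8 horizontal edge
#' lengths (4 lower + 4 upper) against the level's true side length, and one
#' panel of the 4 vertical corner-to-corner heights against the true step
#' height. All lengths are Euclidean distances, hence pose-invariant.
#'
#' @param corners a [landmark_set()] with the labelled pyramid corners.
#' @param true_sides true side length per level, largest first.
#' @param true_height true step height (one value for all levels).
#' @return a named list of [measurement_panel()]s
#'   (`plane1_lengths`, `plane1_heights`, ...).
#' @export
pyramid_edge_lengths <- function(corners, true_sides = c(30, 25, 20, 15, 10),
                                 true_height = 1.8) {
  stopifnot(inherits(corners, "landmark_set"))
  lab <- function(k, ring, i) sprintf("level%d_%s_corner%d", k, ring, i)
  get <- function(l) {
    if (!l %in% corners$labels) stop("missing labelled corner: ", l)
    corners$coords[l, ]
  }
  d <- function(a, b) sqrt(sum((a - b)^2))
  panels <- list()
  for (k in seq_along(true_sides)) {
    lengths <- heights <- numeric(0)
    for (ring in c("lower", "upper")) {
      p <- lapply(1:4, function(i) get(lab(k, ring, i)))
      lengths <- c(lengths, vapply(1:4, function(i)
        d(p[[i]], p[[i %% 4 + 1]]), numeric(1)))
    }
    heights <- vapply(1:4, function(i)
      d(get(lab(k, "lower", i)), get(lab(k, "upper", i))), numeric(1))
    panels[[sprintf("plane%d_lengths", k)]] <-
      measurement_panel(lengths, true_sides[k],
                        sprintf("plane %d side lengths", k))
    panels[[sprintf("plane%d_heights", k)]] <-
      measurement_panel(heights, true_height,
                        sprintf("plane %d heights", k))
  }
  panels
}
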