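#' Draw a random landmark subset, keeping all primary landmarks
#'
#' Emulates variation in landmarking density: all primary landmarks are
#' retained and a fraction of the secondary landmarks is drawn uniformly
#' without replacement. The number drawn is `round(fraction/100 * n_secondary)`
#' (half away from zero), with a minimum of 1. Original configuration order
#' is preserved among the retained landmarks.
#'
#' @param set a [landmark_set()] with at least one secondary landmark.
#' @param fraction percentage of secondary landmarks to retain, in (0, 100].
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used (as inside [bootstrap_volumes()]).
#' @param of `"secondary"` (default: the fraction applies to the secondary
#'   landmarks, the primaries being retained separately) or `"total"` (the
#'   fraction applies to the full landmark count, primaries counted in).
#' @return a smaller `landmark_set`.
#' @export
draw_subset <- function(set, fraction, seed = NULL,
                        of = c("secondary", "total")) {
  stopifnot(inherits(set, "landmark_set"))
  of <- match.arg(of)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 100)
    stop("fraction must be in (0, 100]")
  sec <- which(!set$primary)
  if (!length(sec)) stop("set has no secondary landmarks to subsample")
  if (!is.null(seed)) set.seed(seed)
  n_target <- if (of == "secondary") length(sec) else n_landmarks(set)
  m <- max(1L, floor(fraction / 100 * n_target + 0.5))
  if (of == "total") m <- max(1L, m - sum(set$primary))
  m <- min(m, length(sec))
  keep <- sort(c(which(set$primary),
                 if (m == length(sec)) sec else sample(sec, m)))
  out <- set
  out$labels <- set$labels[keep]
  out$coords <- set$coords[keep, , drop = FALSE]
  out$primary <- set$primary[keep]
  out
}

#' Bootstrap volume estimates under random landmark subsets
#'
#' For each fraction, draws `n_reps` random secondary-landmark subsets
#' (primaries always retained), runs the full volume pipeline on each, and
#' summarises replicate volumes by their mean and sample variance. This
#' reproduces the mean/variance structure seen when landmark number and
#' density vary: mean volume rises asymptotically with landmark coverage
#' while the variance of the estimates falls.
#'
#' Replicate RNG streams are derived from `seed` by a fixed counter scheme,
#' so the full list of volumes is reproducible bit-for-bit and independent
#' of evaluation order. A replicate whose subset cannot be triangulated is
#' redrawn up to `max_retries` times, then recorded as missing; summaries
#' report the effective replicate count.
#'
#' @param set a [landmark_set()] with primary landmarks designated.
#' @param fractions percentages of secondary landmarks to retain
#'   (default `c(25, 50, 75, 90)`).
#' @param n_reps replicates per fraction (default 100).
#' @param seed integer seed for the whole analysis.
#' @param keep_primary must be `TRUE` (the protocol always retains the
#'   homologous landmarks); present to make the convention explicit.
#' @param max_retries redraw attempts for degenerate subsets.
#' @param of fraction basis, see [draw_subset()].
#' @param ... passed to [estimate_volume()] (`known_distance`, `scale_pair`,
#'   `nx`, `ny`, ...).
#' @return an object of class `subsample_summary`: `replicates` (data frame
#'   fraction/replicate/n_landmarks/volume), `summary` (data frame
#'   fraction/n_effective/mean_volume/variance), and the `settings` used.
#' @export
bootstrap_volumes <- function(set, fractions = c(25, 50, 75, 90),
                              n_reps = 100, seed = 1, keep_primary = TRUE,
                              max_retries = 10, of = "secondary", ...) {
  stopifnot(inherits(set, "landmark_set"), n_reps >= 1,
            all(fractions > 0 & fractions <= 100))
  if (!isTRUE(keep_primary))
    stop("the protocol always retains the primary landmarks")
  rep_rows <- vector("list", length(fractions) * n_reps)
  k <- 0L
  counter <- 0L
  for (f in fractions) {
    for (r in seq_len(n_reps)) {
      counter <- counter + 1L
      set.seed((as.integer(seed) + 99991L * counter) %% .Machine$integer.max)
      vol <- NA_real_; nl <- NA_integer_
      for (try in seq_len(max_retries + 1L)) {
        sub <- draw_subset(set, f, seed = NULL, of = of)
        est <- tryCatch(estimate_volume(sub, ...), error = function(e) NULL)
        if (!is.null(est)) { vol <- est$volume; nl <- n_landmarks(sub); break }
      }
      k <- k + 1L
      rep_rows[[k]] <- data.frame(specimen_id = set$specimen_id, fraction = f,
                                  replicate = r, n_landmarks = nl, volume = vol)
    }
  }
  reps <- do.call(rbind, rep_rows)
  summ <- do.call(rbind, lapply(split(reps, reps$fraction), function(d) {
    v <- d$volume[!is.na(d$volume)]
    data.frame(fraction = d$fraction[1], n_effective = length(v),
               mean_volume = mean(v),
               variance = if (length(v) > 1) stats::var(v) else 0)
  }))
  summ <- summ[order(summ$fraction), ]
  rownames(summ) <- NULL
  structure(list(replicates = reps, summary = summ,
                 settings = list(fractions = fractions, n_reps = n_reps,
                             seed = seed, keep_primary = TRUE, of = of)),
            class = "subsample_summary")
}

#' @export
print.subsample_summary <- function(x, ...) {
  cat("Bootstrap landmark subsampling (", x$settings$n_reps, " replicates, seed ",
      x$settings$seed, ")\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
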