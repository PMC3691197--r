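#' Construct a landmark set
#'
#' A landmark set is a labelled 3D point cloud with a primary/secondary
#' designation per landmark. Primary landmarks are homologous anatomical
#' points identifiable on every specimen at any time (for anogenital
#' swellings: the middle of the anus, the upper end of the vaginal entrance,
#' and the four points where callosities, labia and swelling meet); they alone
#' define the orientation frame. Secondary landmarks (scars, wrinkles, debris)
#' describe the surface and are affected by, but never influence, alignment.
#'
#' @param coords numeric matrix with one row per landmark and columns x, y, z.
#' @param labels character vector of unique landmark identifiers. Defaults to
#'   `"L1"`, `"L2"`, ... File order is meaningful: cross-references such as
#'   "the 3rd and 4th landmarks" use 1-based position in this order.
#' @param primary logical vector marking primary landmarks (recycled if length
#'   one). Defaults to all `TRUE`; use [designate_primary()] to demote.
#' @param units free-text unit tag; `"unscaled"` until scale restoration.
#' @param specimen_id identifier carried through to volume reports.
#' @return an object of class `landmark_set`.
#' @seealso [designate_primary()], [read_pointlist()], [read_ntsys()]
#' @export
landmark_set <- function(coords, labels = NULL, primary = TRUE,
                         units = "unscaled", specimen_id = "") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("coords must have 3 columns (x, y, z)")
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (n < 1L) stop("a landmark set needs at least one landmark")
  if (is.null(labels)) labels <- paste0("L", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("length of labels (", length(labels), ") != number of landmarks (", n, ")")
  if (anyDuplicated(labels))
    stop("duplicate landmark labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  primary <- rep_len(as.logical(primary), n)
  if (anyNA(primary)) stop("primary mask must not contain NA")
  if (!all(is.finite(coords)))
    stop("all coordinates must be finite")
  dimnames(coords) <- list(labels, c("x", "y", "z"))
  structure(
    list(labels = labels, coords = coords, primary = primary,
         units = units, specimen_id = specimen_id),
    class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("Landmark set", if (nzchar(x$specimen_id)) paste0("'", x$specimen_id, "'"),
      "\n")
  cat("  ", n_landmarks(x), " landmarks (", sum(x$primary), " primary, ",
      sum(!x$primary), " secondary), units: ", x$units, "\n", sep = "")
  bb <- apply(x$coords, 2, range)
  cat(sprintf("  extent: x [%.4g, %.4g]  y [%.4g, %.4g]  z [%.4g, %.4g]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Number of landmarks in a set
#' @param set a `landmark_set`.
#' @export
n_landmarks <- function(set) nrow(set$coords)

#' Labels of the primary landmarks, in configuration order
#' @param set a `landmark_set`.
#' @export
primary_labels <- function(set) set$labels[set$primary]

#' Designate which landmarks are primary
#'
#' Marks exactly the named landmarks as primary and demotes all others to
#' secondary. Calling with all labels promotes every landmark to primary (as
#' done after orientation, when all points enter the volume computation).
#' The operation is idempotent and never reorders landmarks.
#'
#' @param set a `landmark_set`.
#' @param primary_labels character vector of labels to mark primary.
#' @return the set with the new primary mask. If fewer than 3 labels are
#'   given the set is returned with a warning: orientation needs at least 3
#'   primary points to define a plane.
#' @export
designate_primary <- function(set, primary_labels) {
  stopifnot(inherits(set, "landmark_set"))
  primary_labels <- as.character(primary_labels)
  missing <- setdiff(primary_labels, set$labels)
  if (length(missing))
    stop("unknown landmark label(s): ", paste(missing, collapse = ", "))
  if (length(primary_labels) < 3L)
    warning("fewer than 3 primary landmarks: orientation will be infeasible")
  set$primary <- set$labels %in% primary_labels
  set
}

# coords of primary landmarks only
.primary_coords <- function(set) set$coords[set$primary, , drop = FALSE]
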