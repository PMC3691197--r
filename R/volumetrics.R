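#' Base plane of an oriented configuration
#'
#' The volume of the tissue is measured above the horizontal plane
#' `z = base_z` passing through the lowest z value over all landmarks,
#' primary and secondary. Note the documented sensitivity: the lowest point
#' can differ between replicate landmarkings, shifting the cutting plane and
#' hence the absolute volume.
#'
#' @param set an oriented [landmark_set()].
#' @return the base-plane height `base_z` (minimum z).
#' @export
base_plane <- function(set) {
  stopifnot(inherits(set, "landmark_set"))
  if (n_landmarks(set) < 1L) stop("empty landmark set")
  min(set$coords[, 3])
}

# Piecewise-cubic interpolation of scattered (x, y, z) onto grid nodes.
# Returns a length(xo) x length(yo) matrix, NA outside the convex hull.
# Duplicate xy sites (within `tol`) are merged by averaging z, with a warning.
.interp_cubic <- function(x, y, z, xo, yo, tol = 1e-9, degree = 1) {
  key <- paste(round(x / tol), round(y / tol))
  if (anyDuplicated(key)) {
    warning("duplicate xy landmark positions merged by averaging z")
    x <- tapply(x, key, mean)[unique(key)]
    y <- tapply(y, key, mean)[unique(key)]
    z <- tapply(z, key, mean)[unique(key)]
  }
  if (length(x) < 4L)
    stop("interpolation needs at least 4 distinct xy positions")
  # s-hull first (fast); deldir is robust to the exactly-collinear point runs
  # of engineered surfaces that make s-hull give up
  tri <- tryCatch(
    interp::triangles(suppressWarnings(interp::tri.mesh(x, y)))[, 1:3,
                                                                drop = FALSE],
    error = function(e) NULL)
  if (is.null(tri))
    tri <- tryCatch(
      deldir::triMat(suppressMessages(deldir::deldir(as.numeric(x),
                                                     as.numeric(y)))),
      error = function(e)
        stop("triangulation of landmark xy positions failed: ",
             conditionMessage(e), call. = FALSE))
  pts <- cbind(as.numeric(x), as.numeric(y))
  grad <- cpp_vertex_gradients(pts, as.numeric(z), tri, degree)
  q <- expand.grid(x = xo, y = yo)
  v <- cpp_eval_cubic(pts, as.numeric(z), grad, tri, q$x, q$y)
  matrix(v, nrow = length(xo), ncol = length(yo))
}

#' Interpolate landmark heights onto a regular grid
#'
#' Builds the smoothed surface of the reconstruction: heights above the base
#' plane are interpolated onto the nodes of a regular `nx` by `ny` cell grid
#' spanning the xy bounding box of the landmarks, using piecewise-cubic
#' interpolation over the Delaunay triangulation of all landmark xy
#' positions. Nodes outside the convex hull of the landmarks are undefined
#' (`NA`): the interpolant is hull-limited and extrapolation would invent
#' tissue. Negative interpolated heights (cubic overshoot below the lowest
#' landmark) are clamped to 0.
#'
#' @param set an oriented, scaled [landmark_set()].
#' @param nx,ny number of grid cells per axis (default 60x60, i.e. 61x61
#'   nodes).
#' @param gradient vertex-gradient estimation scheme: `"plane"` (default;
#'   weighted local plane fits, bounded by the data slopes and robust on
#'   sparse clouds) or `"quadratic"` (weighted quadratic fits, reproduces
#'   quadratic surfaces exactly but can overshoot on sparse, steep data).
#' @return an object of class `height_grid`: `x_edges`, `y_edges` (node
#'   coordinates), `heights` ((nx+1) x (ny+1), `NA` outside the hull),
#'   `base_z`, `nx`, `ny`, `units`.
#' @export
interpolate_heights <- function(set, nx = 60, ny = 60,
                                gradient = c("plane", "quadratic")) {
  stopifnot(inherits(set, "landmark_set"), nx >= 1, ny >= 1)
  gradient <- match.arg(gradient)
  xy <- set$coords
  base_z <- base_plane(set)
  x_edges <- seq(min(xy[, 1]), max(xy[, 1]), length.out = nx + 1L)
  y_edges <- seq(min(xy[, 2]), max(xy[, 2]), length.out = ny + 1L)
  h <- .interp_cubic(xy[, 1], xy[, 2], xy[, 3], x_edges, y_edges,
                     degree = if (gradient == "plane") 1L else 2L) - base_z
  h[!is.na(h) & h < 0] <- 0
  structure(list(x_edges = x_edges, y_edges = y_edges, heights = h,
                 base_z = base_z, nx = as.integer(nx), ny = as.integer(ny),
                 units = set$units, specimen_id = set$specimen_id,
                 n_landmarks = n_landmarks(set)),
            class = "height_grid")
}

#' @export
print.height_grid <- function(x, ...) {
  cat("Height grid ", x$nx, "x", x$ny, " cells (base z = ",
      format(x$base_z, digits = 6), ", units: ", x$units, ")\n", sep = "")
  cat("  defined nodes:", sum(!is.na(x$heights)), "of", length(x$heights), "\n")
  invisible(x)
}

#' Prism-sum volume of a height grid
#'
#' Each grid cell defines a rectangular prism whose height is the average of
#' the interpolated heights at its four corner nodes; the volume is the sum
#' of the prism volumes. Cells touching an undefined (outside-hull) node
#' contribute nothing under `outside = "exclude"` (default); with
#' `outside = "zero"` undefined corners count as height 0, which adds the
#' partial prisms of boundary cells. With `cell_sample = "centers"` the
#' prism height is the interpolated height at the cell center instead of
#' the corner average (requires the `set` used to build the grid).
#'
#' @param grid a `height_grid` from [interpolate_heights()].
#' @param outside `"exclude"` or `"zero"`; see above.
#' @param cell_sample `"corners"` (default) or `"centers"`.
#' @param set the oriented landmark set, only needed for
#'   `cell_sample = "centers"`.
#' @return an object of class `volume_estimate`: `volume` (cubic units),
#'   `units`, `n_landmarks`, `n_cells_counted`, `grid`, `base_z`,
#'   `specimen_id`.
#' @export
prism_volume <- function(grid, outside = c("exclude", "zero"),
                         cell_sample = c("corners", "centers"), set = NULL) {
  stopifnot(inherits(grid, "height_grid"))
  outside <- match.arg(outside)
  cell_sample <- match.arg(cell_sample)
  nx <- grid$nx; ny <- grid$ny
  dx <- diff(grid$x_edges); dy <- diff(grid$y_edges)
  area <- outer(dx, dy)
  if (cell_sample == "corners") {
    h <- grid$heights
    if (outside == "zero") h[is.na(h)] <- 0
    hm <- (h[-(nx + 1L), -(ny + 1L)] + h[-1L, -(ny + 1L)] +
           h[-(nx + 1L), -1L] + h[-1L, -1L]) / 4
  } else {
    if (is.null(set)) stop("cell_sample = 'centers' needs the landmark set")
    xc <- (grid$x_edges[-1L] + grid$x_edges[-(nx + 1L)]) / 2
    yc <- (grid$y_edges[-1L] + grid$y_edges[-(ny + 1L)]) / 2
    hm <- .interp_cubic(set$coords[, 1], set$coords[, 2], set$coords[, 3],
                        xc, yc) - grid$base_z
    hm[!is.na(hm) & hm < 0] <- 0
    if (outside == "zero") hm[is.na(hm)] <- 0
  }
  counted <- !is.na(hm)
  vol <- sum(area[counted] * hm[counted])
  structure(list(volume = vol,
                 units = if (identical(grid$units, "unscaled")) "unscaled"
                         else paste0(grid$units, "^3"),
                 n_landmarks = grid$n_landmarks,
                 n_cells_counted = sum(counted),
                 grid = c(nx = nx, ny = ny), base_z = grid$base_z,
                 specimen_id = grid$specimen_id),
            class = "volume_estimate")
}

#' @export
print.volume_estimate <- function(x, ...) {
  cat("Volume estimate", if (nzchar(x$specimen_id)) paste0("'", x$specimen_id, "'"),
      "\n")
  cat("  volume:", format(x$volume, digits = 8), x$units, "\n")
  cat("  ", x$n_landmarks, " landmarks, ", x$n_cells_counted, "/",
      x$grid[1] * x$grid[2], " cells, grid ", x$grid[1], "x", x$grid[2],
      ", base z = ", format(x$base_z, digits = 6), "\n", sep = "")
  invisible(x)
}

#' End-to-end volume estimation from a raw landmark set
#'
#' Runs the full pipeline: orientation by the primary principal axes
#' ([orient()]), scale restoration from one known distance
#' ([restore_scale()]), base plane ([base_plane()]), cubic height-grid
#' interpolation ([interpolate_heights()]), and prism summation
#' ([prism_volume()]). Deterministic for a fixed input.
#'
#' @param set a [landmark_set()] with primary landmarks designated.
#' @param known_distance,scale_pair,units passed to [restore_scale()].
#' @param nx,ny grid cells per axis (default 60x60).
#' @param outside,cell_sample passed to [prism_volume()].
#' @return a `volume_estimate`.
#' @export
estimate_volume <- function(set, known_distance = 5, scale_pair = NULL,
                            units = "cm", nx = 60, ny = 60,
                            outside = c("exclude", "zero"),
                            cell_sample = c("corners", "centers")) {
  stage <- function(what, expr)
    tryCatch(expr, error = function(e)
      stop(what, ": ", conditionMessage(e), call. = FALSE))
  oset <- stage("orient", orient(set))
  oset <- stage("restore_scale",
                restore_scale(oset, known_distance, scale_pair, units))
  grid <- stage("interpolate_heights", interpolate_heights(oset, nx, ny))
  stage("prism_volume",
        prism_volume(grid, outside = outside, cell_sample = cell_sample,
                     set = oset))
}
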