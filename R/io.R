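#' Read landmarks from an NTSYS-pc rectangular matrix file
#'
#' NTSYS-pc files carry an optional leading comment (lines starting with
#' `"`), then a header `type nrows ncols missing` and the matrix body. Two
#' dialects are auto-detected by the header dimensions:
#' \describe{
#'   \item{wide}{one row per specimen with `3k` columns `x1 y1 z1 x2 ...`;
#'     the file must contain exactly one specimen row.}
#'   \item{long}{one row per landmark with 3 columns `x y z`.}
#' }
#' A row-count suffix `L` (e.g. `96L`) declares row labels, which become the
#' landmark labels in the long dialect. Without labels, landmarks are named
#' `L1`, `L2`, ... in file order (file order is the configuration order).
#'
#' All landmarks are read as primary; apply [designate_primary()] afterwards.
#'
#' @param path path to the file.
#' @param specimen_id specimen identifier; defaults to the file name.
#' @return a [landmark_set()].
#' @export
read_ntsys <- function(path, specimen_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  # leading comment lines start with a double quote
  while (length(lines) && startsWith(trimws(lines[1]), "\"")) lines <- lines[-1]
  if (!length(lines)) stop("empty NTSYS file: ", path)

  hdr <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  if (length(hdr) < 4L)
    stop("malformed NTSYS header (need 'type nrows ncols missing'): ", lines[1])
  nr_tok <- hdr[2]; nc_tok <- hdr[3]
  row_labels <- grepl("[Ll]$", nr_tok)
  col_labels <- grepl("[Ll]$", nc_tok)
  nr <- suppressWarnings(as.integer(sub("[Ll]$", "", nr_tok)))
  nc <- suppressWarnings(as.integer(sub("[Ll]$", "", nc_tok)))
  if (is.na(nr) || is.na(nc) || nr < 1L || nc < 1L)
    stop("malformed NTSYS header dimensions: ", lines[1])

  body <- lines[-1]
  tokens <- unlist(strsplit(trimws(body), "[[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]

  labels <- NULL
  if (col_labels) {                      # one line of column labels precedes data
    if (length(tokens) < nc) stop("NTSYS column label line missing")
    tokens <- tokens[-seq_len(nc)]
  }
  n_expected <- nr * nc + if (row_labels) nr else 0L
  if (length(tokens) != n_expected)
    stop("NTSYS body has ", length(tokens), " fields; header declares ",
         n_expected, " (", nr, "x", nc, if (row_labels) " + row labels", ")")

  if (row_labels) {
    per_row <- nc + 1L
    mat_tok <- matrix(tokens, nrow = nr, ncol = per_row, byrow = TRUE)
    labels <- mat_tok[, 1L]
    tokens <- as.vector(t(mat_tok[, -1L, drop = FALSE]))
  }
  vals <- suppressWarnings(as.numeric(tokens))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop("non-numeric NTSYS cell '", tokens[bad], "' at row ",
         (bad - 1L) %/% nc + 1L, ", column ", (bad - 1L) %% nc + 1L)
  }
  mat <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)

  if (is.null(specimen_id)) specimen_id <- basename(path)
  if (nc == 3L) {                        # long: one landmark per row
    coords <- mat
    lab <- if (!is.null(labels)) labels else paste0("L", seq_len(nr))
  } else {
    if (nc %% 3L != 0L)
      stop("NTSYS column count ", nc, " is not divisible by 3")
    if (nr != 1L)
      stop("wide NTSYS file declares ", nr,
           " specimen rows; read_ntsys handles exactly one")
    coords <- matrix(mat[1L, ], ncol = 3L, byrow = TRUE)
    lab <- paste0("L", seq_len(nrow(coords)))
    if (!is.null(labels) && nzchar(labels[1])) specimen_id <- labels[1]
  }
  landmark_set(coords, labels = lab, primary = TRUE, units = "unscaled",
               specimen_id = specimen_id)
}

#' Write landmarks to an NTSYS-pc matrix file
#'
#' @param set a [landmark_set()].
#' @param path output path.
#' @param layout `"long"` (one labelled row per landmark, 3 columns; the
#'   default, label-preserving) or `"wide"` (one specimen row, 3k columns).
#' @param digits significant digits written; the read/write round trip is
#'   exact at this precision.
#' @return the path, invisibly.
#' @export
write_ntsys <- function(set, path, layout = c("long", "wide"), digits = 15) {
  stopifnot(inherits(set, "landmark_set"))
  layout <- match.arg(layout)
  n <- n_landmarks(set)
  if (n < 1L) stop("refusing to write an empty landmark set")
  fmt <- function(v) format(v, digits = digits, scientific = FALSE, trim = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  if (layout == "long") {
    writeLines(sprintf("1 %dL 3 0", n), con)
    writeLines(paste(set$labels, fmt(set$coords[, 1]), fmt(set$coords[, 2]),
                     fmt(set$coords[, 3])), con)
  } else {
    writeLines(sprintf("1 1 %d 0", 3L * n), con)
    writeLines(paste(fmt(as.vector(t(set$coords))), collapse = " "), con)
  }
  invisible(path)
}

#' Read landmarks from a point-list file
#'
#' The canonical exchange format of this package: one landmark per line,
#' `label x y z`, whitespace- or comma-delimited; lines beginning with `#`
#' are comments. This is the format into which photogrammetric RAW exports
#' are converted. File order is preserved and meaningful.
#'
#' @param path path to the file.
#' @param specimen_id specimen identifier; defaults to the file name.
#' @return a [landmark_set()] with all landmarks primary.
#' @export
read_pointlist <- function(path, specimen_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no landmarks in file: ", path)
  parts <- strsplit(trimws(gsub(",", " ", lines)), "[[:space:]]+")
  nf <- lengths(parts)
  if (any(nf != 4L)) {
    bad <- which(nf != 4L)[1]
    stop("line ", lineno[bad], " has ", nf[bad],
         " fields; expected 'label x y z'")
  }
  m <- do.call(rbind, parts)
  labels <- m[, 1]
  if (anyDuplicated(labels))
    stop("duplicate landmark label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  coords <- suppressWarnings(matrix(as.numeric(m[, 2:4]), ncol = 3L))
  if (anyNA(coords)) {
    bad <- which(is.na(coords), arr.ind = TRUE)[1, ]
    stop("non-numeric coordinate at line ", lineno[bad[1]],
         ", field ", bad[2] + 1L)
  }
  if (is.null(specimen_id)) specimen_id <- basename(path)
  landmark_set(coords, labels = labels, primary = TRUE,
               units = "unscaled", specimen_id = specimen_id)
}

#' Write landmarks to a point-list file
#'
#' @inheritParams write_ntsys
#' @return the path, invisibly.
#' @export
write_pointlist <- function(set, path, digits = 15) {
  stopifnot(inherits(set, "landmark_set"))
  if (n_landmarks(set) < 1L) stop("refusing to write an empty landmark set")
  fmt <- function(v) format(v, digits = digits, scientific = FALSE, trim = TRUE)
  writeLines(c("# label x y z",
               paste(set$labels, fmt(set$coords[, 1]), fmt(set$coords[, 2]),
                     fmt(set$coords[, 3]))), path)
  invisible(path)
}
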