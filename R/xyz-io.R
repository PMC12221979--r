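#' Construct a point cloud
#'
#' A point cloud is the raw representation of a particle surface: an N x 3
#' matrix of Cartesian coordinates plus a source identifier.
#'
#' @param points numeric N x 3 matrix of coordinates.
#' @param source_id character tag recording where the cloud came from.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, source_id = "<memory>") {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("point cloud must have 3 columns")
  if (!all(is.finite(points))) stop("point cloud contains non-finite coordinates")
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  structure(list(points = points, source_id = as.character(source_id)),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points from %s\n", nrow(x$points), x$source_id))
  invisible(x)
}

as_point_matrix <- function(pc) {
  if (inherits(pc, "point_cloud")) pc$points else point_cloud(pc)$points
}

#' Read an XYZ point-cloud file
#'
#' Parses plain-text XYZ files with one `x y z` triple per line.  Two
#' dialects are supported: `"bare"` (triples only) and `"header"` (first
#' non-comment line is the point count, as written by some simulation
#' tools).  Lines starting with `#` are skipped in either dialect.
#'
#' @param path file path.
#' @param dialect `"bare"` or `"header"`.
#' @return A [point_cloud()].
#' @export
read_xyz <- function(path, dialect = c("bare", "header")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (dialect == "header") {
    if (length(lines) == 0L) stop("empty file: ", path)
    cnt <- suppressWarnings(as.integer(trimws(lines[1L])))
    if (is.na(cnt)) stop("XYZ parse error at line ", lineno[1L],
                         ": expected integer point count")
    lines <- lines[-1L]
    lineno <- lineno[-1L]
    if (length(lines) != cnt)
      stop("XYZ header declares ", cnt, " points but file has ", length(lines))
  }
  if (length(lines) == 0L) stop("no coordinate rows in ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(toks, length, 1L) != 3L)
  if (length(bad))
    stop("XYZ parse error at line ", lineno[bad[1L]],
         ": expected 3 columns, found ", length(toks[[bad[1L]]]))
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals)) {
    row <- ceiling(which(is.na(vals))[1L] / 3)
    stop("XYZ parse error at line ", lineno[row], ": non-numeric token")
  }
  point_cloud(matrix(vals, ncol = 3L, byrow = TRUE), source_id = path)
}

#' Write a point cloud to an XYZ file
#'
#' @param pc a [point_cloud()] or N x 3 matrix.
#' @param path output path.
#' @param dialect `"bare"` writes triples only; `"header"` prepends the
#'   point count on the first line.
#' @param digits decimal places (fixed notation), default 6.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(pc, path, dialect = c("bare", "header"), digits = 6L) {
  dialect <- match.arg(dialect)
  pts <- as_point_matrix(pc)
  fmt <- paste0("%.", digits, "f")
  rows <- sprintf(paste(fmt, fmt, fmt), pts[, 1L], pts[, 2L], pts[, 3L])
  if (dialect == "header") rows <- c(as.character(nrow(pts)), rows)
  writeLines(rows, path)
  invisible(path)
}
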