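#' Convex hull of a 3-D point set
#'
#' Incremental hull with outward-oriented triangular facets. Returns the
#' facet triangulation, per-facet unit normals and plane offsets
#' (`n . x = offset`), total surface area, enclosed volume and the volume
#' (solid) centroid.
#'
#' @param pc a [point_cloud()] or N x 3 matrix (N >= 4, not coplanar).
#' @return An object of class `hull3d` with elements `points`, `faces`
#'   (M x 3 vertex indices), `normals`, `offsets`, `area`, `volume`,
#'   `centroid`, `vertex_indices`.
#' @export
convex_hull <- function(pc) {
  pts <- as_point_matrix(pc)
  if (nrow(pts) < 4L) stop("hull error: need at least 4 points")
  h <- .hull3d_cpp(pts)
  h$points <- pts
  class(h) <- "hull3d"
  h
}

#' @export
print.hull3d <- function(x, ...) {
  cat(sprintf("<hull3d> %d vertices, %d facets, area %.4g, volume %.4g\n",
              length(x$vertex_indices), nrow(x$faces), x$area, x$volume))
  invisible(x)
}

# TRUE for points inside or on the hull (within tol).
hull_contains <- function(hull, pts, tol = 1e-9) {
  pts <- as_point_matrix(pts)
  s <- pts %*% t(hull$normals)
  scale <- max(abs(hull$offsets), 1)
  apply(s <= rep(hull$offsets + tol * scale, each = nrow(pts)), 1L, all)
}

# Per-facet triangle areas (for area-weighted sampling).
hull_face_areas <- function(hull) {
  a <- hull$points[hull$faces[, 1L], , drop = FALSE]
  b <- hull$points[hull$faces[, 2L], , drop = FALSE]
  c3 <- hull$points[hull$faces[, 3L], , drop = FALSE]
  u <- b - a
  v <- c3 - a
  cr <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
              u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
              u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  0.5 * sqrt(rowSums(cr^2))
}

# Exact second moment (about the solid centroid) of the uniform density over
# a convex hull, via signed tetrahedra against the origin:
# for tet (0, a, b, c), integral of x x^T equals
# (detV/120) * (M + S S^T) with M = sum v_i v_i^T over the 3 vertices and
# S = a + b + c.  Eigenvalue square roots give exact RMS solid extents.
hull_solid_covariance <- function(hull) {
  V <- 0
  m1 <- c(0, 0, 0)
  m2 <- matrix(0, 3, 3)
  for (r in seq_len(nrow(hull$faces))) {
    a <- hull$points[hull$faces[r, 1L], ]
    b <- hull$points[hull$faces[r, 2L], ]
    c3 <- hull$points[hull$faces[r, 3L], ]
    d6 <- det(rbind(a, b, c3))           # 6 * signed volume
    V <- V + d6 / 6
    s <- a + b + c3
    m1 <- m1 + d6 / 6 * s / 4
    M <- tcrossprod(a) + tcrossprod(b) + tcrossprod(c3)
    m2 <- m2 + d6 / 120 * (M + tcrossprod(s))
  }
  if (abs(V) < 1e-300) stop("degenerate hull: zero volume")
  mu <- m1 / V
  m2 / V - tcrossprod(mu)
}

# Exact RMS half-extents (sorted ascending) of the uniform solid.
hull_solid_extents <- function(hull) {
  ev <- eigen(hull_solid_covariance(hull), symmetric = TRUE)$values
  sqrt(pmax(sort(ev), 0))
}
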