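# Independent brute-force oracles used to validate the package's geometry,
# statistics and pooling code. These deliberately share no code with the
# implementation: hulls by supporting-plane enumeration, halfspace vertices
# by triple enumeration, Pearson by an explicit two-pass formula, pooling by
# triple loops.

# Fixture clouds -------------------------------------------------------------

cube_corners <- function(half = 1) {
  as.matrix(expand.grid(x = c(-half, half), y = c(-half, half),
                        z = c(-half, half)))
}

# regular tetrahedron with edge length `a`
tetrahedron_points <- function(a = 1) {
  a * rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
            c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
}

# dense regular grid filling an axis-aligned box with half-extents h
box_grid_cloud <- function(h, n_per_axis = 25) {
  as.matrix(expand.grid(
    x = seq(-h[1], h[1], length.out = n_per_axis),
    y = seq(-h[2], h[2], length.out = n_per_axis),
    z = seq(-h[3], h[3], length.out = n_per_axis)))
}

unit_sphere_cloud <- function(n = 2000, seed = 1) {
  set.seed(seed)
  p <- matrix(rnorm(3 * n), ncol = 3)
  p / sqrt(rowSums(p^2))
}

# Oracles --------------------------------------------------------------------

# Convex-hull volume and area by supporting-plane triple enumeration
# (points must be in convex position, e.g. on a sphere): a triple forms a
# facet iff all other points lie on one side of its plane.
oracle_hull_metrics <- function(pts) {
  n <- nrow(pts)
  ctr <- colMeans(pts)
  vol <- 0
  area <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; c3 <- pts[k, ]
    nrm <- c((b - a)[2] * (c3 - a)[3] - (b - a)[3] * (c3 - a)[2],
             (b - a)[3] * (c3 - a)[1] - (b - a)[1] * (c3 - a)[3],
             (b - a)[1] * (c3 - a)[2] - (b - a)[2] * (c3 - a)[1])
    nl <- sqrt(sum(nrm^2))
    if (nl < 1e-12) next
    nrm <- nrm / nl
    s <- drop((pts - rep(a, each = n)) %*% nrm)
    if (all(s <= 1e-9)) {
      # outward facet
    } else if (all(s >= -1e-9)) {
      nrm <- -nrm
    } else next
    area <- area + nl / 2
    vol <- vol + abs(det(rbind(a - ctr, b - ctr, c3 - ctr))) / 6
  }
  list(area = area, volume = vol)
}

# Halfspace-intersection vertices by enumeration of all normal triples.
oracle_halfspace_vertices <- function(normals, distances, tol = 1e-8) {
  f <- nrow(normals)
  verts <- NULL
  for (i in 1:(f - 2)) for (j in (i + 1):(f - 1)) for (k in (j + 1):f) {
    A <- normals[c(i, j, k), ]
    if (abs(det(A)) < 1e-10) next
    v <- solve(A, distances[c(i, j, k)])
    if (all(normals %*% v <= distances + tol)) verts <- rbind(verts, v)
  }
  if (is.null(verts)) return(matrix(0, 0, 3))
  scale <- max(abs(verts), 1)
  verts[!duplicated(round(verts / scale, 7)), , drop = FALSE]
}

# Two-pass Pearson correlation.
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Block-max pooling by explicit triple loop.
oracle_block_max <- function(arr, f) {
  d <- dim(arr)[1] / f
  out <- array(NA_real_, rep(d, 3))
  for (i in 1:d) for (j in 1:d) for (k in 1:d)
    out[i, j, k] <- max(arr[((i - 1) * f + 1):(i * f),
                            ((j - 1) * f + 1):(j * f),
                            ((k - 1) * f + 1):(k * f)])
  out
}

# Aspect ratios of a uniform dense solid sample (Zingg oracle route).
oracle_solid_ratios <- function(pts) {
  cc <- sweep(pts, 2, colMeans(pts))
  ev <- sort(eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$values)
  s <- sqrt(pmax(ev, 0))
  c(s_m = s[1] / s[2], m_l = s[2] / s[3])
}

# Small helper: classify a cloud end to end.
measure_class <- function(pc, threshold = 0.66) {
  ax <- pca_axes(pc)
  zingg_classify(ax$s_m, ax$m_l, threshold = threshold)
}
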