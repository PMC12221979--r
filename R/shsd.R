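#' Spherical quadrature grid
#'
#' Product rule: Gauss–Legendre nodes in cos(theta) crossed with a uniform
#' grid in phi. Exact for spherical polynomials of degree
#' `2 * n_theta - 1` in cos(theta) and azimuthal orders below `n_phi`, so
#' `n_theta >= lmax + 1` and `n_phi >= 2 * lmax + 1` integrate products of
#' two degree-`lmax` harmonics exactly. Weights sum to 4 pi.
#'
#' @param n_theta polar Gauss–Legendre order (default 32).
#' @param n_phi azimuthal point count (default 64).
#' @return List with `directions` (K x 3 unit vectors), `weights`,
#'   `theta`, `phi`, `n_theta`, `n_phi`.
#' @export
sphere_quadrature <- function(n_theta = 32L, n_phi = 64L) {
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  ct <- gl$x
  st <- sqrt(pmax(1 - ct^2, 0))
  phi <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi
  theta_g <- rep(acos(ct), times = n_phi)
  phi_g <- rep(phi, each = n_theta)
  st_g <- rep(st, times = n_phi)
  ct_g <- rep(ct, times = n_phi)
  dirs <- cbind(st_g * cos(phi_g), st_g * sin(phi_g), ct_g)
  w <- rep(gl$w, times = n_phi) * (2 * pi / n_phi)
  list(directions = dirs, weights = w, theta = theta_g, phi = phi_g,
       n_theta = n_theta, n_phi = n_phi)
}

# Orthonormal complex spherical harmonics Y_l^m (physics convention,
# Condon–Shortley phase via pracma::legendre) evaluated for all
# 0 <= m <= l <= lmax at the given angles.  Returns a K x ((lmax+1)(lmax+2)/2)
# complex matrix, columns in (l, m) lexicographic order.
sph_harm_matrix <- function(lmax, theta, phi) {
  K <- length(theta)
  ncoef <- (lmax + 1L) * (lmax + 2L) / 2L
  Y <- matrix(0 + 0i, K, ncoef)
  ct <- cos(theta)
  for (l in 0:lmax) {
    P <- pracma::legendre(l, ct)           # (l+1) x K, rows m = 0..l
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1L)
    for (m in 0:l) {
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      Y[, coefficient_index(l, m) + 1L] <-
        nrm * P[m + 1L, ] * exp(1i * m * phi)
    }
  }
  Y
}

#' Descriptor index of a spherical-harmonic coefficient
#'
#' Coefficients with `0 <= m <= l` are stored in (l, m) lexicographic order,
#' so `Mag_0 .. Mag_5` are Y00, Y10, Y11, Y20, Y21, Y22. The index is
#' 0-based: `coefficient_index(0, 0) = 0`, `coefficient_index(10, 10) = 65`.
#'
#' @param l degree, `0 <= l`.
#' @param m order, `0 <= m <= l`.
#' @return Integer index `l (l + 1) / 2 + m`.
#' @export
coefficient_index <- function(l, m) {
  if (any(m < 0) || any(m > l) || any(l < 0))
    stop("coefficient_index: require 0 <= m <= l")
  as.integer(l * (l + 1) / 2 + m)
}

#' Radial support map of a convex hull
#'
#' Distance from the hull's volume centroid to the hull boundary along each
#' direction: the minimum over facets of `offset_f / (n_f . u)` restricted
#' to positive denominators (star-domain radial function; always
#' single-valued for a convex body viewed from an interior point).
#'
#' @param hull a `hull3d` from [convex_hull()].
#' @param quadrature a [sphere_quadrature()] grid (or any list with unit
#'   `directions`).
#' @return The quadrature list with a `radii` vector added (class
#'   `radial_map`).
#' @export
radial_function <- function(hull, quadrature = sphere_quadrature()) {
  ctr <- hull$centroid
  off <- hull$offsets - drop(hull$normals %*% ctr)
  if (any(off <= 0)) stop("internal error: centroid outside hull")
  den <- quadrature$directions %*% t(hull$normals)
  den[den < 1e-12] <- NA_real_                 # ray parallel or away
  radii <- apply(sweep(1 / den, 2L, off, `*`), 1L, min, na.rm = TRUE)
  if (any(!is.finite(radii) | radii <= 0))
    stop("radial_function: unbounded ray (open hull?)")
  out <- quadrature
  out$radii <- radii
  class(out) <- "radial_map"
  out
}

#' Expand a radial map in spherical harmonics
#'
#' Quadrature projection `c_lm = sum_k w_k r_k conj(Y_l^m)` onto the
#' orthonormal complex harmonics with `0 <= m <= l <= lmax`; for a real
#' radial function the `m < 0` coefficients are conjugates and carry no
#' extra information. The descriptor is the vector of coefficient
#' magnitudes `Mag_i = |c_lm|`, 66 values at the default `lmax = 10`.
#'
#' Refuses quadratures too coarse for exact degree-`2 lmax` integration
#' (`n_theta >= lmax + 1`, `n_phi >= 2 lmax + 1`).
#'
#' @param rmap a `radial_map` from [radial_function()] (or a quadrature
#'   list with a `radii` element).
#' @param lmax truncation degree, default 10.
#' @return An object of class `sh_descriptor`: `lmax`, `coefficients`
#'   (complex, named `c_l_m`), `magnitudes` (named `Mag_0`...).
#' @export
sh_expand <- function(rmap, lmax = 10L) {
  if (is.null(rmap$radii)) stop("sh_expand: radial map has no radii")
  if (rmap$n_theta < lmax + 1L || rmap$n_phi < 2L * lmax + 1L)
    stop("insufficient quadrature order for lmax = ", lmax,
         ": need n_theta >= ", lmax + 1L, " and n_phi >= ", 2L * lmax + 1L)
  Y <- sph_harm_matrix(lmax, rmap$theta, rmap$phi)
  coef <- drop(crossprod(Conj(Y), rmap$weights * rmap$radii))
  lm <- do.call(rbind, lapply(0:lmax, function(l) cbind(l, 0:l)))
  names(coef) <- sprintf("c_%d_%d", lm[, 1L], lm[, 2L])
  mags <- Mod(coef)
  names(mags) <- sprintf("Mag_%d", seq_along(mags) - 1L)
  structure(list(lmax = as.integer(lmax), coefficients = coef,
                 magnitudes = mags, lm = lm), class = "sh_descriptor")
}

#' @export
print.sh_descriptor <- function(x, ...) {
  cat(sprintf("<sh_descriptor> lmax = %d (%d magnitudes); Mag_0 = %.4f\n",
              x$lmax, length(x$magnitudes), x$magnitudes[1L]))
  invisible(x)
}

#' Spherical-harmonic shape descriptor of a point cloud
#'
#' Convex hull, radial support map from the volume centroid, then
#' [sh_expand()]. Descriptors are computed in the fixed Cartesian frame of
#' the input (no rotation alignment), so coefficient-by-coefficient
#' comparisons between shapes are direct and not rotation invariant.
#'
#' @param pc a [point_cloud()] or matrix (N >= 4, non-coplanar).
#' @param lmax truncation degree, default 10 (66 magnitudes).
#' @param quadrature quadrature grid, default [sphere_quadrature()].
#' @return An `sh_descriptor`.
#' @export
describe_cloud <- function(pc, lmax = 10L, quadrature = sphere_quadrature()) {
  hull <- convex_hull(pc)
  sh_expand(radial_function(hull, quadrature), lmax = lmax)
}

#' Synthesize a radial map from a descriptor
#'
#' Truncated inverse transform (real part of the full +/- m synthesis)
#' evaluated at arbitrary angles; used for reconstruction-error checks.
#'
#' @param desc an `sh_descriptor`.
#' @param theta,phi angles at which to evaluate.
#' @return Numeric vector of synthesized radii.
#' @export
sh_synthesize <- function(desc, theta, phi) {
  Y <- sph_harm_matrix(desc$lmax, theta, phi)
  mult <- ifelse(desc$lm[, 2L] == 0L, 1, 2)   # m<0 terms via conjugation
  drop(Re(Y %*% (mult * desc$coefficients)))
}

#' Descriptor table for a list of clouds
#'
#' @param clouds list of point clouds.
#' @param ids optional ids.
#' @param lmax truncation degree.
#' @param quadrature shared quadrature grid.
#' @return `data.frame` with `id` and `Mag_0 .. Mag_k` columns.
#' @export
describe_clouds <- function(clouds, ids = NULL, lmax = 10L,
                            quadrature = sphere_quadrature()) {
  mags <- t(vapply(clouds, function(p)
    describe_cloud(p, lmax = lmax, quadrature = quadrature)$magnitudes,
    numeric((lmax + 1) * (lmax + 2) / 2)))
  out <- as.data.frame(mags)
  out$id <- ids %||% as.character(seq_along(clouds))
  out[, c("id", setdiff(names(out), "id"))]
}
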