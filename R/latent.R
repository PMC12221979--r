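latent_matrix <- function(latents) {
  z <- as.matrix(latents)
  if (is.null(colnames(z))) colnames(z) <- paste0("Dim_", seq_len(ncol(z)) - 1L)
  z
}

# Pearson correlation matrix with NA flagging for zero-variance columns.
pearson_matrix <- function(z, f) {
  out <- matrix(NA_real_, ncol(z), ncol(f),
                dimnames = list(colnames(z), colnames(f)))
  const_f <- apply(f, 2L, sd) == 0
  const_z <- apply(z, 2L, sd) == 0
  ok_f <- which(!const_f)
  ok_z <- which(!const_z)
  if (length(ok_f) && length(ok_z))
    out[ok_z, ok_f] <- cor(z[, ok_z, drop = FALSE], f[, ok_f, drop = FALSE])
  if (any(const_f) || any(const_z))
    warning("undefined correlations flagged NA (constant column: ",
            paste(c(colnames(f)[const_f], colnames(z)[const_z]),
                  collapse = ", "), ")", call. = FALSE)
  out
}

#' Correlations between latent dimensions and shape features
#'
#' Pearson correlation of each latent dimension (`Dim_0 ..`) with the five
#' quantitative shape descriptors: S:M aspect ratio, M:L aspect ratio,
#' hull surface area, hull volume, and surface-area-to-volume ratio.
#' Entries are in \[-1, 1\] and invariant to affine rescaling of any
#' feature; a constant feature column yields a flagged `NA`.
#'
#' @param latents n x d latent matrix (see [encode()]).
#' @param records shape-record `data.frame` with columns `s_m`, `m_l`,
#'   `surface_area`, `volume`, `sa_vol` (see [shape_record_table()]).
#' @return A d x 5 correlation matrix.
#' @export
feature_correlations <- function(latents, records) {
  z <- latent_matrix(latents)
  if (nrow(z) < 3L) stop("feature_correlations: need at least 3 samples")
  feats <- c("s_m", "m_l", "surface_area", "volume", "sa_vol")
  stopifnot(all(feats %in% names(records)))
  f <- as.matrix(records[, feats])
  if (nrow(f) != nrow(z)) stop("latents and records disagree in length")
  if (!all(is.finite(f))) stop("non-finite feature values")
  pearson_matrix(z, f)
}

#' Correlations between latent dimensions and harmonic magnitudes
#'
#' Pearson correlation of each latent dimension with the first
#' spherical-harmonic coefficient magnitudes `Mag_0 .. Mag_5` (Y00, Y10,
#' Y11, Y20, Y21, Y22) by default.
#'
#' @param latents n x d latent matrix.
#' @param descriptors `data.frame` or matrix with `Mag_*` columns (see
#'   [describe_clouds()]).
#' @param n_mags number of leading magnitudes, default 6.
#' @return A d x `n_mags` correlation matrix.
#' @export
harmonic_correlations <- function(latents, descriptors, n_mags = 6L) {
  z <- latent_matrix(latents)
  cols <- paste0("Mag_", seq_len(n_mags) - 1L)
  d <- as.data.frame(descriptors)
  stopifnot(all(cols %in% names(d)))
  f <- as.matrix(d[, cols])
  if (nrow(f) != nrow(z)) stop("latents and descriptors disagree in length")
  pearson_matrix(z, f)
}

#' Project latent vectors to 2-D
#'
#' Two methods. `"first_two_dims"` selects (no fitting) the latent
#' dimension most correlated in absolute value with the S:M ratio and,
#' among the remaining dimensions, the one most correlated with M:L —
#' the axes used to map the latent space by shape class. `"nmds"` is a
#' nonlinear 2-D embedding of the full latent space by Kruskal
#' non-metric multidimensional scaling on Euclidean latent distances
#' (deterministic for a fixed seed).
#'
#' @param latents n x d latent matrix.
#' @param method `"first_two_dims"` or `"nmds"`.
#' @param records shape records (required for `"first_two_dims"`).
#' @param seed seed for the embedding.
#' @return n x 2 coordinate matrix; for `"first_two_dims"` the selected
#'   dimensions are reported in `attr(, "dims")`.
#' @export
project_2d <- function(latents, method = c("first_two_dims", "nmds"),
                       records = NULL, seed = 1L) {
  method <- match.arg(method)
  z <- latent_matrix(latents)
  if (!all(is.finite(z))) stop("project_2d: non-finite latent values")
  if (method == "first_two_dims") {
    if (is.null(records)) stop("first_two_dims needs shape records")
    r1 <- abs(cor(z, records$s_m))
    d1 <- which.max(r1)
    r2 <- abs(cor(z, records$m_l))
    r2[d1] <- -Inf
    d2 <- which.max(r2)
    out <- z[, c(d1, d2), drop = FALSE]
    attr(out, "dims") <- c(colnames(z)[d1], colnames(z)[d2])
    return(out)
  }
  if (nrow(z) < 4L) stop("nmds needs at least 4 samples")
  with_local_seed(seed, {
    zz <- z + matrix(rnorm(length(z), sd = 1e-9 * max(1, sd(z))), nrow(z))
    dd <- dist(zz)
    fit <- MASS::isoMDS(dd, y = cmdscale(dd, k = 2L), k = 2L, trace = FALSE)
    out <- fit$points
    colnames(out) <- c("V1", "V2")
    out
  })
}

#' Latent-space centroid of each Zingg class
#'
#' @param latents n x d latent matrix.
#' @param labels character vector of Zingg classes, one per row.
#' @return A 4 x d matrix, rows `block`, `needle`, `lath`, `plate`
#'   (arithmetic means). Errors, listing the absent classes, if any class
#'   has no member.
#' @export
class_centroids <- function(latents, labels) {
  z <- latent_matrix(latents)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(z))
  missing <- setdiff(zingg_levels(), unique(labels))
  if (length(missing))
    stop("class_centroids: no members for class(es): ",
         paste(missing, collapse = ", "))
  out <- t(vapply(zingg_levels(), function(cl)
    colMeans(z[labels == cl, , drop = FALSE]), numeric(ncol(z))))
  colnames(out) <- colnames(z)
  out
}

#' Decoded shape-morphing trajectory between two latent points
#'
#' Linear interpolation `z_t = (1 - t) z_a + t z_b` at `n_steps` evenly
#' spaced `t` in \[0, 1\], decoded to voxel volumes; aspect ratios of each
#' decoded step are measured on the binarized volume (voxel centres at or
#' above `threshold` -> PCA axis ratios -> Zingg class). A step whose
#' decode is empty at the threshold is flagged, not an error.
#'
#' @param model a trained `dae_model`.
#' @param z_a,z_b latent endpoint vectors (e.g. class centroids).
#' @param n_steps number of steps (>= 2), default 8.
#' @param threshold binarization threshold for aspect measurement.
#' @param endpoints optional pair of class labels for bookkeeping.
#' @return An object of class `trajectory`: `steps` (n_steps x d latent
#'   matrix), `decoded` (list of [voxel_grid()]), `aspect_series`
#'   (`data.frame` with `step`, `t`, `s_m`, `m_l`, `zingg_class`, `empty`),
#'   `endpoints`.
#' @export
interpolate_trajectory <- function(model, z_a, z_b, n_steps = 8L,
                                   threshold = 0.5, endpoints = NULL) {
  if (n_steps < 2L) stop("interpolate_trajectory: n_steps must be >= 2")
  z_a <- as.numeric(z_a); z_b <- as.numeric(z_b)
  tt <- seq(0, 1, length.out = n_steps)
  steps <- outer(1 - tt, z_a) + outer(tt, z_b)
  colnames(steps) <- paste0("Dim_", seq_along(z_a) - 1L)
  decoded <- decode(model, steps)
  rows <- lapply(seq_len(n_steps), function(i) {
    pc <- tryCatch(voxels_to_points(decoded[[i]], threshold = threshold),
                   error = function(e) NULL)
    if (is.null(pc) || nrow(pc$points) < 4L)
      return(data.frame(step = i, t = tt[i], s_m = NA_real_, m_l = NA_real_,
                        zingg_class = NA_character_, empty = TRUE))
    ax <- suppressWarnings(pca_axes(pc))
    data.frame(step = i, t = tt[i], s_m = ax$s_m, m_l = ax$m_l,
               zingg_class = zingg_classify(ax$s_m, ax$m_l), empty = FALSE)
  })
  structure(list(steps = steps, decoded = decoded,
                 aspect_series = do.call(rbind, rows),
                 endpoints = endpoints), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  ep <- if (is.null(x$endpoints)) "" else
    paste0(" ", x$endpoints[1L], " -> ", x$endpoints[2L])
  cat(sprintf("<trajectory>%s %d steps\n", ep, nrow(x$steps)))
  print(x$aspect_series[, c("t", "s_m", "m_l", "zingg_class")], digits = 3)
  invisible(x)
}
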