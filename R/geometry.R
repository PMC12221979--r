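#' Center a point cloud and scale to unit maximum norm
#'
#' Moves the cloud centroid to the origin and divides every coordinate by
#' the maximum Euclidean norm of the centred points, so the cloud fits in
#' the closed unit ball with at least one point on its boundary. The
#' operation is idempotent and preserves aspect ratios and Zingg class.
#'
#' @param pc a [point_cloud()] or N x 3 matrix.
#' @return A normalized [point_cloud()].
#' @export
center_and_normalize <- function(pc) {
  pts <- as_point_matrix(pc)
  ctr <- colMeans(pts)
  pts <- sweep(pts, 2L, ctr)
  r <- sqrt(max(rowSums(pts^2)))
  if (r < 1e-300) stop("degenerate cloud: all points identical")
  src <- if (inherits(pc, "point_cloud")) pc$source_id else "<memory>"
  point_cloud(pts / r, source_id = src)
}

#' Principal axis lengths (S, M, L) of a point cloud
#'
#' Singular values of the centred coordinate matrix divided by sqrt(N)
#' (i.e. RMS extents along the principal axes), sorted ascending into
#' S <= M <= L. Ratios S/M and M/L are the Zingg aspect ratios.  Values are
#' sample-size independent; ratios are invariant to rotation, translation
#' and uniform scaling.
#'
#' @param pc a [point_cloud()] or N x 3 matrix with at least 4 points.
#' @return A list with `S`, `M`, `L`, `s_m`, `m_l`, and `degenerate`
#'   (TRUE when the cloud has rank < 3, in which case S = 0 and s_m = 0).
#' @export
pca_axes <- function(pc) {
  pts <- as_point_matrix(pc)
  if (nrow(pts) < 4L) stop("pca_axes: need at least 4 points")
  pts <- sweep(pts, 2L, colMeans(pts))
  sv <- svd(pts, nu = 0L, nv = 0L)$d / sqrt(nrow(pts))
  sv <- sort(sv)                       # ascending: S, M, L
  scale <- max(sv[3L], 1e-300)
  degenerate <- sv[1L] / scale < 1e-9
  if (degenerate) {
    sv[1L] <- 0
    warning("rank-deficient cloud: S axis is zero", call. = FALSE)
  }
  s_m <- if (sv[2L] > 0) sv[1L] / sv[2L] else 0
  m_l <- if (sv[3L] > 0) sv[2L] / sv[3L] else 0
  list(S = sv[1L], M = sv[2L], L = sv[3L], s_m = s_m, m_l = m_l,
       degenerate = degenerate)
}

#' Convex-hull surface area and volume
#'
#' @param pc a [point_cloud()] or N x 3 matrix (non-coplanar, N >= 4).
#' @return A list with `surface_area` and `volume` (both > 0).
#' @export
hull_metrics <- function(pc) {
  h <- convex_hull(pc)
  list(surface_area = h$area, volume = h$volume)
}

#' Full shape record for one particle
#'
#' Combines the PCA aspect ratios, the Zingg class, and the convex-hull
#' surface area, volume and surface-area-to-volume ratio into the one-row
#' summary used throughout the latent analysis.
#'
#' @param pc a [point_cloud()] or N x 3 matrix.
#' @param threshold Zingg threshold passed to [zingg_classify()].
#' @return A one-row `data.frame` with columns `s_m`, `m_l`, `zingg_class`,
#'   `surface_area`, `volume`, `sa_vol`.
#' @export
shape_record <- function(pc, threshold = 0.66) {
  ax <- pca_axes(pc)
  hm <- hull_metrics(pc)
  data.frame(
    s_m = ax$s_m, m_l = ax$m_l,
    zingg_class = zingg_classify(ax$s_m, ax$m_l, threshold = threshold),
    surface_area = hm$surface_area, volume = hm$volume,
    sa_vol = hm$surface_area / hm$volume,
    stringsAsFactors = FALSE)
}

#' Shape records for a list of clouds
#'
#' @param clouds list of point clouds.
#' @param ids optional character ids (defaults to cloud source ids).
#' @param threshold Zingg threshold.
#' @return A `data.frame`, one row per cloud, with an `id` column.
#' @export
shape_record_table <- function(clouds, ids = NULL, threshold = 0.66) {
  recs <- lapply(clouds, shape_record, threshold = threshold)
  out <- do.call(rbind, recs)
  out$id <- ids %||% vapply(clouds, function(p)
    if (inherits(p, "point_cloud")) p$source_id else "<memory>", "")
  out[, c("id", setdiff(names(out), "id"))]
}

# Rotate a cloud so its principal axes coincide with the Cartesian axes
# (L -> z, M -> y, S -> x); signs fixed by making each axis's third moment
# non-negative.  Needed because the autoencoder's convolutions are not
# rotation-equivariant.
align_to_axes <- function(pc) {
  pts <- as_point_matrix(pc)
  ctr <- colMeans(pts)
  pts <- sweep(pts, 2L, ctr)
  sv <- svd(pts, nu = 0L)
  V <- sv$v[, order(sv$d, decreasing = TRUE), drop = FALSE]  # L, M, S cols
  rot <- V[, c(3L, 2L, 1L), drop = FALSE]                    # S->x, M->y, L->z
  if (det(rot) < 0) rot[, 1L] <- -rot[, 1L]
  al <- pts %*% rot
  m3 <- colSums(al^3)
  flip <- m3 < 0
  if (sum(flip) %% 2L == 1L) flip[which(flip)[1L]] <- FALSE  # keep det +1
  al[, flip] <- -al[, flip, drop = FALSE]
  src <- if (inherits(pc, "point_cloud")) pc$source_id else "<memory>"
  point_cloud(al, source_id = src)
}
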