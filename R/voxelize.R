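#' Construct a voxel grid
#'
#' A cubic occupancy grid with values in \[0, 1\]. The physical frame is set
#' by `origin` (low corner of the grid) and `spacing`; voxel `(i, j, k)`
#' (1-based) is centred at `origin + (c(i, j, k) - 0.5) * spacing`.
#'
#' @param values numeric D x D x D array with values in \[0, 1\].
#' @param origin length-3 low corner, default `c(-1, -1, -1)`.
#' @param spacing positive voxel edge length.
#' @param binary flag: TRUE when values are strictly 0/1 occupancy.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, origin = c(-1, -1, -1), spacing = NULL,
                       binary = TRUE) {
  d <- dim(values)
  if (length(d) != 3L || length(unique(d)) != 1L)
    stop("voxel grid must be a cubic 3-D array")
  if (min(values) < -1e-12 || max(values) > 1 + 1e-12)
    stop("voxel values must lie in [0, 1]")
  spacing <- spacing %||% (2 / d[1L])
  if (spacing <= 0) stop("spacing must be positive")
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing), binary = isTRUE(binary)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d^3, spacing %.4g, %.1f%% occupied\n",
              dim(x$values)[1L], x$spacing, 100 * mean(x$values > 0.5)))
  invisible(x)
}

grid_side <- function(grid) dim(grid$values)[1L]

#' Rasterize a normalized point cloud to an occupancy grid
#'
#' The grid spans \eqn{[-1, 1]^3}, so the cloud must be normalized (maximum
#' point norm 1, see [center_and_normalize()]). Two fill modes:
#' `"convex_solid"` (default) marks every voxel whose centre lies inside the
#' cloud's convex hull, plus the voxels containing the input points (so the
#' solid occupancy always contains the surface occupancy, including hull
#' boundary voxels whose centre falls just outside); `"surface"` marks
#' voxels containing at least one point. Occupancy is binary at the source
#' resolution: the continuum hull volume is approximated to within about
#' one voxel layer per face.
#'
#' @param pc a [point_cloud()] or matrix.
#' @param resolution grid side (even, >= 8), default 64.
#' @param fill `"convex_solid"` or `"surface"`.
#' @return A binary [voxel_grid()].
#' @export
rasterize <- function(pc, resolution = 64L,
                      fill = c("convex_solid", "surface")) {
  fill <- match.arg(fill)
  pts <- as_point_matrix(pc)
  if (nrow(pts) == 0L) stop("rasterize: empty cloud")
  if (resolution < 8L || resolution %% 2L != 0L)
    stop("rasterize: resolution must be even and >= 8")
  if (max(abs(pts)) > 1 + 1e-9)
    stop("rasterize: cloud must be normalized to the unit ball")
  spacing <- 2 / resolution
  vals <- array(0, dim = rep(resolution, 3L))
  if (fill == "surface") {
    ijk <- pmin(pmax(floor((pts + 1) / spacing) + 1L, 1L), resolution)
    vals[ijk] <- 1
  } else {
    hull <- convex_hull(pts)
    centers <- seq(-1 + spacing / 2, 1 - spacing / 2, by = spacing)
    # convexity: the occupied voxels of each (x, y) column form one
    # contiguous z-interval, so only interval bounds are computed per column
    xy <- as.matrix(expand.grid(x = centers, y = centers))
    S <- rep(hull$offsets + 1e-12, each = nrow(xy)) -
      xy %*% t(hull$normals[, 1:2, drop = FALSE])    # slack at z = 0
    nz <- hull$normals[, 3L]
    zhi <- rep(Inf, nrow(xy))
    zlo <- rep(-Inf, nrow(xy))
    for (f in seq_along(nz)) {
      if (nz[f] > 1e-12) zhi <- pmin(zhi, S[, f] / nz[f])
      else if (nz[f] < -1e-12) zlo <- pmax(zlo, S[, f] / nz[f])
      else zhi[S[, f] < 0] <- -Inf                   # column misses the hull
    }
    inside <- outer(centers, zlo, `>=`) & outer(centers, zhi, `<=`)
    vals[] <- as.numeric(t(inside))
    ijk <- pmin(pmax(floor((pts + 1) / spacing) + 1L, 1L), resolution)
    vals[ijk] <- 1
  }
  voxel_grid(vals, origin = c(-1, -1, -1), spacing = spacing, binary = TRUE)
}

#' Pad a voxel grid with zeros to a target cubic side
#'
#' The original values are centred; an odd margin puts the extra zero layer
#' on the high-index side. The value sum is conserved and the physical frame
#' is extended accordingly.
#'
#' @param grid a [voxel_grid()].
#' @param target target side, >= current side.
#' @return A padded [voxel_grid()].
#' @export
pad_to_cube <- function(grid, target) {
  side <- grid_side(grid)
  if (target < side) stop("pad_to_cube: target smaller than current side")
  if (target == side) return(grid)
  lo <- (target - side) %/% 2L
  vals <- array(0, dim = rep(target, 3L))
  idx <- seq_len(side) + lo
  vals[idx, idx, idx] <- grid$values
  voxel_grid(vals, origin = grid$origin - lo * grid$spacing,
             spacing = grid$spacing, binary = grid$binary)
}

#' Block-max downsampling of a voxel grid
#'
#' Reduces the side by `factor` by taking the maximum over non-overlapping
#' `factor^3` blocks, so occupancy is never created and single occupied
#' voxels survive.
#'
#' @param grid a [voxel_grid()] whose side is divisible by `factor`.
#' @param factor integer block edge, default 2.
#' @return A [voxel_grid()] with side `side / factor`.
#' @export
block_max_downsample <- function(grid, factor = 2L) {
  side <- grid_side(grid)
  if (side %% factor != 0L)
    stop("block_max_downsample: side ", side, " not divisible by ", factor)
  d_out <- side %/% factor
  out <- array(-Inf, dim = rep(d_out, 3L))
  for (dz in seq_len(factor)) for (dy in seq_len(factor))
    for (dx in seq_len(factor)) {
      out <- pmax(out, grid$values[seq(dx, side, by = factor),
                                   seq(dy, side, by = factor),
                                   seq(dz, side, by = factor)])
    }
  voxel_grid(out, origin = grid$origin, spacing = grid$spacing * factor,
             binary = grid$binary)
}

#' Convert a voxel grid back to a point cloud
#'
#' Returns the physical centres of all voxels with value at or above the
#' threshold; used to measure aspect ratios of decoded volumes.
#'
#' @param grid a [voxel_grid()].
#' @param threshold occupancy threshold, default 0.5.
#' @return A [point_cloud()] of voxel centres.
#' @export
voxels_to_points <- function(grid, threshold = 0.5) {
  side <- grid_side(grid)
  occ <- which(grid$values >= threshold, arr.ind = TRUE)
  if (nrow(occ) == 0L)
    stop("empty shape: no voxel at or above threshold ", threshold)
  pts <- sweep((occ - 0.5) * grid$spacing, 2L, -grid$origin)
  point_cloud(pts, source_id = "voxel-centers")
}

#' Voxelize a point cloud for model input
#'
#' The standard preprocessing chain: normalize, rasterize at the source
#' resolution (64 by default), pad to a block-divisible side and block-max
#' downsample to the model side (32 by default).
#'
#' @param pc a [point_cloud()] (any frame; normalized internally).
#' @param model_side final side (default 32).
#' @param source_resolution rasterization side (default `2 * model_side`).
#' @param fill see [rasterize()].
#' @param align rotate principal axes onto the Cartesian axes first
#'   (default TRUE; the autoencoder requires aligned inputs).
#' @return A [voxel_grid()] of side `model_side`.
#' @export
voxelize_cloud <- function(pc, model_side = 32L,
                           source_resolution = 2L * model_side,
                           fill = "convex_solid", align = TRUE) {
  if (align) pc <- align_to_axes(pc)
  pc <- center_and_normalize(pc)
  g <- rasterize(pc, resolution = source_resolution, fill = fill)
  factor <- source_resolution %/% model_side
  if (source_resolution %% model_side != 0L)
    stop("source_resolution must be a multiple of model_side")
  g <- pad_to_cube(g, target = model_side * factor)
  block_max_downsample(g, factor = factor)
}

#' Write voxel grids to a single-file container
#'
#' Stores one or more grids as raw little-endian float32 blocks after a
#' one-line JSON header carrying side, origin, spacing, binary flag and
#' sample ids.
#'
#' @param grids a [voxel_grid()] or named list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_voxels <- function(grids, path) {
  if (inherits(grids, "voxel_grid")) grids <- list(sample = grids)
  sides <- vapply(grids, grid_side, 1L)
  if (length(unique(sides)) != 1L) stop("all grids must share one side")
  g1 <- grids[[1L]]
  hdr <- jsonlite::toJSON(list(
    n = length(grids), side = sides[[1L]], origin = g1$origin,
    spacing = g1$spacing, binary = g1$binary,
    ids = names(grids) %||% as.character(seq_along(grids))),
    auto_unbox = TRUE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(as.character(hdr), "\n")), con)
  for (g in grids)
    writeBin(as.numeric(g$values), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read voxel grids written by [write_voxels()]
#'
#' @param path container path.
#' @return A named list of [voxel_grid()]s.
#' @export
read_voxels <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  nl <- which(raw == charToRaw("\n"))[1L]
  hdr <- jsonlite::fromJSON(rawToChar(raw[seq_len(nl - 1L)]))
  side <- hdr$side
  per <- side^3
  vals <- readBin(raw[-seq_len(nl)], "numeric", n = hdr$n * per, size = 4L,
                  endian = "little")
  out <- lapply(seq_len(hdr$n), function(i) {
    v <- array(vals[((i - 1L) * per + 1L):(i * per)], dim = rep(side, 3L))
    voxel_grid(pmin(pmax(v, 0), 1), origin = hdr$origin,
               spacing = hdr$spacing, binary = isTRUE(hdr$binary))
  })
  names(out) <- hdr$ids
  out
}
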