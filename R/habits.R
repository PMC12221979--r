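#' Specify a synthetic crystal habit
#'
#' A habit spec is a set of facet halfspaces `n_i . x <= d_i` (unit outward
#' normals, positive distances) tagged with a crystal system and its cell
#' angles. The bounded intersection of the halfspaces is a convex
#' polyhedron standing in for a grown crystal shape.
#'
#' Validation enforces: unit normals (1e-9), positive distances, a bounded
#' intersection containing the origin, and the crystal-system constraints
#' (tetragonal: gamma = 90 with the in-plane facet family sharing equal
#' symmetry-related distances; hexagonal: gamma = 120 with one shared
#' in-plane distance).
#'
#' @param crystal_system one of `"monoclinic"`, `"tetragonal"`, `"hexagonal"`.
#' @param cell_angles numeric length-3 (alpha, beta, gamma) in degrees.
#' @param facet_normals F x 3 matrix of unit outward normals.
#' @param facet_distances length-F positive distances.
#' @param n_surface_points surface points to draw when sampling.
#' @param seed integer seed for sampling.
#' @return An object of class `habit_spec`.
#' @export
habit_spec <- function(crystal_system, cell_angles, facet_normals,
                       facet_distances, n_surface_points = 800L, seed = 1L) {
  crystal_system <- match.arg(crystal_system,
                              c("monoclinic", "tetragonal", "hexagonal"))
  facet_normals <- as.matrix(facet_normals)
  stopifnot(ncol(facet_normals) == 3L,
            length(facet_distances) == nrow(facet_normals),
            length(cell_angles) == 3L)
  if (any(facet_distances <= 0)) stop("facet distances must be positive")
  nn <- sqrt(rowSums(facet_normals^2))
  if (any(abs(nn - 1) > 1e-9)) stop("facet normals must be unit length")
  gamma <- cell_angles[3L]
  inplane <- abs(facet_normals[, 3L]) < 1e-9
  if (crystal_system == "tetragonal") {
    if (abs(gamma - 90) > 1e-9) stop("tetragonal spec requires gamma = 90")
    d <- facet_distances[inplane]
    if (length(d) && diff(range(d)) > 1e-9 * max(d) &&
        length(unique(round(d, 9))) > 2L)
      stop("tetragonal in-plane facets must form symmetry-equivalent pairs")
  }
  if (crystal_system == "hexagonal") {
    if (abs(gamma - 120) > 1e-9) stop("hexagonal spec requires gamma = 120")
    d <- facet_distances[inplane]
    if (length(d) && diff(range(d)) > 1e-9 * max(d))
      stop("hexagonal in-plane facet family must share one distance")
  }
  structure(list(crystal_system = crystal_system,
                 cell_angles = as.numeric(cell_angles),
                 facet_normals = facet_normals,
                 facet_distances = as.numeric(facet_distances),
                 n_surface_points = as.integer(n_surface_points),
                 seed = as.integer(seed)),
            class = "habit_spec")
}

#' @export
print.habit_spec <- function(x, ...) {
  cat(sprintf("<habit_spec> %s, %d facets, gamma = %g deg\n",
              x$crystal_system, nrow(x$facet_normals), x$cell_angles[3L]))
  invisible(x)
}

# Vertex enumeration of {x : N x <= d} via convex-hull duality: with the
# origin interior, the vertices are the polars of the facets of
# conv{n_i / d_i}.  Requires boundedness, i.e. 0 strictly inside conv{n_i}.
halfspace_vertices <- function(normals, distances) {
  normals <- as.matrix(normals)
  bounded <- FALSE
  if (nrow(normals) >= 4L) {
    nh <- tryCatch(convex_hull(normals), error = function(e) NULL)
    bounded <- !is.null(nh) && min(nh$offsets) > 1e-9
  }
  if (!bounded) stop("unbounded habit: facet normals do not enclose the origin")
  dual <- normals / distances
  dh <- convex_hull(dual)
  verts <- matrix(NA_real_, nrow(dh$faces), 3L)
  for (r in seq_len(nrow(dh$faces))) {
    i <- dh$faces[r, ]
    verts[r, ] <- solve(normals[i, , drop = FALSE], distances[i])
  }
  scale <- max(abs(verts))
  key <- apply(round(verts / scale, 9L), 1L, paste, collapse = ",")
  verts <- verts[!duplicated(key), , drop = FALSE]
  slack <- verts %*% t(normals) - rep(distances, each = nrow(verts))
  verts[apply(slack <= 1e-9 * scale, 1L, all), , drop = FALSE]
}

#' Realize a habit spec as a convex polyhedron
#'
#' Intersects the spec's facet halfspaces, returning the vertex set plus the
#' hull triangulation, and labels the solid with its ground-truth Zingg
#' class. The ground truth uses the exact uniform-solid covariance of the
#' polyhedron (tetrahedral decomposition), whose eigenvalue square roots are
#' the RMS S, M, L half-extents.
#'
#' @param spec a [habit_spec()].
#' @param threshold Zingg threshold for the ground-truth label.
#' @return An object of class `habit`: `vertices` (V x 3), `hull`
#'   (see [convex_hull()]), `spec`, and `ground_truth` (list with
#'   `zingg_class`, `crystal_system`, `s_m`, `m_l`).
#' @export
make_habit <- function(spec, threshold = 0.66) {
  stopifnot(inherits(spec, "habit_spec"))
  verts <- halfspace_vertices(spec$facet_normals, spec$facet_distances)
  if (nrow(verts) < 4L) stop("degenerate habit: fewer than 4 vertices")
  hull <- convex_hull(verts)
  if (hull$volume < 1e-9 * max(abs(verts))^3)
    stop("degenerate habit: volume below tolerance")
  ext <- hull_solid_extents(hull)
  s_m <- ext[1L] / ext[2L]
  m_l <- ext[2L] / ext[3L]
  gt <- list(zingg_class = zingg_classify(s_m, m_l, threshold = threshold),
             crystal_system = spec$crystal_system, s_m = s_m, m_l = m_l)
  structure(list(vertices = verts, hull = hull, spec = spec,
                 ground_truth = gt), class = "habit")
}

#' @export
print.habit <- function(x, ...) {
  cat(sprintf("<habit> %s %s: %d vertices, s_m %.3f, m_l %.3f\n",
              x$ground_truth$crystal_system, x$ground_truth$zingg_class,
              nrow(x$vertices), x$ground_truth$s_m, x$ground_truth$m_l))
  invisible(x)
}

#' Sample points uniformly on a polyhedron surface
#'
#' Draws `n_points` points on the facets of a closed convex polyhedron,
#' with expected per-facet counts proportional to facet area (facet chosen
#' categorically by area, position uniform by barycentric coordinates).
#' Every returned point lies on a facet plane to within 1e-9 of the shape
#' scale. Deterministic for a fixed seed.
#'
#' @param habit a `habit` from [make_habit()], or a `hull3d`.
#' @param n_points number of points (>= 4).
#' @param seed integer seed.
#' @return A [point_cloud()].
#' @export
sample_surface <- function(habit, n_points = 800L, seed = 1L) {
  hull <- if (inherits(habit, "habit")) habit$hull
          else if (inherits(habit, "hull3d")) habit
          else stop("sample_surface: need a habit or hull3d")
  if (n_points < 4L) stop("sample_surface: n_points must be >= 4")
  areas <- hull_face_areas(hull)
  if (!all(is.finite(areas)) || sum(areas) <= 0)
    stop("sample_surface: open or degenerate surface")
  with_local_seed(seed, {
    fi <- sample.int(length(areas), n_points, replace = TRUE, prob = areas)
    u <- runif(n_points)
    v <- runif(n_points)
    flip <- u + v > 1
    u[flip] <- 1 - u[flip]
    v[flip] <- 1 - v[flip]
    a <- hull$points[hull$faces[fi, 1L], , drop = FALSE]
    b <- hull$points[hull$faces[fi, 2L], , drop = FALSE]
    c3 <- hull$points[hull$faces[fi, 3L], , drop = FALSE]
    point_cloud(a + u * (b - a) + v * (c3 - a), source_id = "surface-sample")
  })
}

# Uniform sample of the solid interior (tetrahedral decomposition against
# the volume centroid); used by oracle-style checks.
sample_solid <- function(habit, n_points = 2000L, seed = 1L) {
  hull <- if (inherits(habit, "habit")) habit$hull else habit
  ctr <- hull$centroid
  a <- hull$points[hull$faces[, 1L], , drop = FALSE]
  b <- hull$points[hull$faces[, 2L], , drop = FALSE]
  c3 <- hull$points[hull$faces[, 3L], , drop = FALSE]
  vol <- abs(vapply(seq_len(nrow(a)), function(r)
    det(rbind(a[r, ] - ctr, b[r, ] - ctr, c3[r, ] - ctr)) / 6, 0))
  with_local_seed(seed, {
    ti <- sample.int(length(vol), n_points, replace = TRUE, prob = abs(vol))
    r1 <- runif(n_points)^(1 / 3)
    r2 <- sqrt(runif(n_points))
    r3 <- runif(n_points)
    A <- sweep(a[ti, , drop = FALSE], 2L, ctr)
    B <- sweep(b[ti, , drop = FALSE], 2L, ctr)
    C <- sweep(c3[ti, , drop = FALSE], 2L, ctr)
    P <- r1 * ((1 - r2) * A + r2 * ((1 - r3) * B + r3 * C))
    point_cloud(sweep(P, 2L, -ctr), source_id = "solid-sample")
  })
}

# ---- spec builders ---------------------------------------------------------

rot2 <- function(theta) c(cos(theta), sin(theta))

# Monoclinic: beta != 90 parallelepiped (3 facet pairs), optional corner
# truncations. Distances d target RMS solid half-extent ratios directly for
# the untruncated orthogonal limit.
spec_monoclinic <- function(d, beta, trunc_frac = NA, n_surface_points = 800L,
                            seed = 1L) {
  br <- beta * pi / 180
  n1 <- c(sin(br), 0, -cos(br))          # normal of the (b, c) face pair
  normals <- rbind(n1, -n1, c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  dists <- c(d[1L], d[1L], d[2L], d[2L], d[3L], d[3L])
  if (is.finite(trunc_frac)) {
    corners <- as.matrix(expand.grid(s1 = c(-1, 1), s2 = c(-1, 1),
                                     s3 = c(-1, 1)))
    cn <- corners %*% rbind(n1, c(0, 1, 0), c(0, 0, 1))
    cn <- cn / sqrt(rowSums(cn^2))
    # cut at trunc_frac of the farthest support along each corner direction
    dmax <- apply(cn, 1L, function(u) {
      v <- halfspace_support(normals, dists, u)
      v
    })
    normals <- rbind(normals, cn)
    dists <- c(dists, trunc_frac * dmax)
  }
  habit_spec("monoclinic", c(90, beta, 90), normals, dists,
             n_surface_points = n_surface_points, seed = seed)
}

# Support function h(u) = max_x u.x over the halfspace intersection,
# evaluated through its vertices.
halfspace_support <- function(normals, distances, u) {
  verts <- halfspace_vertices(normals, distances)
  max(verts %*% u)
}

# Tetragonal prism (a = b, gamma = 90): square cross-section with shared
# in-plane distance, optional {110} edge cuts preserving the symmetry.
spec_tetragonal <- function(d_ab, d_c, cut_frac = NA, n_surface_points = 800L,
                            seed = 1L) {
  normals <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))
  dists <- c(d_ab, d_ab, d_ab, d_ab, d_c, d_c)
  if (is.finite(cut_frac)) {
    s2 <- 1 / sqrt(2)
    cuts <- rbind(c(s2, s2, 0), c(-s2, s2, 0), c(s2, -s2, 0), c(-s2, -s2, 0))
    normals <- rbind(normals, cuts)
    dists <- c(dists, rep(cut_frac * sqrt(2) * d_ab, 4L))
  }
  habit_spec("tetragonal", c(90, 90, 90), normals, dists,
             n_surface_points = n_surface_points, seed = seed)
}

# Hexagonal prism (a = b, gamma = 120): regular-hexagon cross-section from
# the six-member in-plane facet family sharing one distance.
spec_hexagonal <- function(d_ab, d_c, n_surface_points = 800L, seed = 1L) {
  ang <- (0:5) * pi / 3
  normals <- rbind(cbind(cos(ang), sin(ang), 0), c(0, 0, 1), c(0, 0, -1))
  dists <- c(rep(d_ab, 6L), d_c, d_c)
  habit_spec("hexagonal", c(90, 90, 120), normals, dists,
             n_surface_points = n_surface_points, seed = seed)
}

# Draw one habit spec targeting a Zingg class within a crystal system.
# Aspect targets are log-uniform in [0.15, 1] per ratio, resampled until the
# realized exact-solid class matches the request. Monoclinic draws
# beta ~ U(95, 125) deg and corner truncations with probability 1/2;
# tetragonal draws optional edge cuts; hexagonal prisms are untruncated.
draw_habit_spec <- function(crystal_system, zingg_class, n_surface_points,
                            seed, threshold = 0.66, max_tries = 200L) {
  crystal_system <- match.arg(crystal_system,
                              c("monoclinic", "tetragonal", "hexagonal"))
  zingg_class <- match.arg(zingg_class, zingg_levels())
  if (zingg_class == "lath" && crystal_system != "monoclinic")
    stop("configuration error: lath habits are not accessible in the ",
         crystal_system, " system (two equal cell axes)")
  log_u <- function(lo, hi) exp(runif(1L, log(lo), log(hi)))
  with_local_seed(seed, {
    for (try in seq_len(max_tries)) {
      spec <- if (crystal_system == "monoclinic") {
        tgt <- switch(zingg_class,
          block  = c(log_u(threshold, 1), log_u(threshold, 1)),
          needle = c(log_u(threshold, 1), log_u(0.15, threshold)),
          plate  = c(log_u(0.15, threshold), log_u(threshold, 1)),
          lath   = c(log_u(0.15, threshold), log_u(0.15, threshold)))
        beta <- runif(1L, 95, 125)
        tf <- if (runif(1L) < 0.5) runif(1L, 0.85, 0.99) else NA
        spec_monoclinic(c(tgt[1L] * tgt[2L], tgt[2L], 1), beta,
                        trunc_frac = tf,
                        n_surface_points = n_surface_points, seed = seed)
      } else {
        # two equal in-plane extents: only the prism height ratio varies
        r <- switch(zingg_class,
          block  = log_u(threshold + 0.02, 1),
          needle = log_u(0.15, threshold),
          plate  = log_u(0.15, threshold))
        tall <- zingg_class == "needle" ||
          (zingg_class == "block" && runif(1L) < 0.5)
        d_ab <- if (tall) r else 1
        d_c <- if (tall) 1 else r
        if (crystal_system == "tetragonal") {
          cf <- if (runif(1L) < 0.5) runif(1L, 0.8, 0.98) else NA
          spec_tetragonal(d_ab, d_c, cut_frac = cf,
                          n_surface_points = n_surface_points, seed = seed)
        } else {
          spec_hexagonal(d_ab, d_c, n_surface_points = n_surface_points,
                         seed = seed)
        }
      }
      hb <- make_habit(spec, threshold = threshold)
      if (hb$ground_truth$zingg_class == zingg_class) return(hb)
    }
    stop("draw_habit_spec: could not realize class ", zingg_class, " in ",
         crystal_system, " after ", max_tries, " tries")
  })
}

#' Generate one labelled synthetic habit cloud
#'
#' Draws a habit spec targeting the requested crystal system and Zingg
#' class, realizes the polyhedron, samples its surface, and adds a small
#' isotropic coordinate jitter emulating growth-surface roughness.
#'
#' @param crystal_system,zingg_class requested labels. Laths are
#'   geometrically inaccessible to tetragonal and hexagonal systems and
#'   raise a configuration error.
#' @param n_surface_points surface sample size.
#' @param seed integer seed (deterministic output).
#' @param jitter_sd jitter standard deviation as a fraction of the maximum
#'   extent (default 0.003); set 0 to disable.
#' @param threshold Zingg threshold for ground truth.
#' @return List with `cloud` ([point_cloud()]), `habit`, and `ground_truth`.
#' @export
generate_habit <- function(crystal_system, zingg_class,
                           n_surface_points = 800L, seed = 1L,
                           jitter_sd = 0.003, threshold = 0.66) {
  hb <- draw_habit_spec(crystal_system, zingg_class, n_surface_points,
                        seed = seed, threshold = threshold)
  pc <- sample_surface(hb, n_points = n_surface_points, seed = seed + 7L)
  if (jitter_sd > 0) {
    ext <- max(sqrt(rowSums(sweep(pc$points, 2L, colMeans(pc$points))^2)))
    pc <- with_local_seed(seed + 13L, point_cloud(
      pc$points + matrix(rnorm(length(pc$points), sd = jitter_sd * ext),
                         ncol = 3L),
      source_id = pc$source_id))
  }
  list(cloud = pc, habit = hb, ground_truth = hb$ground_truth)
}

#' Generate a labelled synthetic habit dataset
#'
#' Produces the requested number of habits per (crystal system, Zingg
#' class) cell. With `out_dir` set, one XYZ file per habit plus a
#' `labels.csv` manifest (columns `file`, `zingg_class`, `crystal_system`,
#' `s_m`, `m_l`, `seed`) are written; the run is byte-identical for a fixed
#' seed. Without `out_dir` the clouds are returned in memory.
#'
#' @param counts `data.frame` with columns `crystal_system`, `zingg_class`,
#'   `n`. Requesting laths in tetragonal or hexagonal systems is a
#'   configuration error.
#' @param out_dir optional output directory.
#' @param n_surface_points points per habit surface.
#' @param seed master seed; per-habit seeds are derived from it.
#' @param jitter_sd see [generate_habit()].
#' @param dialect XYZ dialect for [write_xyz()].
#' @return List with `manifest` (`data.frame`) and `clouds` (list of
#'   [point_cloud()], in manifest order).
#' @export
generate_dataset <- function(counts, out_dir = NULL, n_surface_points = 800L,
                             seed = 1L, jitter_sd = 0.003,
                             dialect = "bare") {
  stopifnot(all(c("crystal_system", "zingg_class", "n") %in% names(counts)))
  bad <- counts$zingg_class == "lath" &
    counts$crystal_system %in% c("tetragonal", "hexagonal") & counts$n > 0
  if (any(bad))
    stop("configuration error: lath habits requested for ",
         paste(unique(counts$crystal_system[bad]), collapse = ", "),
         " system(s)")
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  rows <- list()
  clouds <- list()
  k <- 0L
  for (r in seq_len(nrow(counts))) {
    for (i in seq_len(counts$n[r])) {
      k <- k + 1L
      sd_i <- seed + 1000L * k
      g <- generate_habit(counts$crystal_system[r], counts$zingg_class[r],
                          n_surface_points = n_surface_points, seed = sd_i,
                          jitter_sd = jitter_sd)
      fname <- sprintf("habit_%05d.xyz", k)
      if (!is.null(out_dir))
        write_xyz(g$cloud, file.path(out_dir, fname), dialect = dialect)
      rows[[k]] <- data.frame(
        file = fname, zingg_class = g$ground_truth$zingg_class,
        crystal_system = g$ground_truth$crystal_system,
        s_m = g$ground_truth$s_m, m_l = g$ground_truth$m_l, seed = sd_i,
        stringsAsFactors = FALSE)
      clouds[[k]] <- g$cloud
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir))
    write.csv(manifest, file.path(out_dir, "labels.csv"), row.names = FALSE)
  list(manifest = manifest, clouds = clouds)
}
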