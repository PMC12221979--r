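test_that("surface rasterization marks exactly the voxels containing points", {
  g <- rasterize(matrix(c(0, 0, 0), 1, 3), resolution = 16,
                 fill = "surface")
  expect_equal(sum(g$values), 1)

  expect_error(rasterize(matrix(numeric(0), 0, 3)), "empty")
  expect_error(rasterize(matrix(0, 4, 3), resolution = 7), "even")
})

test_that("convex-solid occupancy tracks the hull volume fraction", {
  # generic hull (ball): centre containment is unbiased, fraction within 3%
  sph <- center_and_normalize(unit_sphere_cloud(3000))
  gb <- rasterize(sph, resolution = 64, fill = "convex_solid")
  expect_equal(mean(gb$values), hull_metrics(sph)$volume / 8,
               tolerance = 0.03)

  # ball-inscribed cube: derived expectation under centre containment.
  # The cube face at 1/sqrt(3) = 0.57735 falls just inside the centres at
  # 0.578125, so exactly 36 centres per axis qualify, plus the 8 corner
  # voxels that contain input points.
  pc <- center_and_normalize(cube_corners(1))
  g <- rasterize(pc, resolution = 64, fill = "convex_solid")
  expect_equal(sum(g$values), 36^3 + 8)
  hull_vol <- (2 / sqrt(3))^3                    # inscribed cube
  expect_equal(mean(g$values), hull_vol / 8, tolerance = 0.08)

  # solid occupancy is a superset of surface occupancy
  gs <- rasterize(pc, resolution = 64, fill = "surface")
  expect_true(all(g$values >= gs$values))
  gss <- rasterize(sph, resolution = 32, fill = "surface")
  gsb <- rasterize(sph, resolution = 32, fill = "convex_solid")
  expect_true(all(gsb$values >= gss$values))
})

test_that("padding centres values, conserves the sum and handles odd margins", {
  set.seed(1)
  v <- array(runif(60^3) > 0.5, rep(60, 3)) * 1
  g <- voxel_grid(v, spacing = 2 / 60)
  p <- pad_to_cube(g, 64)
  expect_equal(dim(p$values), rep(64L, 3))
  expect_equal(sum(p$values), sum(v))
  expect_identical(pad_to_cube(g, 60), g)
  expect_error(pad_to_cube(g, 32), "smaller")

  # odd margin: extra zero layer on the high side
  g3 <- voxel_grid(array(1, rep(3, 3)), spacing = 1)
  p3 <- pad_to_cube(g3, 6)
  expect_equal(sum(p3$values[1, , ]), 0)        # low side: one layer
  expect_equal(sum(p3$values[2:4, 2:4, 2:4]), 27)
  expect_equal(sum(p3$values[5:6, , ]), 0)      # high side: two layers
})

test_that("block-max pooling equals the triple-loop oracle", {
  set.seed(9)
  for (rep in 1:3) {
    v <- array(runif(16^3), rep(16, 3))
    g <- voxel_grid(v, spacing = 2 / 16, binary = FALSE)
    got <- block_max_downsample(g, 2)$values
    expect_equal(got, oracle_block_max(v, 2))
  }
  ones <- voxel_grid(array(1, rep(64, 3)))
  expect_true(all(block_max_downsample(ones, 2)$values == 1))
  single <- array(0, rep(16, 3)); single[5, 11, 2] <- 1
  out <- block_max_downsample(voxel_grid(single, spacing = 2 / 16), 2)
  expect_equal(sum(out$values), 1)
  expect_error(block_max_downsample(voxel_grid(array(0, rep(15, 3)),
                                               spacing = 1), 2),
               "divisible")
})

test_that("pooling plus padding can never create occupancy", {
  set.seed(11)
  v <- array(runif(30^3) > 0.8, rep(30, 3)) * 1
  g <- voxel_grid(v, spacing = 2 / 30)
  out <- block_max_downsample(pad_to_cube(g, 32), 2)
  expect_lte(sum(out$values), sum(v))
})

test_that("voxels_to_points returns voxel centres and respects the threshold", {
  v <- array(0, rep(8, 3)); v[3, 5, 8] <- 1
  g <- voxel_grid(v, origin = c(-1, -1, -1), spacing = 0.25)
  pc <- voxels_to_points(g)
  expect_equal(drop(pc$points),
               c(-1 + 2.5 * 0.25, -1 + 4.5 * 0.25, -1 + 7.5 * 0.25))
  expect_error(voxels_to_points(g, threshold = 1.1), "empty shape")
})

test_that("voxel round trip preserves box aspect ratios within 5%", {
  cloud <- box_grid_cloud(c(1, 2, 4), 15)
  ax0 <- pca_axes(cloud)
  g <- rasterize(center_and_normalize(cloud), resolution = 64,
                 fill = "convex_solid")
  ax1 <- pca_axes(voxels_to_points(g))
  expect_equal(ax1$s_m, ax0$s_m, tolerance = 0.05)
  expect_equal(ax1$m_l, ax0$m_l, tolerance = 0.05)
})

test_that("voxelization preserves the Zingg class of generated habits", {
  counts <- data.frame(
    crystal_system = c("monoclinic", "monoclinic", "tetragonal"),
    zingg_class = c("lath", "block", "needle"),
    n = c(8L, 8L, 8L))
  ds <- generate_dataset(counts, n_surface_points = 400, seed = 21)
  keep <- abs(ds$manifest$s_m - 0.66) > 0.08 &
    abs(ds$manifest$m_l - 0.66) > 0.08
  cls_cloud <- vapply(ds$clouds, measure_class, "")
  cls_voxel <- vapply(ds$clouds, function(pc) {
    g <- voxelize_cloud(pc, model_side = 32, align = FALSE)
    measure_class(voxels_to_points(g))
  }, "")
  expect_gte(mean(cls_voxel[keep] == cls_cloud[keep]), 0.95)
})

test_that("the voxel container round-trips grids with metadata", {
  set.seed(3)
  gs <- list(
    a = voxel_grid(array(runif(8^3), rep(8, 3)), spacing = 0.25,
                   binary = FALSE),
    b = voxel_grid(array(runif(8^3) > 0.5, rep(8, 3)) * 1, spacing = 0.25))
  f <- withr::local_tempfile(fileext = ".vxb")
  write_voxels(gs, f)
  back <- read_voxels(f)
  expect_equal(names(back), c("a", "b"))
  expect_equal(back$a$values, gs$a$values, tolerance = 1e-6)
  expect_equal(back$b$values, gs$b$values)   # binary survives exactly
  expect_equal(back$a$spacing, 0.25)
})
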