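axis_normals <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                      c(0, 0, 1), c(0, 0, -1))

test_that("a cube spec realizes the 8 corner vertices", {
  spec <- habit_spec("tetragonal", c(90, 90, 90), axis_normals, rep(2, 6))
  hb <- make_habit(spec)
  v <- hb$vertices
  expect_equal(nrow(v), 8L)
  expect_equal(sort(unique(round(as.vector(v), 9))), c(-2, 2))
  expect_equal(hb$ground_truth$zingg_class, "block")
})

test_that("halfspace vertices match the triple-enumeration oracle", {
  set.seed(10)
  for (rep in 1:5) {
    # random bounded system: cube faces plus random cutting planes
    extra <- matrix(rnorm(18), ncol = 3)
    extra <- extra / sqrt(rowSums(extra^2))
    normals <- rbind(axis_normals, extra)
    dists <- c(rep(1, 6), runif(6, 0.8, 1.6))
    got <- habitspace:::halfspace_vertices(normals, dists)
    want <- oracle_halfspace_vertices(normals, dists)
    expect_equal(nrow(got), nrow(want))
    ord <- function(m) m[order(round(m[, 1], 6), round(m[, 2], 6),
                               round(m[, 3], 6)), , drop = FALSE]
    expect_equal(ord(got), ord(want), tolerance = 1e-7,
                 ignore_attr = TRUE)
  }
})

test_that("unbounded and degenerate systems raise the right errors", {
  # open slab: normals do not enclose the origin
  expect_error(
    make_habit(habit_spec("tetragonal", c(90, 90, 90),
                          axis_normals[1:4, ], rep(1, 4))),
    "unbounded habit")
  expect_error(habit_spec("tetragonal", c(90, 90, 90), axis_normals,
                          c(1, 1, 1, 1, 1, -1)), "positive")
  expect_error(habit_spec("tetragonal", c(90, 90, 90),
                          axis_normals * 1.01, rep(1, 6)), "unit length")
})

test_that("a 6:1 tetragonal prism is a needle by the solid oracle", {
  s <- 0.5
  spec <- habitspace:::spec_tetragonal(s, 6 * s)
  hb <- make_habit(spec)
  expect_equal(hb$ground_truth$zingg_class, "needle")
  # independent dense-grid solid oracle
  r <- oracle_solid_ratios(box_grid_cloud(c(s, s, 6 * s)))
  expect_equal(unname(r["s_m"]), 1, tolerance = 1e-9)
  expect_equal(unname(r["m_l"]), 1 / 6, tolerance = 1e-3)
  expect_equal(hb$ground_truth$s_m, 1, tolerance = 1e-9)
  expect_equal(hb$ground_truth$m_l, 1 / 6, tolerance = 1e-9)
})

test_that("gamma = 120 rhombic cross-section has diagonals a sqrt(2 +/- 2 cos 60)", {
  # in-plane facet pairs of the gamma = 120 cell: faces parallel to the a
  # and b cell vectors; the cross-section is a rhombus of side a
  b_dir <- c(cos(2 * pi / 3), sin(2 * pi / 3))
  n1 <- c(b_dir[2], -b_dir[1])              # unit normal to b
  n2 <- c(0, 1)                             # unit normal to a = x
  a_len <- 2
  d_in <- a_len * sqrt(3) / 2 / 2           # half-height of the rhombus
  normals <- rbind(c(n1, 0), c(-n1, 0), c(n2, 0), c(-n2, 0),
                   c(0, 0, 1), c(0, 0, -1))
  spec <- habit_spec("hexagonal", c(90, 90, 120), normals,
                     c(rep(d_in, 4), 1, 1))
  hb <- make_habit(spec)
  xy <- unique(round(hb$vertices[, 1:2], 9))
  expect_equal(nrow(xy), 4L)
  diags <- sort(c(max(dist(xy)), min(apply(xy, 1, function(p)
    max(sqrt(rowSums((xy - rep(p, each = 4))^2)))))))
  alpha <- pi / 3
  expect_equal(diags[1], a_len * sqrt(2 - 2 * cos(alpha)), tolerance = 1e-9)
  expect_equal(diags[2], a_len * sqrt(2 + 2 * cos(alpha)), tolerance = 1e-9)
})

test_that("surface samples lie on facet planes with area-proportional counts", {
  spec <- habit_spec("tetragonal", c(90, 90, 90), axis_normals, rep(1, 6))
  hb <- make_habit(spec)
  pc <- sample_surface(hb, n_points = 5000, seed = 3)
  expect_equal(nrow(pc$points), 5000L)
  # every point on some facet plane
  resid <- apply(abs(pc$points %*% t(hb$hull$normals) -
                       rep(hb$hull$offsets, each = 5000)), 1, min)
  expect_lt(max(resid), 1e-9)
  # per-face counts: faces of a cube have equal area
  face <- apply(abs(pc$points), 1, which.max) * sign(
    pc$points[cbind(1:5000, apply(abs(pc$points), 1, which.max))])
  counts <- table(face)
  expect_equal(length(counts), 6L)
  chi <- suppressWarnings(chisq.test(counts))
  expect_gt(chi$p.value, 0.001)
  # determinism
  pc2 <- sample_surface(hb, n_points = 5000, seed = 3)
  expect_identical(pc$points, pc2$points)
})

test_that("square-cross-section prisms never classify as lath", {
  for (hr in c(0.2, 0.5, 0.9, 1, 1.3, 3, 8)) {
    hb <- make_habit(habitspace:::spec_tetragonal(1, hr))
    expect_true(hb$ground_truth$zingg_class != "lath")
    hbh <- make_habit(habitspace:::spec_hexagonal(1, hr))
    expect_true(hbh$ground_truth$zingg_class != "lath")
  }
})

test_that("tetragonal height sweep only yields plate, block or needle", {
  cls <- vapply(seq(0.15, 6, length.out = 12), function(hr)
    make_habit(habitspace:::spec_tetragonal(1, hr))$ground_truth$zingg_class,
    "")
  expect_true(all(cls %in% c("plate", "block", "needle")))
  expect_true(all(c("plate", "block", "needle") %in% cls))
})

test_that("generate_dataset honours counts, rejects impossible requests and is reproducible", {
  counts <- data.frame(
    crystal_system = "monoclinic",
    zingg_class = c("block", "needle", "plate", "lath"),
    n = c(10L, 10L, 10L, 10L))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  ds1 <- generate_dataset(counts, out_dir = d1, n_surface_points = 200,
                          seed = 42)
  expect_equal(nrow(ds1$manifest), 40L)
  expect_equal(unname(table(ds1$manifest$zingg_class)[zingg_levels()]),
               rep(10L, 4), ignore_attr = TRUE)
  ds2 <- generate_dataset(counts, out_dir = d2, n_surface_points = 200,
                          seed = 42)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  expect_error(
    generate_dataset(data.frame(crystal_system = "tetragonal",
                                zingg_class = "lath", n = 1L)),
    "configuration error")
})

test_that("generated labels agree with cloud classification away from the boundary", {
  counts <- data.frame(
    crystal_system = c("monoclinic", "monoclinic", "tetragonal", "hexagonal"),
    zingg_class = c("lath", "needle", "plate", "block"),
    n = c(15L, 15L, 15L, 15L))
  ds <- generate_dataset(counts, n_surface_points = 500, seed = 7)
  meas <- vapply(ds$clouds, measure_class, "")
  margin <- 0.08   # surface sampling biases ratios upward near the threshold
  away <- abs(ds$manifest$s_m - 0.66) > margin &
    abs(ds$manifest$m_l - 0.66) > margin
  agree <- meas[away] == ds$manifest$zingg_class[away]
  expect_gte(mean(agree), 0.95)
})
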