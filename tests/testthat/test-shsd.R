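test_that("coefficient indexing follows the (l, m) lexicographic order", {
  expect_equal(coefficient_index(0, 0), 0L)
  expect_equal(coefficient_index(1, 0), 1L)
  expect_equal(coefficient_index(1, 1), 2L)
  expect_equal(coefficient_index(2, 0), 3L)
  expect_equal(coefficient_index(2, 1), 4L)
  expect_equal(coefficient_index(2, 2), 5L)
  expect_equal(coefficient_index(10, 10), 65L)
  expect_error(coefficient_index(2, 3), "m <= l")
  expect_error(coefficient_index(2, -1), "m <= l")
})

test_that("a constant radial map has Mag_0 = 2 sqrt(pi) and nothing else", {
  q <- sphere_quadrature(32, 64)
  rmap <- q
  rmap$radii <- rep(1, nrow(q$directions))
  class(rmap) <- "radial_map"
  d <- sh_expand(rmap, lmax = 10)
  expect_length(d$magnitudes, 66L)
  expect_equal(unname(d$magnitudes[1]), 2 * sqrt(pi), tolerance = 1e-10)
  expect_lt(max(d$magnitudes[-1]), 1e-8)
})

test_that("quadratures too coarse for the requested lmax are refused", {
  q <- sphere_quadrature(8, 64)
  q$radii <- rep(1, nrow(q$directions))
  expect_error(sh_expand(q, lmax = 10), "n_theta >= 11")
  q2 <- sphere_quadrature(16, 12)
  q2$radii <- rep(1, nrow(q2$directions))
  expect_error(sh_expand(q2, lmax = 10), "n_phi >= 21")
})

test_that("band-limited radial maps are recovered exactly", {
  # r(theta, phi) built from degree <= 10 harmonics comes back to 1e-10
  q <- sphere_quadrature(24, 48)
  Y <- habitspace:::sph_harm_matrix(10, q$theta, q$phi)
  r <- 2 + 0.3 * Re(Y[, coefficient_index(3, 2) + 1]) +
    0.2 * Re(Y[, coefficient_index(10, 4) + 1]) -
    0.15 * Y[, coefficient_index(6, 0) + 1]   # m = 0 harmonics are real
  rmap <- q
  rmap$radii <- Re(r)
  d <- sh_expand(rmap, lmax = 10)
  # Re(Y_lm) = (Y_lm + conj(Y_lm))/2 contributes c_lm = 0.5 * amplitude
  expect_equal(unname(d$magnitudes[coefficient_index(3, 2) + 1]), 0.15,
               tolerance = 1e-10)
  expect_equal(unname(d$magnitudes[coefficient_index(10, 4) + 1]), 0.1,
               tolerance = 1e-10)
  expect_equal(unname(Mod(d$coefficients[coefficient_index(6, 0) + 1])),
               0.15, tolerance = 1e-10)
  expect_equal(unname(Mod(d$coefficients[coefficient_index(0, 0) + 1])),
               4 * sqrt(pi), tolerance = 1e-10)  # constant term 2 * Y00 norm
})

test_that("Parseval holds for band-limited maps", {
  q <- sphere_quadrature(24, 48)
  Y <- habitspace:::sph_harm_matrix(5, q$theta, q$phi)
  r <- 1.5 + 0.4 * Re(Y[, coefficient_index(4, 3) + 1])
  rmap <- q
  rmap$radii <- Re(r)
  d <- sh_expand(rmap, lmax = 5)
  # full +/- m power: m > 0 magnitudes count twice
  mult <- ifelse(d$lm[, 2] == 0, 1, 2)
  power <- sum(mult * d$magnitudes^2)
  integral <- sum(q$weights * rmap$radii^2)
  expect_equal(power, integral, tolerance = 1e-6)
})

test_that("radial support map of cubes and boxes is exact", {
  h <- convex_hull(cube_corners(1))
  dirs <- rbind(c(1, 0, 0), c(0, 0, 1), c(1, 1, 1) / sqrt(3))
  q <- list(directions = dirs, weights = rep(1, 3), theta = acos(dirs[, 3]),
            phi = atan2(dirs[, 2], dirs[, 1]), n_theta = 64, n_phi = 128)
  rmap <- radial_function(h, q)
  expect_equal(rmap$radii, c(1, 1, sqrt(3)), tolerance = 1e-12)

  hb <- convex_hull(cube_corners(1) %*% diag(c(1, 2, 4)))
  rb <- radial_function(hb, q)
  expect_equal(rb$radii[1], 1, tolerance = 1e-12)
  expect_equal(rb$radii[2], 4, tolerance = 1e-12)
})

test_that("descriptors respect symmetry, scaling and continuity", {
  q <- sphere_quadrature(24, 48)
  cube <- cube_corners(1)
  d0 <- describe_cloud(cube, quadrature = q)
  # 90-degree rotation about z maps the cube onto itself
  rot <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  d90 <- describe_cloud(cube %*% rot, quadrature = q)
  expect_equal(d90$magnitudes, d0$magnitudes, tolerance = 1e-6)

  d2x <- describe_cloud(2 * cube, quadrature = q)
  expect_equal(d2x$magnitudes, 2 * d0$magnitudes, tolerance = 1e-9)

  box <- cube %*% diag(c(1, 2, 4))
  d_box <- describe_cloud(box, quadrature = q)
  d_near <- describe_cloud(cube %*% diag(c(1, 2, 4.0001)), quadrature = q)
  expect_lt(sqrt(sum((d_near$magnitudes - d_box$magnitudes)^2)),
            sqrt(sum((d0$magnitudes - d_box$magnitudes)^2)))
})

test_that("prolate shapes put the largest l = 2 magnitude in Mag_3", {
  prolate <- cube_corners(1) %*% diag(c(1, 1, 3))
  d <- describe_cloud(prolate)
  l2 <- d$magnitudes[coefficient_index(2, 0:2) + 1]
  expect_equal(unname(which.max(l2)), 1L)   # (2, 0), i.e. Mag_3
})

test_that("truncated synthesis error is small for equant habits and grows with anisotropy", {
  # A degree-10 truncation resolves near-equant polyhedra well; thin
  # high-aspect shapes have sharp radial features it cannot follow, so the
  # error must increase monotonically with elongation.
  q <- sphere_quadrature(32, 64)
  recon_err <- function(hull) {
    rmap <- radial_function(hull, q)
    d <- sh_expand(rmap, lmax = 10)
    rhat <- sh_synthesize(d, q$theta, q$phi)
    max(abs(rhat - rmap$radii) / rmap$radii)
  }
  errs <- vapply(1:6, function(seed) {
    g <- generate_habit("monoclinic", "block", n_surface_points = 300,
                        seed = 100 * seed + 3, jitter_sd = 0)
    recon_err(g$habit$hull)
  }, 0)
  expect_lt(median(errs), 0.10)
  expect_lt(max(errs), 0.16)
  prism_err <- vapply(c(1, 3, 8), function(ar)
    recon_err(convex_hull(cube_corners(1) %*% diag(c(1, 1, ar)))), 0)
  expect_lt(prism_err[1], 0.10)
  expect_true(all(diff(prism_err) > 0))
})

test_that("describe_clouds produces a keyed magnitude table", {
  tab <- describe_clouds(list(cube_corners(1), cube_corners(2)),
                         ids = c("a", "b"), lmax = 4,
                         quadrature = sphere_quadrature(12, 24))
  expect_equal(names(tab)[1:2], c("id", "Mag_0"))
  expect_equal(ncol(tab), 1 + 15)
  expect_equal(tab$Mag_0[2] / tab$Mag_0[1], 2, tolerance = 1e-9)
})
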