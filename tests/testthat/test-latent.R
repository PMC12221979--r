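fake_records <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(s_m = runif(n), m_l = runif(n),
             surface_area = runif(n, 1, 5), volume = runif(n, 0.1, 2),
             sa_vol = runif(n, 1, 20))
}

test_that("feature correlations match a two-pass Pearson oracle", {
  rec <- fake_records(200)
  set.seed(3)
  z <- matrix(rnorm(200 * 6), 200, 6)
  fc <- feature_correlations(z, rec)
  expect_equal(dim(fc), c(6L, 5L))
  expect_true(all(abs(fc) <= 1))
  for (i in 1:6) for (f in colnames(fc))
    expect_equal(fc[i, f], oracle_pearson(z[, i], rec[[f]]),
                 tolerance = 1e-12)
})

test_that("a feature equal to a latent dimension correlates exactly 1", {
  rec <- fake_records(50)
  z <- matrix(rnorm(50 * 6), 50, 6)
  z[, 3] <- rec$s_m                      # Dim_2 duplicates s_m
  fc <- feature_correlations(z, rec)
  expect_equal(unname(fc["Dim_2", "s_m"]), 1)
})

test_that("independent normal columns stay inside the null band", {
  set.seed(5)
  n <- 1e4
  z <- matrix(rnorm(n * 6), n, 6)
  rec <- fake_records(n, seed = 6)
  fc <- feature_correlations(z, rec)
  expect_lt(max(abs(fc)), 0.05)
})

test_that("correlations are invariant to affine feature rescaling and order", {
  rec <- fake_records(80)
  set.seed(7)
  z <- matrix(rnorm(80 * 6), 80, 6)
  fc1 <- feature_correlations(z, rec)
  rec2 <- rec
  rec2$s_m <- 3 * rec$s_m - 0.4
  rec2$volume <- rec$volume / 7 + 2
  expect_equal(feature_correlations(z, rec2), fc1, tolerance = 1e-12)
  ord <- sample(80)
  expect_equal(feature_correlations(z[ord, ], rec[ord, ]), fc1,
               tolerance = 1e-12)
})

test_that("constant columns are flagged as undefined", {
  rec <- fake_records(30)
  rec$volume <- 1.5
  z <- matrix(rnorm(30 * 6), 30, 6)
  expect_warning(fc <- feature_correlations(z, rec), "volume")
  expect_true(all(is.na(fc[, "volume"])))
  expect_true(all(!is.na(fc[, "s_m"])))
})

test_that("harmonic correlations mirror the feature machinery", {
  set.seed(9)
  z <- matrix(rnorm(60 * 6), 60, 6)
  mags <- as.data.frame(matrix(runif(60 * 8), 60,
                               dimnames = list(NULL, paste0("Mag_", 0:7))))
  hc <- harmonic_correlations(z, mags)
  expect_equal(dim(hc), c(6L, 6L))
  expect_equal(colnames(hc), paste0("Mag_", 0:5))
  expect_equal(hc[2, "Mag_0"], oracle_pearson(z[, 2], mags$Mag_0),
               tolerance = 1e-12)
  # duplicated latent columns give identical matrix rows
  z[, 5] <- z[, 2]
  hc2 <- harmonic_correlations(z, mags)
  expect_equal(hc2[5, ], hc2[2, ], ignore_attr = TRUE)
})

test_that("first_two_dims selects the aspect-correlated dimensions", {
  set.seed(11)
  n <- 300
  rec <- fake_records(n, seed = 12)
  z <- matrix(rnorm(n * 6, sd = 0.05), n, 6)
  z[, 1] <- rec$s_m + rnorm(n, sd = 0.01)
  z[, 2] <- -rec$m_l + rnorm(n, sd = 0.01)
  emb <- project_2d(z, "first_two_dims", records = rec)
  expect_equal(attr(emb, "dims"), c("Dim_0", "Dim_1"))
  expect_equal(emb[, 1], z[, 1], ignore_attr = TRUE)
  expect_error(project_2d(z, "first_two_dims"), "records")
})

test_that("the nonlinear embedding is seed-deterministic and separates blobs", {
  skip_if_not_installed("cluster")
  set.seed(13)
  z <- rbind(matrix(rnorm(60 * 6, mean = 0), ncol = 6),
             matrix(rnorm(60 * 6, mean = 6), ncol = 6))
  lab <- rep(1:2, each = 60)
  e1 <- project_2d(z, "nmds", seed = 5)
  e2 <- project_2d(z, "nmds", seed = 5)
  expect_identical(e1, e2)
  sil <- cluster::silhouette(lab, dist(e1))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("class centroids are means with strict class coverage", {
  z <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  lab <- c("block", "needle", "lath", "plate")
  cents <- class_centroids(z, lab)
  expect_equal(cents["block", ], c(Dim_0 = 1, Dim_1 = 0))
  # duplication leaves centroids unchanged
  expect_equal(class_centroids(rbind(z, z), c(lab, lab)), cents)
  # symmetric pair averages to zero
  z2 <- rbind(z, c(3, 3), c(-3, -3))
  lab2 <- c(lab, "block", "block")
  expect_equal(class_centroids(z2, lab2)["block", ],
               c(Dim_0 = 1 / 3, Dim_1 = 0))
  expect_error(class_centroids(z[1:3, ], lab[1:3]), "plate")
})

test_that("trajectories interpolate linearly between endpoints", {
  cfg <- dae_config(conv_channels = c(4L, 8L), input_side = 16L, seed = 21)
  m <- build_dae(cfg)
  z_a <- rnorm(6); z_b <- rnorm(6)
  tr <- interpolate_trajectory(m, z_a, z_b, n_steps = 2)
  expect_equal(nrow(tr$steps), 2L)
  expect_equal(unname(tr$steps[1, ]), z_a)
  expect_equal(unname(tr$steps[2, ]), z_b)
  tr3 <- interpolate_trajectory(m, z_a, z_b, n_steps = 3)
  expect_equal(unname(tr3$steps[2, ]), (z_a + z_b) / 2)
  expect_length(tr3$decoded, 3L)
  expect_equal(nrow(tr3$aspect_series), 3L)
  expect_error(interpolate_trajectory(m, z_a, z_b, n_steps = 1), "n_steps")
})
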