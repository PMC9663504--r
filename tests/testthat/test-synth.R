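test_that("doublet generation is deterministic and respects the angle model", {
  d1 <- gen_doublets(500, mean_angle = 70, sd_angle = 10, seed = 99)
  d2 <- gen_doublets(500, mean_angle = 70, sd_angle = 10, seed = 99)
  expect_identical(d1, d2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_doublets(d1, f1); write_doublets(d2, f2)
  expect_identical(readBin(f1, "raw", file.info(f1)$size),
                   readBin(f2, "raw", file.info(f2)$size))
  ang <- doublet_angles(d1)
  expect_true(all(ang >= 0 & ang <= 90))
  # doublet length honored
  len <- sqrt(rowSums((as.matrix(d1[, c("ax", "ay", "az")]) -
                         as.matrix(d1[, c("bx", "by", "bz")]))^2))
  expect_equal(len, rep(0.02, 500), tolerance = 1e-12)
  # midpoints inside the cylinder
  mid <- (as.matrix(d1[, c("ax", "ay", "az")]) +
            as.matrix(d1[, c("bx", "by", "bz")])) / 2
  expect_true(all(sqrt(mid[, 1]^2 + mid[, 2]^2) <= 1 + 1e-12))
  expect_true(all(mid[, 3] >= 0 & mid[, 3] <= 10))
  expect_error(gen_doublets(10, sd_angle = 0), "sd_angle")
})

test_that("sampled angles reproduce the truncated-normal moments", {
  # closed form against numerical integration
  expect_equal(truncated_normal_mean(70, 10), oracle_truncnorm_mean(70, 10),
               tolerance = 1e-10)
  expect_equal(truncated_normal_mean(20, 15), oracle_truncnorm_mean(20, 15),
               tolerance = 1e-10)
  d <- gen_doublets(10000, mean_angle = 70, sd_angle = 10, seed = 123)
  expect_lt(abs(mean(doublet_angles(d)) - truncated_normal_mean(70, 10)), 0.5)
  expect_equal(attr(d, "analytic_mean"), truncated_normal_mean(70, 10))
})

test_that("profile volumes carry analytic ground truth beside the raster", {
  g <- gen_profile_volume("constant", base_radius = 1, length = 10,
                          voxel = 0.1)
  expect_equal(g$analytic_volume_mm3, pi * 10, tolerance = 1e-8)
  expect_equal(labeled_volume_quantify(g$volume, 1), g$analytic_volume_mm3,
               tolerance = 0.01)
  # amplitude 0 gaussian bulge is identical to the constant profile
  g0 <- gen_profile_volume("gaussian_bulge", amplitude = 0, voxel = 0.1)
  expect_identical(g0$volume$data, g$volume$data)
  # emitted surface recovers the bump within 2%
  gb <- gen_profile_volume("gaussian_bulge", amplitude = 0.3, width = 2,
                           voxel = 0.2, n_axial = 120, n_angular = 48)
  p <- diameter_profile(gb$surface, n_bins = 25)
  expect_equal(p$radius_mean, gb$r(p$center), tolerance = 0.02)
  # analytic volume of the bulge matches the raster count
  expect_equal(labeled_volume_quantify(
    gen_profile_volume("gaussian_bulge", amplitude = 0.3, voxel = 0.05)$volume,
    1),
    gen_profile_volume("gaussian_bulge", amplitude = 0.3,
                       voxel = 0.05)$analytic_volume_mm3,
    tolerance = 0.01)
  expect_error(gen_profile_volume("gaussian_waist", amplitude = 1.2),
               "non-positive")
  expect_error(gen_profile_volume("linear_taper", amplitude = -1.5),
               "non-positive")
})

test_that("surface pairs come with closed-form expected deviations", {
  pair <- gen_surface_pair("concentric", delta_r = 0.2, n_axial = 40,
                           n_angular = 48)
  dm <- surface_deviation(pair$test, pair$reference, lateral = pair$lateral)
  sagitta <- 1.2 * (1 - cos(pi / 48))
  expect_true(all(abs(dm$distance[pair$lateral] -
                        pair$expected[pair$lateral]) <= 2 * sagitta + 1e-12))
  z <- gen_surface_pair("concentric", delta_r = 0)
  dmz <- surface_deviation(z$test, z$reference, lateral = z$lateral)
  expect_equal(max(dmz$distance[z$lateral]), 0, tolerance = 1e-12)
  pb <- gen_surface_pair("bulge_vs_straight", amplitude = 0.3, width = 2,
                         n_axial = 80, n_angular = 48)
  expect_equal(max(pb$expected, na.rm = TRUE), 0.3, tolerance = 1e-3)
  dmb <- surface_deviation(pb$test, pb$reference, lateral = pb$lateral)
  peak <- which.max(ifelse(pb$lateral, dmb$distance, -Inf))
  expect_equal(dmb$distance[peak], 0.3, tolerance = 0.02)
  expect_equal(pb$test$vertices[peak, 3], 5, tolerance = 0.2)
})
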