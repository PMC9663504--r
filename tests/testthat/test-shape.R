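test_that("diameter profile recovers constant and bulged analytic profiles", {
  cyl <- revolve_surface(function(z) rep(1, length(z)), length = 10,
                         n_axial = 60, n_angular = 32)
  p <- diameter_profile(cyl, n_bins = 20)
  expect_equal(p$radius_mean, rep(1, 20), tolerance = 0.01)
  expect_equal(sum(p$count), attr(p, "n_lateral"))
  # synthetic bulge: recovered bin radii match r(bin center) within 2%
  r_fun <- function(z) 1 + 0.3 * exp(-((z - 5) / 2)^2)
  bulged <- revolve_surface(r_fun, length = 10, n_axial = 100, n_angular = 48)
  pb <- diameter_profile(bulged, n_bins = 25)
  expect_equal(pb$radius_mean, r_fun(pb$center), tolerance = 0.02)
  # all vertices on caps -> error
  disk <- revolve_surface(function(z) rep(1, length(z)), length = 1e-9,
                          n_axial = 2, n_angular = 8)
  expect_error(diameter_profile(disk, n_bins = 5), "lateral")
})

test_that("bulge index separates cylinders, bulges and waists", {
  mk <- function(r_fun) diameter_profile(
    revolve_surface(r_fun, length = 10, n_axial = 80, n_angular = 32),
    n_bins = 20)
  expect_equal(bulge_index(mk(function(z) rep(1, length(z)))), 1,
               tolerance = 0.01)
  bi_bulge <- bulge_index(mk(function(z) 1 + 0.3 * exp(-((z - 5) / 2)^2)))
  expect_gt(bi_bulge, 1)
  expect_equal(bi_bulge, 1.28, tolerance = 0.03)   # ~1.29/1.004 analytic
  expect_lt(bulge_index(mk(function(z) 1 - 0.3 * exp(-((z - 5) / 2)^2))), 1)
  p5 <- diameter_profile(
    revolve_surface(function(z) rep(1, length(z)), 10, 20, 16), n_bins = 5)
  expect_error(bulge_index(p5), "10 bins")
})

test_that("closest-point distances match the region-case oracle exactly", {
  set.seed(7)
  ref <- revolve_surface(function(z) 1 + 0.2 * sin(z), length = 4,
                         n_axial = 10, n_angular = 10)   # 220 triangles
  ref$triangles <- ref$triangles[seq_len(200), ]          # open 200-tri sheet
  pts <- cbind(runif(500, -2, 2), runif(500, -2, 2), runif(500, -1, 5))
  got <- surface_distance(pts, ref)
  want <- oracle_surface_distance(pts, ref)
  expect_lt(max(abs(got$distance - want)), 1e-12)
})

test_that("deviation maps satisfy identity, concentric and rigid-invariance contracts", {
  cyl <- function(r) revolve_surface(function(z) rep(r, length(z)),
                                     length = 10, n_axial = 40,
                                     n_angular = 48)
  s1 <- cyl(1)
  self <- surface_deviation(s1, s1)
  expect_equal(max(self$distance), 0, tolerance = 1e-12)
  # concentric cylinders: lateral deviation = delta R within the chord
  # sagitta of the discretization
  s12 <- cyl(1.2)
  lat <- lateral_vertex_mask(s12)
  dm <- surface_deviation(s12, s1, lateral = lat)
  sagitta <- 1.2 * (1 - cos(pi / 48))
  expect_true(all(abs(dm$distance[lat] - 0.2) <= 2 * sagitta + 1e-12))
  expect_true(all(dm$signed[lat] > 0))    # outside the reference
  # inner vs outer: negative signed deviation
  dm_in <- surface_deviation(s1, s12, lateral = lateral_vertex_mask(s1))
  expect_true(all(dm_in$signed[lateral_vertex_mask(s1)] < 0))
  # one-sided means agree within the documented 20% for comparable surfaces
  expect_lt(abs(dm$summary["mean"] - dm_in$summary["mean"]) /
              dm$summary["mean"], 0.2)
  # rigid transform applied to BOTH surfaces leaves the map unchanged
  Q <- random_rotation(3)
  shift <- c(0.5, -1, 2)
  rig <- function(s) tri_surface(sweep(s$vertices %*% t(Q), 2, shift, `+`),
                                 s$triangles)
  dm2 <- surface_deviation(rig(s12), rig(s1), lateral = lat)
  expect_equal(dm2$distance, dm$distance, tolerance = 1e-9)
  expect_error(surface_deviation(s1, tri_surface(s1$vertices,
                                                 matrix(0L, 0, 3))),
               "empty|range")
})

test_that("labeled volumes quantify label counts times voxel volume", {
  arr <- array(0L, c(4, 4, 4))
  vol0 <- labeled_volume(arr, 0.5)
  expect_equal(labeled_volume_quantify(vol0, 1), 0)
  arr[1:2, 1, 1] <- 1L; arr[3, 3, 3] <- 2L
  vol <- labeled_volume(arr, 0.5)
  expect_equal(labeled_volume_quantify(vol, 1), 2 * 0.125)
  expect_equal(labeled_volume_quantify(vol, "bone"), 0.125)
  expect_error(labeled_volume_quantify(vol, 7), "not declared")
  expect_error(labeled_volume(array(5L, c(2, 2, 2)), 1), "undeclared")
  # rasterized cylinder volume converges to the analytic value
  g1 <- gen_profile_volume("constant", voxel = 0.1)
  g2 <- gen_profile_volume("constant", voxel = 0.02)
  e1 <- abs(labeled_volume_quantify(g1$volume, 1) - pi * 10)
  e2 <- abs(labeled_volume_quantify(g2$volume, 1) - pi * 10)
  expect_lt(e2, e1)
  expect_lt(e1 / (pi * 10), 0.01)
})

test_that("rigid pre-alignment recovers a displaced surface's frame", {
  ref <- revolve_surface(function(z) rep(1, length(z)), length = 10,
                         n_axial = 30, n_angular = 24)
  Q <- random_rotation(9)
  moved <- tri_surface(sweep(ref$vertices %*% t(Q), 2, c(3, -2, 7), `+`),
                       ref$triangles)
  dm_raw <- surface_deviation(moved, ref)
  expect_gt(dm_raw$summary["mean"], 1)         # frames differ badly
  dm <- surface_deviation(moved, ref, pre_align = TRUE)
  expect_lt(dm$summary["max"], 0.05)           # recovered up to symmetry
})
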