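test_that("cylinder_spec and region_partition validate their fields", {
  expect_error(cylinder_spec(length_mm = -1), "length_mm")
  expect_error(cylinder_spec(radius_mm = 0), "radius_mm")
  expect_error(cylinder_spec(n_axial = 1), "n_axial")
  expect_error(cylinder_spec(n_angular = 7), "even")
  expect_error(region_partition(c(0, 0.5, 0.4, 1)), "increasing")
  expect_error(region_partition(c(0.1, 1)), "start at 0")
  expect_equal(region_partition(c(0, 0.5, 1))$n_regions, 2L)
})

test_that("structured cylinder mesh is valid, watertight and volume-consistent", {
  m <- small_mesh(8, 2, 8)
  vol <- tet_volumes(m)
  expect_true(all(vol > 0))
  expect_true(bulkybone:::is_watertight(mesh_surface(m)))
  expect_equal(enclosed_volume(mesh_surface(m)), sum(vol),
               tolerance = 1e-9)
  expect_equal(range(m$vertices[, 3]), c(0, 10))
  # surface vertices lie on the lateral wall or an end cap
  sv <- unique(as.vector(m$surface_tris))
  r <- sqrt(m$vertices[sv, 1]^2 + m$vertices[sv, 2]^2)
  z <- m$vertices[sv, 3]
  expect_true(all(abs(r - 1) < 1e-9 | abs(z) < 1e-9 | abs(z - 10) < 1e-9))
  # smallest legal mesh
  m0 <- build_cylinder_mesh(cylinder_spec(1, 1, 2, 1, 6))
  expect_true(all(tet_volumes(m0) > 0))
  expect_true(bulkybone:::is_watertight(mesh_surface(m0)))
})

test_that("mesh volume is inscribed and converges to the analytic cylinder", {
  # the discretized cross-section is the inscribed polygon: volume deficit
  # is 1 - sin(x)/x with x = 2*pi/n_angular, independent of the other
  # resolutions
  m <- build_cylinder_mesh(cylinder_spec(10, 1, 40, 8, 16))
  v <- sum(tet_volumes(m))
  expect_lt(v, pi * 10)
  x <- 2 * pi / 16
  expect_equal(v / (pi * 10), sin(x) / x, tolerance = 1e-12)
  # within 1% of analytic once n_angular >= 32
  m32 <- build_cylinder_mesh(cylinder_spec(10, 1, 10, 4, 32))
  expect_equal(sum(tet_volumes(m32)), pi * 10, tolerance = 0.01)
  # refining n_angular strictly decreases the volume error
  errs <- vapply(c(16, 32, 64), function(na) {
    abs(sum(tet_volumes(build_cylinder_mesh(
      cylinder_spec(10, 1, 6, 3, na)))) - pi * 10)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("generated vertex set is mirror-symmetric about both axial planes", {
  m <- small_mesh(4, 2, 10)
  key <- function(v) sort(paste(round(v[, 1], 12), round(v[, 2], 12),
                                round(v[, 3], 12)))
  expect_identical(key(m$vertices),
                   key(cbind(-m$vertices[, 1], m$vertices[, 2:3])))
  expect_identical(key(m$vertices),
                   key(cbind(m$vertices[, 1], -m$vertices[, 2],
                             m$vertices[, 3])))
})

test_that("axial region assignment follows tet centroids", {
  m <- small_mesh(10, 2, 8)
  m2 <- assign_axial_regions(m, region_partition(c(0, 0.5, 1)))
  zc <- (m$vertices[m$tets[, 1], 3] + m$vertices[m$tets[, 2], 3] +
           m$vertices[m$tets[, 3], 3] + m$vertices[m$tets[, 4], 3]) / 4
  expect_identical(m2$region, ifelse(zc < 5, 1L, 2L))
  # single region
  m1 <- assign_axial_regions(m, region_partition(c(0, 1)))
  expect_true(all(m1$region == 1L))
  # default 5-region partition: element counts proportional to slab
  # thickness (layers align with boundaries at n_axial = 40)
  m40 <- assign_axial_regions(small_mesh(40, 2, 8), region_partition())
  counts <- tabulate(m40$region, 5)
  expect_equal(counts / sum(counts), c(0.15, 0.2, 0.3, 0.2, 0.15),
               tolerance = 0.1)
  # empty region triggers a warning naming it
  expect_warning(
    assign_axial_regions(small_mesh(2, 1, 6),
                         region_partition(c(0, 0.45, 0.55, 1))),
    "empty region")
})

test_that("mesh_quality reports and flags inverted elements", {
  m <- small_mesh(4, 1, 6)
  q <- mesh_quality(m)
  expect_gt(q$min_volume, 0)
  expect_identical(q$n_tets, nrow(m$tets))
  # perturb one vertex far enough to invert an element
  bad <- m
  k <- bad$tets[1, 1]
  bad$vertices[k, ] <- colMeans(bad$vertices[bad$tets[1, 2:4], ]) +
    10 * (colMeans(bad$vertices[bad$tets[1, 2:4], ]) - bad$vertices[k, ])
  expect_error(mesh_quality(bad), "inverted")
})

test_that("enclosed_volume obeys orientation and watertightness contracts", {
  # unit cube, outward-oriented
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  tr <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  cube <- tri_surface(v, tr)
  expect_equal(enclosed_volume(cube), 1, tolerance = 1e-12)
  flipped <- tri_surface(v, tr[, c(1, 3, 2)])
  expect_equal(enclosed_volume(flipped), -1, tolerance = 1e-12)
  open_box <- tri_surface(v, tr[-1, ])
  expect_error(enclosed_volume(open_box), "watertight")
})
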