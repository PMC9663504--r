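test_that("deform advects vertices and preserves connectivity", {
  m <- small_mesh(6, 2, 8)
  u0 <- matrix(0, nrow(m$vertices), 3)
  expect_identical(deform(m, u0, scale = 0)$vertices, m$vertices)
  # rigid translation: volume unchanged to machine precision
  ut <- matrix(rep(c(0.3, -0.2, 1.4), each = nrow(m$vertices)), ncol = 3)
  md <- deform(m, ut)
  expect_equal(sum(tet_volumes(md)), sum(tet_volumes(m)), tolerance = 1e-12)
  expect_identical(md$tets, m$tets)
  # uniform radial field of 0.1 on an R = 1 cylinder: wall radius 1.1
  rdir <- bulkybone:::radial_directions(m$vertices, m$axis, m$origin)
  r <- sqrt(m$vertices[, 1]^2 + m$vertices[, 2]^2)
  mr <- deform(m, 0.1 * rdir * (r / ifelse(r > 0, r, 1)))
  wall <- which(abs(r - 1) < 1e-9)
  expect_equal(sqrt(rowSums(mr$vertices[wall, 1:2]^2)), rep(1.1, length(wall)),
               tolerance = 1e-12)
  # inversion warning
  big <- matrix(rnorm(length(m$vertices), sd = 2), ncol = 3)
  expect_warning(deform(m, big), "inverted")
})

test_that("one growth step equals solve + deform exactly", {
  m <- small_mesh(8, 2, 8)
  sc <- make_scenario("regeneration", f_axial0 = 0.005, f_radial0 = 0.05)
  sim <- simulate_growth(m, sc, n_steps = 1, load_scale = 1)
  m_reg <- assign_axial_regions(m, sc$partition)
  K <- assemble_stiffness(m_reg, sc$material)
  f <- assemble_body_load(m_reg, sc$loads)
  u <- solve_static(K, f, default_constraints(m_reg))
  expect_identical(sim$mesh$vertices, deform(m_reg, u)$vertices)
  expect_identical(sim$displacement$u, u$u)
})

test_that("incremental growth under uniform radial load inflates the mid-shaft monotonically", {
  m <- small_mesh(8, 2, 8)
  sc <- make_scenario("regeneration", f_axial0 = 0, f_radial0 = 1)
  sim <- simulate_growth(m, sc, n_steps = 3, step_scale = 0.25)
  lat <- lateral_vertex_mask(m)
  mid_radius <- function(mesh) {
    v <- mesh$vertices
    sel <- lat & abs(v[, 3] - 5) < 2
    mean(sqrt(v[sel, 1]^2 + v[sel, 2]^2))
  }
  radii <- vapply(sim$snapshots, mid_radius, numeric(1))
  expect_true(all(diff(c(mid_radius(sim$mesh0), radii)) > 0))
  # small steps track the single-step linear prediction
  lin <- simulate_growth(m, sc, n_steps = 1, load_scale = sim$load_scale,
                         step_scale = 0.25)
  expect_equal(mid_radius(lin$mesh), radii[1], tolerance = 1e-12)
  expect_equal(radii[1] - mid_radius(sim$mesh0),
               (radii[2] - radii[1]), tolerance = 0.05)
  # excessive advection aborts naming the step
  expect_error(
    suppressWarnings(simulate_growth(m, sc, n_steps = 2, load_scale = 60)),
    "step")
})

test_that("normalization scales the first-step maximum displacement to 0.2 R", {
  m <- small_mesh(16, 2, 8)
  sc <- make_scenario("regeneration", f_axial0 = 0.1, f_radial0 = 1)
  sim <- simulate_growth(m, sc)
  expect_equal(max(sqrt(rowSums(sim$displacement$u^2))), 0.2,
               tolerance = 1e-9)
  s <- summary(sim, n_bins = 12)
  expect_s3_class(s, "summary.bone_growth")
  expect_gt(s$volume_final, s$volume_initial)
})

test_that("matched-impulse contrast: regeneration grows bulkier than development", {
  m <- small_mesh(24, 4, 12)
  part <- region_partition()
  reg <- make_scenario("regeneration")
  dev <- match_radial_impulse(make_scenario("development"), reg,
                              assign_axial_regions(m, part))
  sim_r <- simulate_growth(m, reg)
  sim_d <- simulate_growth(m, dev, load_scale = sim_r$load_scale)
  lat <- lateral_vertex_mask(m)
  bi_r <- bulge_index(diameter_profile(mesh_surface(sim_r$mesh),
                                       n_bins = 16, lateral = lat))
  bi_d <- bulge_index(diameter_profile(mesh_surface(sim_d$mesh),
                                       n_bins = 16, lateral = lat))
  expect_gt(bi_r, bi_d)
  # the regenerate sits outside the development shape mid-shaft: positive
  # signed deviation band localized centrally
  dm <- surface_deviation(mesh_surface(sim_r$mesh), mesh_surface(sim_d$mesh),
                          lateral = lat)
  z <- sim_r$mesh$vertices[, 3]
  zr <- range(z[lat])
  frac <- (z - zr[1]) / diff(zr)
  central <- dm$lateral & frac > 0.3 & frac < 0.7
  expect_gt(mean(dm$signed[central]), 0)
  expect_gt(max(dm$signed[central], na.rm = TRUE),
            max(dm$signed[dm$lateral & !central], na.rm = TRUE))
})
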