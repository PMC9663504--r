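test_that("element stiffness matches the independent B-matrix oracle", {
  ref <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  K <- element_stiffness(ref, material(1, 0.3))
  expect_lt(max(abs(K - oracle_element_stiffness(ref, 1, 0.3))), 1e-12)
  # a few skewed tets, different materials
  set.seed(42)
  for (i in 1:5) {
    co <- matrix(rnorm(12), 4, 3)
    if (det(cbind(co[2, ] - co[1, ], co[3, ] - co[1, ],
                  co[4, ] - co[1, ])) < 0) co <- co[c(1, 2, 4, 3), ]
    E <- runif(1, 0.5, 5); nu <- runif(1, 0.1, 0.45)
    K <- element_stiffness(co, material(E, nu))
    expect_lt(max(abs(K - oracle_element_stiffness(co, E, nu))),
              1e-10 * max(abs(K)))
    expect_lt(max(abs(K - t(K))), 1e-12 * max(abs(K)))
    # rigid-body nullspace: 3 translations + 3 infinitesimal rotations
    for (d in 1:3) {
      tr <- rep(diag(3)[d, ], 4)
      expect_lt(max(abs(K %*% tr)), 1e-10 * max(abs(K)))
    }
    W <- list(matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 0), 3, byrow = TRUE),
              matrix(c(0, 0, 1, 0, 0, 0, -1, 0, 0), 3, byrow = TRUE),
              matrix(c(0, 0, 0, 0, 0, -1, 0, 1, 0), 3, byrow = TRUE))
    for (w in W) {
      rot <- as.vector(t(co %*% t(w)))
      expect_lt(max(abs(K %*% rot)), 1e-9 * max(abs(K)))
    }
  }
  expect_error(element_stiffness(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                       c(3, 0, 0)), material()),
               "degenerate")
})

test_that("global assembly equals a brute-force scatter of element matrices", {
  m <- small_mesh(2, 1, 6)
  mat <- material(2, 0.25)
  K <- assemble_stiffness(m, mat)
  ndof <- 3 * nrow(m$vertices)
  Kb <- matrix(0, ndof, ndof)
  for (e in seq_len(nrow(m$tets))) {
    t4 <- m$tets[e, ]
    Ke <- element_stiffness(m$vertices[t4, ], mat)
    dof <- as.vector(t(outer(t4, 1:3, function(a, i) 3 * (a - 1) + i)))
    Kb[dof, dof] <- Kb[dof, dof] + Ke
  }
  expect_lt(max(abs(as.matrix(K) - Kb)), 1e-12 * max(abs(Kb)))
  expect_lt(max(abs(K - Matrix::t(K))), 1e-12 * max(abs(Kb)))
  trans <- rep(c(1, 0, 0), nrow(m$vertices))
  expect_lt(max(abs(K %*% trans)), 1e-10 * max(abs(Kb)))
})

test_that("body loads integrate consistently and cover all regions", {
  m <- assign_axial_regions(small_mesh(10, 2, 8), region_partition())
  expect_identical(assemble_body_load(m, region_loading(rep(0, 5), rep(0, 5))),
                   rep(0, 3 * nrow(m$vertices)))
  # axial resultant identity
  f <- assemble_body_load(m, region_loading(rep(0.1, 5), rep(0, 5)))
  expect_equal(sum(f[seq(3, length(f), 3)]), 0.1 * sum(tet_volumes(m)),
               tolerance = 1e-9)
  expect_equal(sum(abs(f[-seq(3, length(f), 3)])), 0)
  # missing region
  m2 <- assign_axial_regions(m, region_partition(c(0, 0.5, 1)))
  expect_error(assemble_body_load(m2, region_loading(1, 1)), "region")
  # exact lateral cancellation on a mesh whose TET decomposition is
  # mirror-symmetric (two reflected tets sharing a face)
  v <- rbind(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 0.3, 0.3),
             c(-1, 0.3, 0.3))
  tets <- rbind(c(1, 2, 3, 4), c(1, 3, 2, 5))
  sym <- structure(list(vertices = v, tets = tets,
                        surface_tris = bulkybone:::extract_surface(v, tets),
                        region = c(1L, 1L), axis = c(0, 0, 1),
                        origin = c(0, 0, 0), spec = NULL),
                   class = "tet_mesh")
  fr <- assemble_body_load(sym, region_loading(0, 1))
  expect_lt(abs(sum(fr[seq(1, length(fr), 3)])), 1e-12 * sum(abs(fr)))
})

test_that("surface tractions integrate to traction times selected area", {
  m <- small_mesh(6, 2, 12)
  sigma <- 0.01
  f <- assemble_surface_traction(
    m, function(cen) abs(cen[, 3] - 10) < 1e-9, c(0, 0, sigma))
  # discretized (inscribed-polygon) cap area
  area <- 12 / 2 * sin(2 * pi / 12)
  expect_equal(sum(f[seq(3, length(f), 3)]), sigma * area, tolerance = 1e-9)
  expect_identical(assemble_surface_traction(m, 1:4, c(0, 0, 0)),
                   rep(0, 3 * nrow(m$vertices)))
  # equal-and-opposite tractions on the two caps: total resultant cancels
  fb <- assemble_surface_traction(
    m, function(cen) abs(cen[, 3] - 10) < 1e-9, c(0, 0, sigma)) +
    assemble_surface_traction(
      m, function(cen) abs(cen[, 3]) < 1e-9, c(0, 0, -sigma))
  res <- colSums(matrix(fb, ncol = 3, byrow = TRUE))
  expect_lt(max(abs(res)), 1e-12)
  expect_error(assemble_surface_traction(m, integer(0), c(1, 0, 0)), "empty")
})

test_that("solve_static satisfies linearity, superposition and reciprocity", {
  m <- small_mesh(8, 2, 8)
  mat <- material()
  K <- assemble_stiffness(m, mat)
  cs <- default_constraints(m)
  zmax <- max(m$vertices[, 3])
  f1 <- assemble_surface_traction(
    m, function(cen) abs(cen[, 3] - zmax) < 1e-9, c(0, 0, 0.01))
  m_reg <- assign_axial_regions(m, region_partition())
  f2 <- assemble_body_load(m_reg, region_loading(rep(0.02, 5), rep(0.3, 5)))
  u0 <- solve_static(K, numeric(length(f1)), cs)
  expect_equal(max(abs(u0$u)), 0)
  u1 <- solve_static(K, f1, cs)
  u2 <- solve_static(K, f2, cs)
  u12 <- solve_static(K, f1 + f2, cs)
  scale2 <- solve_static(K, 2 * f1, cs)
  expect_equal(scale2$u, 2 * u1$u, tolerance = 1e-9)
  expect_equal(u12$u, u1$u + u2$u, tolerance = 1e-9)
  # Betti reciprocity
  expect_equal(sum(as.vector(t(u2$u)) * f1), sum(as.vector(t(u1$u)) * f2),
               tolerance = 1e-9)
  expect_lt(u1$residual, 1e-8)
  # missing constraints -> not positive definite
  expect_error(solve_static(K, f1, constraint_set(1L, 3L, 0)),
               "rigid-body")
})

test_that("constrained stiffness is symmetric positive definite", {
  m <- small_mesh(3, 1, 6)
  K <- assemble_stiffness(m, material())
  cs <- default_constraints(m)
  free <- setdiff(seq_len(3 * nrow(m$vertices)), cs$dofs)
  Kff <- as.matrix(K[free, free])
  ev <- eigen(Kff, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 1e-10 * sum(diag(Kff)) / nrow(Kff))
})

test_that("solution is invariant under rigid translation of mesh and loads", {
  m <- small_mesh(6, 2, 8)
  mat <- material()
  cs <- default_constraints(m)
  zmax <- max(m$vertices[, 3])
  sel <- function(cen) abs(cen[, 3] - max(cen[, 3])) < 1e-9
  u1 <- solve_static(assemble_stiffness(m, mat),
                     assemble_surface_traction(m, sel, c(0, 0, 0.01)), cs)
  m2 <- m
  m2$vertices[, 3] <- m2$vertices[, 3] + 5   # translate along the axis
  u2 <- solve_static(assemble_stiffness(m2, mat),
                     assemble_surface_traction(m2, sel, c(0, 0, 0.01)),
                     default_constraints(m2))
  expect_equal(u1$u, u2$u, tolerance = 1e-9)
})

test_that("uniaxial patch test reproduces the closed-form solution", {
  r <- uniaxial_patch_test(small_mesh(10, 3, 12), material(1, 0.4), 0.01)
  expect_lt(r$tip_rel_err, 0.02)
  expect_lt(r$lateral_rel_err, 0.02)
  # linear exact solution: P1 reproduces it to solver precision
  expect_lt(r$tip_rel_err, 1e-9)
})

test_that("material validates Poisson ratio and derives Lame parameters", {
  mat <- material(2, 0.25)
  expect_equal(mat$mu, 2 / (2 * 1.25))
  expect_equal(mat$lambda, 2 * 0.25 / (1.25 * 0.5))
  expect_error(material(-1), "young_modulus")
  expect_error(material(1, 0.5), "poisson_ratio")
  expect_warning(material(1, 0.495), "lock")
})
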