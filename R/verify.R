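#' Uniaxial patch test against the closed-form elasticity solution
#'
#' A cylinder on a rolling base (u_z = 0 at z = 0, minimal lateral pins) is
#' loaded with a uniform axial traction sigma on the distal cap. The exact
#' solution is the homogeneous uniaxial stress state with linear
#' displacements u = (-nu sigma x/E, -nu sigma y/E, sigma z/E); mean tip
#' axial displacement sigma L / E and mean lateral radial displacement
#' -nu sigma R / E. Because the exact field is linear, P1 elements reproduce
#' it to solver precision (a patch test) at any resolution.
#'
#' @param mesh A `tet_mesh` cylinder (axis +z, base at z = 0).
#' @param mat A [material()].
#' @param sigma_frac Traction as a fraction of E (default 0.01).
#' @return List with measured and analytic tip/lateral displacements and
#'   their relative errors.
#' @export
uniaxial_patch_test <- function(mesh = NULL, mat = material(),
                                sigma_frac = 0.01) {
  if (is.null(mesh)) mesh <- build_cylinder_mesh(cylinder_spec())
  E <- mat$young_modulus; nu <- mat$poisson_ratio
  sigma <- sigma_frac * E
  L <- diff(range(mesh$vertices[, 3L]))
  R <- max(sqrt(mesh$vertices[, 1L]^2 + mesh$vertices[, 2L]^2))
  zmax <- max(mesh$vertices[, 3L])
  K <- assemble_stiffness(mesh, mat)
  f <- assemble_surface_traction(
    mesh, function(cen) abs(cen[, 3L] - zmax) < 1e-9, c(0, 0, sigma))
  u <- solve_static(K, f, default_constraints(mesh))
  tip <- which(abs(mesh$vertices[, 3L] - zmax) < 1e-9)
  mean_tip_uz <- mean(u$u[tip, 3L])
  lat <- which(lateral_vertex_mask(mesh) &
                 abs(sqrt(mesh$vertices[, 1L]^2 + mesh$vertices[, 2L]^2) - R) < 1e-9)
  rdir <- radial_directions(mesh$vertices[lat, , drop = FALSE],
                            mesh$axis, mesh$origin)
  mean_lat_ur <- mean(rowSums(u$u[lat, , drop = FALSE] * rdir))
  tip_exact <- sigma * L / E
  lat_exact <- -nu * sigma * R / E
  list(mean_tip_uz = mean_tip_uz, tip_exact = tip_exact,
       tip_rel_err = abs(mean_tip_uz - tip_exact) / abs(tip_exact),
       mean_lateral_ur = mean_lat_ur, lateral_exact = lat_exact,
       lateral_rel_err = abs(mean_lat_ur - lat_exact) / abs(lat_exact),
       displacement = u)
}

#' Uniaxial body-force verification with a quadratic exact solution
#'
#' A cylinder under a uniform axial force density f (the growth-model load
#' type) held at its base by the exact displacement field. The closed-form
#' solution of the corresponding stress state sigma_zz = f (L - z) is
#' quadratic, \deqn{u = (-\nu f (L - z) x / E, -\nu f (L - z) y / E,
#' f (L z - z^2/2)/E - \nu f (x^2 + y^2)/(2E)),} so linear tetrahedra have a
#' genuine O(h^2) discretization error; the RMS tip-displacement error
#' decreases monotonically under uniform refinement. The base (z = 0) is
#' prescribed with the exact solution values.
#'
#' @param mesh A `tet_mesh` cylinder.
#' @param mat A [material()].
#' @param f Axial force density (kPa/mm).
#' @return List with `rms_tip_err` (mm), `max_err`, `mean_tip_uz`, and the
#'   analytic mean for reference.
#' @export
uniaxial_bodyforce_case <- function(mesh, mat = material(), f = 0.01) {
  E <- mat$young_modulus; nu <- mat$poisson_ratio
  v <- mesh$vertices
  L <- diff(range(v[, 3L]))
  exact <- function(p) {
    r2 <- p[, 1L]^2 + p[, 2L]^2
    cbind(-nu * f * (L - p[, 3L]) * p[, 1L] / E,
          -nu * f * (L - p[, 3L]) * p[, 2L] / E,
          f * (L * p[, 3L] - p[, 3L]^2 / 2) / E - nu * f * r2 / (2 * E))
  }
  base <- which(abs(v[, 3L] - min(v[, 3L])) < 1e-9)
  ub <- exact(v[base, , drop = FALSE])
  cs <- constraint_set(rep(base, 3L), rep(1:3, each = length(base)),
                       as.vector(ub))
  K <- assemble_stiffness(mesh, mat)
  load <- assemble_body_load(
    assign_axial_regions(mesh, region_partition(c(0, 1))),
    region_loading(f_axial = f, f_radial = 0))
  u <- solve_static(K, load, cs)
  tip <- which(abs(v[, 3L] - max(v[, 3L])) < 1e-9)
  err <- u$u - exact(v)
  list(rms_tip_err = sqrt(mean(err[tip, 3L]^2)),
       max_err = max(abs(err)),
       mean_tip_uz = mean(u$u[tip, 3L]),
       mean_tip_exact = mean(exact(v[tip, , drop = FALSE])[, 3L]))
}

#' Mesh-convergence study for the uniaxial body-force verification
#'
#' Runs [uniaxial_bodyforce_case()] on a sequence of uniformly refined
#' cylinder meshes and reports the RMS tip-displacement errors, which must
#' decrease monotonically for a convergent discretization.
#'
#' @param specs List of [cylinder_spec()]s, coarse to fine.
#' @param mat A [material()].
#' @param f Axial force density.
#' @return Numeric vector of RMS tip errors, one per level.
#' @export
uniaxial_convergence <- function(specs = list(
                                   cylinder_spec(10, 1, 8, 2, 8),
                                   cylinder_spec(10, 1, 16, 4, 16),
                                   cylinder_spec(10, 1, 32, 8, 32)),
                                 mat = material(), f = 0.01) {
  vapply(specs, function(sp) {
    uniaxial_bodyforce_case(build_cylinder_mesh(sp), mat, f)$rms_tip_err
  }, numeric(1))
}
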