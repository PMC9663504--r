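#' Isotropic linear-elastic material
#'
#' Small-strain, homogeneous, isotropic Hooke's law parameterized by Young's
#' modulus and Poisson's ratio. Growing cartilage is soft; the default
#' E = 1 kPa, nu = 0.40 is a documented stand-in for nearly incompressible
#' soft tissue. Because the elasticity problem is linear, E only scales the
#' displacement magnitude and cancels from all shape ratios.
#'
#' @param young_modulus E (kPa), positive.
#' @param poisson_ratio nu, in (-1, 0.5); a warning is issued for nu >= 0.49
#'   (volumetric locking of linear tetrahedra).
#' @return Object of class `material` with Lam\'e parameters `lambda`, `mu`.
#' @export
material <- function(young_modulus = 1, poisson_ratio = 0.40) {
  check_positive_scalar(young_modulus, "young_modulus")
  if (!is.numeric(poisson_ratio) || length(poisson_ratio) != 1L ||
      poisson_ratio <= -1 || poisson_ratio >= 0.5)
    stop("'poisson_ratio' must lie in (-1, 0.5): got ",
         format(poisson_ratio), call. = FALSE)
  if (poisson_ratio >= 0.49)
    warning("poisson_ratio >= 0.49: linear tetrahedra lock volumetrically; ",
            "results will be overstiff", call. = FALSE)
  E <- young_modulus; nu <- poisson_ratio
  structure(list(young_modulus = E, poisson_ratio = nu,
                 lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
                 mu = E / (2 * (1 + nu))),
            class = "material")
}

# shape-function gradients of a P1 tetrahedron: 4 x 3 matrix (rows g_a),
# plus the signed volume. Closed form via cross products.
tet_gradients <- function(coords) {
  e2 <- coords[2L, ] - coords[1L, ]
  e3 <- coords[3L, ] - coords[1L, ]
  e4 <- coords[4L, ] - coords[1L, ]
  c34 <- c(e3[2L] * e4[3L] - e3[3L] * e4[2L],
           e3[3L] * e4[1L] - e3[1L] * e4[3L],
           e3[1L] * e4[2L] - e3[2L] * e4[1L])
  d <- sum(e2 * c34)                   # 6 * signed volume
  if (d <= 0) stop("degenerate or inverted tetrahedron (volume <= 0)",
                   call. = FALSE)
  c42 <- c(e4[2L] * e2[3L] - e4[3L] * e2[2L],
           e4[3L] * e2[1L] - e4[1L] * e2[3L],
           e4[1L] * e2[2L] - e4[2L] * e2[1L])
  c23 <- c(e2[2L] * e3[3L] - e2[3L] * e3[2L],
           e2[3L] * e3[1L] - e2[1L] * e3[3L],
           e2[1L] * e3[2L] - e2[2L] * e3[1L])
  g <- rbind(-(c34 + c42 + c23), c34, c42, c23) / d
  list(g = g, volume = d / 6)
}

#' Element stiffness matrix of a linear tetrahedron
#'
#' 12 x 12 stiffness of a 4-node (P1) tetrahedral element with isotropic
#' Hooke's law, degrees of freedom ordered vertex-major (v1x v1y v1z v2x ...).
#' Uses the closed form \eqn{K_{(a,i),(b,j)} = V(\lambda g_{a,i} g_{b,j} +
#' \mu g_{a,j} g_{b,i} + \mu \delta_{ij} g_a\cdot g_b)} in the constant
#' shape-function gradients \eqn{g_a}.
#'
#' @param tet_coords 4 x 3 matrix of vertex coordinates (mm), positively
#'   oriented.
#' @param mat A [material()].
#' @return 12 x 12 symmetric positive semi-definite matrix with a
#'   6-dimensional rigid-body nullspace.
#' @export
element_stiffness <- function(tet_coords, mat) {
  stopifnot(inherits(mat, "material"))
  gv <- tet_gradients(as.matrix(tet_coords))
  g <- gv$g; V <- gv$volume
  lam <- mat$lambda; mu <- mat$mu
  K <- matrix(0, 12L, 12L)
  dot <- g %*% t(g)
  for (a in 1:4) for (b in 1:4) {
    blk <- lam * (g[a, ] %o% g[b, ]) + mu * (g[b, ] %o% g[a, ]) +
      mu * dot[a, b] * diag(3)
    K[(3 * a - 2):(3 * a), (3 * b - 2):(3 * b)] <- V * blk
  }
  K
}

# vectorized per-element gradients for a whole mesh:
# list(g = list of four m x 3 matrices, volume = length-m vector)
mesh_gradients <- function(mesh) {
  v <- mesh$vertices; t4 <- mesh$tets
  e2 <- v[t4[, 2L], , drop = FALSE] - v[t4[, 1L], , drop = FALSE]
  e3 <- v[t4[, 3L], , drop = FALSE] - v[t4[, 1L], , drop = FALSE]
  e4 <- v[t4[, 4L], , drop = FALSE] - v[t4[, 1L], , drop = FALSE]
  c34 <- cross_rows(e3, e4)
  c42 <- cross_rows(e4, e2)
  c23 <- cross_rows(e2, e3)
  d <- rowSums(e2 * c34)
  bad <- which(d <= 0)
  if (length(bad))
    stop("degenerate or inverted tetrahedra at indices: ",
         paste(utils::head(bad, 20L), collapse = ", "), call. = FALSE)
  g2 <- c34 / d; g3 <- c42 / d; g4 <- c23 / d
  list(g = list(-(g2 + g3 + g4), g2, g3, g4), volume = d / 6)
}

#' Assemble the global stiffness matrix
#'
#' Scatters all element stiffness contributions into a sparse symmetric
#' matrix of dimension `3 * n_vertices`. Before constraints are applied the
#' matrix is positive semi-definite with exactly six rigid-body zero modes.
#'
#' @param mesh A `tet_mesh`.
#' @param mat A [material()].
#' @return A `dgCMatrix` sparse stiffness (kPa mm).
#' @export
assemble_stiffness <- function(mesh, mat) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(mat, "material"))
  mg <- mesh_gradients(mesh)
  g <- mg$g; V <- mg$volume
  t4 <- mesh$tets
  m <- nrow(t4)
  lam <- mat$lambda; mu <- mat$mu
  dof <- lapply(1:4, function(a) 3L * (t4[, a] - 1L))
  blocks <- 144L
  ii <- integer(blocks * m); jj <- integer(blocks * m); xx <- numeric(blocks * m)
  pos <- 0L
  for (a in 1:4) for (b in 1:4) {
    dot_ab <- rowSums(g[[a]] * g[[b]])
    for (i in 1:3) for (j in 1:3) {
      val <- lam * g[[a]][, i] * g[[b]][, j] + mu * g[[a]][, j] * g[[b]][, i]
      if (i == j) val <- val + mu * dot_ab
      idx <- pos + seq_len(m)
      ii[idx] <- dof[[a]] + i
      jj[idx] <- dof[[b]] + j
      xx[idx] <- V * val
      pos <- pos + m
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(3L * nrow(mesh$vertices),
                                3L * nrow(mesh$vertices)))
}

#' Region-wise growth loading
#'
#' Per-region force densities modelling the push of dividing cells: an axial
#' component along the bone axis and a radial component pointing away from
#' it. Units are force per unit volume (kPa/mm).
#'
#' @param f_axial Numeric vector, axial force density per region.
#' @param f_radial Numeric vector, radial force density per region (positive
#'   = outward).
#' @return Object of class `region_loading`.
#' @export
region_loading <- function(f_axial, f_radial) {
  if (length(f_axial) != length(f_radial))
    stop("f_axial and f_radial must have one entry per region", call. = FALSE)
  if (!length(f_axial)) stop("empty loading", call. = FALSE)
  structure(list(f_axial = as.numeric(f_axial),
                 f_radial = as.numeric(f_radial),
                 n_regions = length(f_axial)),
            class = "region_loading")
}

# unit radial directions (perpendicular to axis) at points; zero on the axis
radial_directions <- function(points, axis, origin, tol = 1e-12) {
  axis <- unit_vector(axis)
  rel <- sweep(points, 2L, origin)
  ax_comp <- drop(rel %*% axis)
  rad <- rel - outer(ax_comp, axis)
  nr <- sqrt(rowSums(rad * rad))
  on_axis <- nr < tol
  nr[on_axis] <- 1
  rad <- rad / nr
  rad[on_axis, ] <- 0
  rad
}

#' Assemble the body-force load vector for region-wise growth forces
#'
#' Consistent P1 integration with the force density evaluated at each
#' element centroid: every tetrahedron distributes `f * V_tet` equally to its
#' four vertices. The radial direction at a point is the unit vector from the
#' bone axis to the point (zero on the axis itself).
#'
#' @param mesh A `tet_mesh` with regions assigned.
#' @param loading A [region_loading()] covering every region label present in
#'   the mesh.
#' @return Numeric load vector of length `3 * n_vertices` (kPa mm^2).
#' @export
assemble_body_load <- function(mesh, loading) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(loading, "region_loading"))
  regions <- sort(unique(mesh$region))
  missing <- regions[regions > loading$n_regions | regions < 1L]
  if (length(missing))
    stop("loading does not cover mesh region(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  v <- mesh$vertices; t4 <- mesh$tets
  cen <- (v[t4[, 1L], , drop = FALSE] + v[t4[, 2L], , drop = FALSE] +
            v[t4[, 3L], , drop = FALSE] + v[t4[, 4L], , drop = FALSE]) / 4
  vol <- tet_volumes(mesh)
  axis <- unit_vector(mesh$axis)
  rdir <- radial_directions(cen, axis, mesh$origin)
  fa <- loading$f_axial[mesh$region]
  fr <- loading$f_radial[mesh$region]
  fvec <- outer(fa, axis) + fr * rdir          # m x 3 force density
  contrib <- fvec * (vol / 4)                  # per-vertex share
  ndof <- 3L * nrow(v)
  idx <- integer(12L * nrow(t4)); val <- numeric(12L * nrow(t4))
  pos <- 0L
  for (a in 1:4) for (i in 1:3) {
    sel <- pos + seq_len(nrow(t4))
    idx[sel] <- 3L * (t4[, a] - 1L) + i
    val[sel] <- contrib[, i]
    pos <- pos + nrow(t4)
  }
  accumulate_dofs(idx, val, ndof)
}

# sum values into a dense vector with duplicate-index accumulation
accumulate_dofs <- function(idx, val, n) {
  as.numeric(Matrix::sparseMatrix(i = idx, j = rep.int(1L, length(idx)),
                                  x = val, dims = c(n, 1L)))
}

#' Assemble a surface-traction load vector
#'
#' Verification-mode loading: a constant traction applied to a subset of the
#' boundary triangles, integrated consistently (each triangle distributes
#' `traction * area` equally to its three vertices).
#'
#' @param mesh A `tet_mesh`.
#' @param face_selector Either an integer/logical index into the rows of
#'   `mesh$surface_tris`, or a function taking the t x 3 matrix of face
#'   centroids and returning a logical vector.
#' @param traction Length-3 traction vector (kPa).
#' @return Load vector of length `3 * n_vertices`.
#' @export
assemble_surface_traction <- function(mesh, face_selector, traction) {
  stopifnot(inherits(mesh, "tet_mesh"), length(traction) == 3L)
  tr <- mesh$surface_tris
  if (is.function(face_selector)) {
    cen <- (mesh$vertices[tr[, 1L], , drop = FALSE] +
              mesh$vertices[tr[, 2L], , drop = FALSE] +
              mesh$vertices[tr[, 3L], , drop = FALSE]) / 3
    sel <- which(face_selector(cen))
  } else if (is.logical(face_selector)) {
    sel <- which(face_selector)
  } else sel <- as.integer(face_selector)
  if (!length(sel)) stop("empty face selection", call. = FALSE)
  f <- tr[sel, , drop = FALSE]
  a <- mesh$vertices[f[, 1L], , drop = FALSE]
  b <- mesh$vertices[f[, 2L], , drop = FALSE]
  c_ <- mesh$vertices[f[, 3L], , drop = FALSE]
  area <- sqrt(rowSums(cross_rows(b - a, c_ - a)^2)) / 2
  contrib <- outer(area / 3, as.numeric(traction))   # per-vertex share
  ndof <- 3L * nrow(mesh$vertices)
  idx <- integer(9L * nrow(f)); val <- numeric(9L * nrow(f))
  pos <- 0L
  for (a_ in 1:3) for (i in 1:3) {
    s <- pos + seq_len(nrow(f))
    idx[s] <- 3L * (f[, a_] - 1L) + i
    val[s] <- contrib[, i]
    pos <- pos + nrow(f)
  }
  accumulate_dofs(idx, val, ndof)
}

#' Essential (Dirichlet) constraint set
#'
#' @param nodes Integer vector of vertex indices.
#' @param comps Integer vector (1 = x, 2 = y, 3 = z), recycled against
#'   `nodes`.
#' @param values Prescribed displacement values (mm), recycled.
#' @return Object of class `constraint_set` with global DOF indices.
#' @export
constraint_set <- function(nodes, comps, values = 0) {
  n <- max(length(nodes), length(comps), length(values))
  nodes <- rep_len(as.integer(nodes), n)
  comps <- rep_len(as.integer(comps), n)
  values <- rep_len(as.numeric(values), n)
  if (any(comps < 1L | comps > 3L)) stop("comps must be 1, 2 or 3", call. = FALSE)
  dofs <- 3L * (nodes - 1L) + comps
  dup <- duplicated(dofs)
  structure(list(nodes = nodes[!dup], comps = comps[!dup],
                 dofs = dofs[!dup], values = values[!dup]),
            class = "constraint_set")
}

# concatenate constraint sets (first occurrence of a DOF wins)
combine_constraints <- function(...) {
  cs <- list(...)
  constraint_set(unlist(lapply(cs, `[[`, "nodes")),
                 unlist(lapply(cs, `[[`, "comps")),
                 unlist(lapply(cs, `[[`, "values")))
}

#' Default growth boundary conditions
#'
#' Constraints for the growth simulations. The default `"symmetry"` set lets
#' the proximal face (z = 0) roll (u_z = 0) and enforces the two mirror
#' symmetries of the loading: u_y = 0 on the y = 0 plane and u_x = 0 on the
#' x = 0 plane (at minimum the axis column). These conditions are satisfied
#' exactly by the axisymmetric growth solutions and by the uniaxial
#' closed-form verification fields, remove all six rigid-body modes with
#' ample redundancy, and leave radial expansion free everywhere. They also
#' keep the structure stiff against the small spurious lateral resultant of
#' the discretized radial body load: the `"minimal"` alternative (roller base
#' plus a fully fixed near-axis node and one tangential pin) removes rigid
#' modes but hangs the entire lateral equilibrium on two nodes, which lets
#' integration asymmetries deflect the whole rod.
#'
#' @param mesh A `tet_mesh` with its proximal face at min z.
#' @param type `"symmetry"` (default) or `"minimal"`.
#' @param tol Plane-membership tolerance (mm).
#' @return A `constraint_set`.
#' @export
default_constraints <- function(mesh, type = c("symmetry", "minimal"),
                                tol = 1e-9) {
  type <- match.arg(type)
  v <- mesh$vertices
  z0 <- min(v[, 3L])
  base <- which(abs(v[, 3L] - z0) < tol)
  if (length(base) < 3L) stop("cannot find proximal face", call. = FALSE)
  if (type == "symmetry") {
    on_y0 <- which(abs(v[, 2L]) < tol)
    on_x0 <- which(abs(v[, 1L]) < tol)
    combine_constraints(
      constraint_set(base, 3L, 0),
      constraint_set(on_y0, 2L, 0),
      constraint_set(on_x0, 1L, 0))
  } else {
    r2 <- v[base, 1L]^2 + v[base, 2L]^2
    center <- base[which.min(r2)]
    xpin <- base[which.max(v[base, 1L])]
    combine_constraints(
      constraint_set(base, 3L, 0),
      constraint_set(center, 1:2, 0),
      constraint_set(xpin, 2L, 0))
  }
}

#' Solve the constrained static elasticity system
#'
#' Eliminates constrained degrees of freedom, factorizes the reduced
#' stiffness with a sparse Cholesky decomposition and back-substitutes. A
#' failure of the factorization (not positive definite) is reported as
#' missing rigid-body constraints.
#'
#' @param stiffness Global sparse stiffness from [assemble_stiffness()].
#' @param load Global load vector.
#' @param constraints A [constraint_set()]; must remove all rigid modes.
#' @return Object of class `displacement_field`: list with `u`
#'   (n_vertices x 3, mm), `residual` (relative, on free DOFs), `method`.
#' @export
solve_static <- function(stiffness, load, constraints) {
  stopifnot(inherits(constraints, "constraint_set"))
  ndof <- length(load)
  fixed <- constraints$dofs
  if (any(fixed > ndof)) stop("constraint DOF out of range", call. = FALSE)
  free <- setdiff(seq_len(ndof), fixed)
  uf <- numeric(ndof)
  uf[fixed] <- constraints$values
  rhs <- load[free] - as.numeric(stiffness[free, fixed, drop = FALSE] %*%
                                   constraints$values)
  Kff <- Matrix::forceSymmetric(stiffness[free, free, drop = FALSE])
  not_pd <- function(cond)
    stop("constrained stiffness is not positive definite; constraints ",
         "likely do not remove all rigid-body modes (",
         conditionMessage(cond), ")", call. = FALSE)
  ch <- withCallingHandlers(
    tryCatch(Matrix::Cholesky(Kff, LDL = FALSE, perm = TRUE),
             error = not_pd),
    warning = function(w) {
      if (grepl("not positive definite", conditionMessage(w))) not_pd(w)
      invokeRestart("muffleWarning")
    })
  uf[free] <- as.numeric(Matrix::solve(ch, rhs))
  res_vec <- as.numeric(stiffness %*% uf - load)[free]
  fn <- sqrt(sum(load[free]^2))
  residual <- if (fn > 0) sqrt(sum(res_vec^2)) / fn else sqrt(sum(res_vec^2))
  if (!all(is.finite(uf)))
    stop("solver produced non-finite displacements", call. = FALSE)
  structure(list(u = matrix(uf, ncol = 3L, byrow = TRUE),
                 residual = residual,
                 method = "sparse Cholesky",
                 n_dof = length(free)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat("Displacement field:", nrow(x$u), "vertices; max |u| =",
      format(max(sqrt(rowSums(x$u^2))), digits = 6), "mm;",
      x$method, "residual", format(x$residual, digits = 3), "\n")
  invisible(x)
}
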