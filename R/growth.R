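#' Advect a mesh by a displacement field
#'
#' @param mesh A `tet_mesh`.
#' @param u A `displacement_field` (or an n x 3 matrix).
#' @param scale Multiplier applied to the displacements.
#' @return The deformed mesh (connectivity, regions and surface unchanged).
#'   Warns, listing offending elements, if the deformation inverts any
#'   tetrahedron.
#' @export
deform <- function(mesh, u, scale = 1) {
  stopifnot(inherits(mesh, "tet_mesh"))
  um <- if (inherits(u, "displacement_field")) u$u else as.matrix(u)
  if (nrow(um) != nrow(mesh$vertices) || ncol(um) != 3L)
    stop("displacement field does not match mesh vertices", call. = FALSE)
  mesh$vertices <- mesh$vertices + scale * um
  vol <- tet_volumes(mesh)
  if (any(vol <= 0))
    warning("deformation inverted ", sum(vol <= 0), " tetrahedra (e.g. ",
            paste(utils::head(which(vol <= 0), 5L), collapse = ", "), ")",
            call. = FALSE)
  mesh
}

#' Simulate internal tissue growth of a long bone
#'
#' Solves the small-strain linear-elasticity problem with the scenario's
#' region-wise growth body forces and advects the mesh by the solution;
#' optionally repeats on the updated geometry (`n_steps > 1`) to produce
#' growth snapshots. With `load_scale = NULL` the loads are scaled once so
#' that the first-step maximum displacement equals
#' `scenario$normalization * R` (small-strain guard); pass an explicit
#' `load_scale` to compare scenarios under identical loading.
#'
#' @param mesh A `tet_mesh`; regions are (re)assigned from the scenario's
#'   partition.
#' @param scenario A [make_scenario()] result.
#' @param n_steps Number of incremental growth steps (default 1: one linear
#'   solve).
#' @param step_scale Fraction of each solution applied per step.
#' @param constraints Optional [constraint_set()]; default
#'   [default_constraints()].
#' @param load_scale Numeric multiplier for the scenario loads, or `NULL` to
#'   normalize automatically.
#' @return Object of class `bone_growth`: the initial and final meshes, all
#'   snapshots, the last displacement field, the applied `load_scale` and
#'   solver metadata.
#' @export
simulate_growth <- function(mesh, scenario, n_steps = 1L, step_scale = 1,
                            constraints = NULL, load_scale = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(scenario, "scenario"))
  n_steps <- check_count(n_steps, "n_steps", min = 1L)
  mesh <- assign_axial_regions(mesh, scenario$partition)
  if (is.null(constraints)) constraints <- default_constraints(mesh)
  R <- if (!is.null(mesh$spec)) mesh$spec$radius_mm else
    max(sqrt(mesh$vertices[, 1L]^2 + mesh$vertices[, 2L]^2))
  mesh0 <- mesh
  snapshots <- vector("list", n_steps)
  field <- NULL
  for (s in seq_len(n_steps)) {
    K <- assemble_stiffness(mesh, scenario$material)
    f <- assemble_body_load(mesh, scenario$loads)
    if (is.null(load_scale)) {     # normalize on the first geometry
      probe <- solve_static(K, f, constraints)
      umax <- max(sqrt(rowSums(probe$u^2)))
      if (umax == 0) stop("zero displacement: cannot normalize loads",
                          call. = FALSE)
      load_scale <- scenario$normalization * R / umax
    }
    field <- solve_static(K, f * load_scale, constraints)
    umax <- max(sqrt(rowSums(field$u^2)))
    if (step_scale * umax > 0.3 * R)
      warning("step ", s, ": max displacement ", format(step_scale * umax),
              " exceeds 0.3 R; small-strain assumption is strained",
              call. = FALSE)
    newmesh <- withCallingHandlers(
      deform(mesh, field, scale = step_scale),
      warning = function(w) {
        if (grepl("inverted", conditionMessage(w)))
          stop("element inversion while advecting at step ", s,
               "; reduce step_scale or load_scale", call. = FALSE)
        invokeRestart("muffleWarning")
      })
    mesh <- newmesh
    snapshots[[s]] <- mesh
  }
  structure(list(mesh0 = mesh0, mesh = mesh, snapshots = snapshots,
                 displacement = field, scenario = scenario,
                 load_scale = load_scale, n_steps = n_steps,
                 step_scale = step_scale, constraints = constraints),
            class = "bone_growth")
}

#' @export
print.bone_growth <- function(x, ...) {
  cat("Bone growth simulation ('", x$scenario$name, "' scenario): ",
      x$n_steps, " step(s), load scale ", format(x$load_scale, digits = 5),
      "\n", sep = "")
  cat("  ", nrow(x$mesh$vertices), " vertices, ", nrow(x$mesh$tets),
      " tets; solver ", x$displacement$method, ", residual ",
      format(x$displacement$residual, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
summary.bone_growth <- function(object, n_bins = 32L, ...) {
  lat <- lateral_vertex_mask(object$mesh0)
  n_bins <- adapt_bins(object$mesh0, lat, n_bins)
  p0 <- diameter_profile(mesh_surface(object$mesh0), n_bins = n_bins,
                         lateral = lat)
  p1 <- diameter_profile(mesh_surface(object$mesh), n_bins = n_bins,
                         lateral = lat)
  out <- list(
    scenario = object$scenario$name,
    n_steps = object$n_steps,
    load_scale = object$load_scale,
    volume_initial = sum(tet_volumes(object$mesh0)),
    volume_final = sum(tet_volumes(object$mesh)),
    length_initial = diff(range(object$mesh0$vertices[, 3L])),
    length_final = diff(range(object$mesh$vertices[, 3L])),
    max_displacement = max(sqrt(rowSums(object$displacement$u^2))),
    bulge_index_initial = bulge_index(p0),
    bulge_index_final = bulge_index(p1),
    residual = object$displacement$residual)
  class(out) <- "summary.bone_growth"
  out
}

#' @export
print.summary.bone_growth <- function(x, ...) {
  cat("Growth simulation summary ('", x$scenario, "')\n", sep = "")
  cat(sprintf("  volume  : %.4f -> %.4f mm^3\n", x$volume_initial, x$volume_final))
  cat(sprintf("  length  : %.4f -> %.4f mm\n", x$length_initial, x$length_final))
  cat(sprintf("  bulge index: %.4f -> %.4f\n",
              x$bulge_index_initial, x$bulge_index_final))
  cat(sprintf("  max |u| %.4g mm, residual %.3g\n",
              x$max_displacement, x$residual))
  invisible(x)
}

#' @export
plot.bone_growth <- function(x, n_bins = 32L, ...) {
  lat <- lateral_vertex_mask(x$mesh0)
  n_bins <- adapt_bins(x$mesh0, lat, n_bins)
  p0 <- diameter_profile(mesh_surface(x$mesh0), n_bins = n_bins, lateral = lat)
  p1 <- diameter_profile(mesh_surface(x$mesh), n_bins = n_bins, lateral = lat)
  graphics::matplot(cbind(p0$center, p1$center),
                    cbind(p0$radius_mean, p1$radius_mean), type = "l",
                    lty = c(2, 1), col = c("grey40", "firebrick"),
                    xlab = "axial position (mm)",
                    ylab = "effective radius (mm)",
                    main = paste0("Diameter profile (", x$scenario$name, ")"),
                    ...)
  graphics::legend("bottom", c("initial", "grown"), lty = c(2, 1),
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

# cap the bin count at the number of distinct axial vertex stations so
# coarse meshes do not produce empty bins (bulge_index needs >= 10)
adapt_bins <- function(mesh, lat, n_bins) {
  nz <- length(unique(round(mesh$vertices[lat, 3L], 9)))
  max(10L, min(as.integer(n_bins), nz))
}

#' Lateral-surface vertex mask
#'
#' Marks vertices of a mesh (or surface) that lie on the lateral wall, i.e.
#' not within `tol` of the two end planes. Computed on the undeformed
#' geometry and reusable on deformed copies (shared connectivity).
#'
#' @param x A `tet_mesh` or `tri_surface`.
#' @param tol End-plane tolerance (mm).
#' @return Logical vector over vertices.
#' @export
lateral_vertex_mask <- function(x, tol = 1e-6) {
  v <- x$vertices
  on_surface <- rep(FALSE, nrow(v))
  tri <- if (inherits(x, "tet_mesh")) x$surface_tris else x$triangles
  on_surface[unique(as.vector(tri))] <- TRUE
  z <- v[, 3L]
  z0 <- min(z[on_surface]); z1 <- max(z[on_surface])
  on_surface & (z > z0 + tol) & (z < z1 - tol)
}
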