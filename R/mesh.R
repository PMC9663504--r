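#' Cylinder discretization specification
#'
#' Describes the idealized long-bone domain: a circular cylinder of given
#' length and radius, together with the structured-mesh resolution along the
#' axis (`n_axial` layers), in radius (`n_radial` concentric rings) and in
#' angle (`n_angular` sectors). `n_angular` must be even so that the generated
#' vertex set is mirror-symmetric about the two orthogonal axial planes.
#'
#' @param length_mm Cylinder length L (mm), positive.
#' @param radius_mm Cylinder radius R (mm), positive.
#' @param n_axial Number of element layers along the axis, integer >= 2.
#' @param n_radial Number of concentric node rings, integer >= 1.
#' @param n_angular Number of angular sectors, even integer >= 6.
#' @return An object of class `cylinder_spec`.
#' @examples
#' cylinder_spec(10, 1, n_axial = 8, n_radial = 2, n_angular = 8)
#' @export
cylinder_spec <- function(length_mm = 10, radius_mm = 1,
                          n_axial = 48L, n_radial = 10L, n_angular = 24L) {
  check_positive_scalar(length_mm, "length_mm")
  check_positive_scalar(radius_mm, "radius_mm")
  n_axial <- check_count(n_axial, "n_axial", min = 2L)
  n_radial <- check_count(n_radial, "n_radial", min = 1L)
  n_angular <- check_count(n_angular, "n_angular", min = 6L)
  if (n_angular %% 2L != 0L)
    stop("'n_angular' must be even (mirror symmetry of the mesh): got ",
         n_angular, call. = FALSE)
  structure(list(length_mm = length_mm, radius_mm = radius_mm,
                 n_axial = n_axial, n_radial = n_radial,
                 n_angular = n_angular),
            class = "cylinder_spec")
}

#' Axial region partition
#'
#' Contiguous axial slabs delimited by monotonically increasing fractions of
#' the cylinder length. The default is a 5-slab epiphysis--metaphysis--
#' diaphysis--metaphysis--epiphysis layout.
#'
#' @param boundaries Numeric vector of axial fractions; must start at 0, end
#'   at 1 and be strictly increasing.
#' @return An object of class `region_partition` with `n_regions =
#'   length(boundaries) - 1`.
#' @export
region_partition <- function(boundaries = c(0, 0.15, 0.35, 0.65, 0.85, 1)) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2L)
    stop("'boundaries' needs at least two values", call. = FALSE)
  if (abs(boundaries[1L]) > 1e-12 || abs(boundaries[length(boundaries)] - 1) > 1e-12)
    stop("'boundaries' must start at 0 and end at 1", call. = FALSE)
  if (any(diff(boundaries) <= 0))
    stop("'boundaries' must be strictly increasing", call. = FALSE)
  boundaries[1L] <- 0; boundaries[length(boundaries)] <- 1
  structure(list(boundaries = boundaries,
                 n_regions = length(boundaries) - 1L),
            class = "region_partition")
}

# cross product of the rows of two n x 3 matrices
cross_rows <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

# Triangulate the unit disk template used at every axial layer:
# node 1 at the center, ring r (1..n_radial) has n_angular nodes at radius
# r/n_radial, angles 2*pi*k/n_angular. Quad diagonals go through the quad's
# smallest node index so the split is orientation independent.
disk_template <- function(n_radial, n_angular) {
  nr <- n_radial; na <- n_angular
  ang <- 2 * pi * (seq_len(na) - 1L) / na
  r <- rep(seq_len(nr) / nr, each = na)
  xy <- rbind(c(0, 0), cbind(r * cos(rep(ang, nr)), r * sin(rep(ang, nr))))
  idx <- function(ring, k) {            # ring 0 = center; k wraps modulo na
    if (ring == 0L) rep.int(1L, length(k))
    else 1L + (ring - 1L) * na + ((k - 1L) %% na) + 1L
  }
  tris <- vector("list", nr)
  k <- seq_len(na)
  tris[[1L]] <- cbind(idx(0L, 1L), idx(1L, k), idx(1L, k + 1L))
  if (nr >= 2L) {
    for (ring in 2:nr) {
      a <- idx(ring - 1L, k); b <- idx(ring - 1L, k + 1L)
      c_ <- idx(ring, k);     d <- idx(ring, k + 1L)
      use_ad <- pmin(a, d) < pmin(b, c_)
      t1 <- cbind(a, b, ifelse(use_ad, d, c_))
      t2 <- cbind(ifelse(use_ad, a, b), d, c_)
      tris[[ring]] <- rbind(t1, t2)
    }
  }
  tris <- do.call(rbind, tris)
  # enforce counter-clockwise orientation in the xy-plane
  ax <- xy[tris[, 1L], , drop = FALSE]
  bx <- xy[tris[, 2L], , drop = FALSE]
  cx <- xy[tris[, 3L], , drop = FALSE]
  area2 <- (bx[, 1L] - ax[, 1L]) * (cx[, 2L] - ax[, 2L]) -
    (bx[, 2L] - ax[, 2L]) * (cx[, 1L] - ax[, 1L])
  flip <- area2 < 0
  if (any(flip)) tris[flip, c(2L, 3L)] <- tris[flip, c(3L, 2L)]
  list(xy = xy, tris = tris)
}

# Split one triangular prism (bottom p1 p2 p3, top p4 p5 p6, pi below p(i+3))
# into 3 tetrahedra with quad-face diagonals through the smallest global
# vertex index, so adjacent prisms always conform (Dompierre et al. rule).
split_prisms <- function(pr) {
  rot <- rbind(c(1L, 2L, 3L, 4L, 5L, 6L),
               c(2L, 3L, 1L, 5L, 6L, 4L),
               c(3L, 1L, 2L, 6L, 4L, 5L),
               c(4L, 6L, 5L, 1L, 3L, 2L),
               c(5L, 4L, 6L, 2L, 1L, 3L),
               c(6L, 5L, 4L, 3L, 2L, 1L))
  amin <- max.col(-pr, ties.method = "first")      # position of min index
  n <- nrow(pr)
  p <- matrix(0L, n, 6L)
  for (j in 1:6) {
    sel <- cbind(seq_len(n), rot[amin, j])
    p[, j] <- pr[sel]
  }
  caseA <- pmin(p[, 2L], p[, 6L]) < pmin(p[, 3L], p[, 5L])
  tets <- matrix(0L, 3L * n, 4L)
  iA <- which(caseA); iB <- which(!caseA)
  if (length(iA)) {
    tets[3L * iA - 2L, ] <- p[iA, c(1L, 2L, 3L, 6L), drop = FALSE]
    tets[3L * iA - 1L, ] <- p[iA, c(1L, 2L, 6L, 5L), drop = FALSE]
    tets[3L * iA, ]      <- p[iA, c(1L, 5L, 6L, 4L), drop = FALSE]
  }
  if (length(iB)) {
    tets[3L * iB - 2L, ] <- p[iB, c(1L, 2L, 3L, 5L), drop = FALSE]
    tets[3L * iB - 1L, ] <- p[iB, c(1L, 5L, 3L, 6L), drop = FALSE]
    tets[3L * iB, ]      <- p[iB, c(1L, 5L, 6L, 4L), drop = FALSE]
  }
  tets
}

#' Signed volumes of all tetrahedra in a mesh
#'
#' @param mesh A `tet_mesh`.
#' @return Numeric vector of signed volumes (mm^3); positive for the mesh's
#'   vertex-ordering convention.
#' @export
tet_volumes <- function(mesh) {
  v <- mesh$vertices; t4 <- mesh$tets
  e2 <- v[t4[, 2L], , drop = FALSE] - v[t4[, 1L], , drop = FALSE]
  e3 <- v[t4[, 3L], , drop = FALSE] - v[t4[, 1L], , drop = FALSE]
  e4 <- v[t4[, 4L], , drop = FALSE] - v[t4[, 1L], , drop = FALSE]
  rowSums(cross_rows(e2, e3) * e4) / 6
}

# Extract the oriented boundary triangulation of a tet mesh. Faces of a
# positively oriented tet, listed so normals point away from the 4th vertex.
extract_surface <- function(vertices, tets) {
  f <- rbind(tets[, c(2L, 3L, 4L)], tets[, c(1L, 4L, 3L)],
             tets[, c(1L, 2L, 4L)], tets[, c(1L, 3L, 2L)])
  n <- as.numeric(nrow(vertices)) + 1
  s1 <- pmin(f[, 1L], f[, 2L], f[, 3L])
  s3 <- pmax(f[, 1L], f[, 2L], f[, 3L])
  s2 <- as.numeric(f[, 1L]) + f[, 2L] + f[, 3L] - s1 - s3
  key <- (s1 * n + s2) * n + s3
  d1 <- duplicated(key); d2 <- duplicated(key, fromLast = TRUE)
  if (any(d1 & d2)) stop("non-manifold face in tetrahedral mesh", call. = FALSE)
  f[!(d1 | d2), , drop = FALSE]
}

#' Build a structured tetrahedral mesh of a cylinder
#'
#' Generates nodes on concentric rings at each axial layer and splits the
#' resulting triangular prisms into tetrahedra with a consistent
#' smallest-index diagonal rule, yielding a conforming, watertight mesh. The
#' discretized cross-section is the inscribed polygon, so the mesh volume is
#' strictly below \eqn{\pi R^2 L} and converges to it as `n_angular` and
#' `n_radial` grow. The bone axis is +z with the proximal face at z = 0.
#'
#' @param spec A [cylinder_spec()].
#' @return A `tet_mesh`: list with `vertices` (n x 3, mm), `tets` (m x 4,
#'   positively oriented), `surface_tris` (outward-oriented boundary
#'   triangles), `region` (integer per tet, initially all 1), `axis`,
#'   `origin`, and the originating `spec`.
#' @examples
#' m <- build_cylinder_mesh(cylinder_spec(2, 1, 2, 1, 6))
#' sum(tet_volumes(m))
#' @export
build_cylinder_mesh <- function(spec = cylinder_spec()) {
  stopifnot(inherits(spec, "cylinder_spec"))
  L <- spec$length_mm; R <- spec$radius_mm
  nz <- spec$n_axial
  disk <- disk_template(spec$n_radial, spec$n_angular)
  nd <- nrow(disk$xy)
  z <- seq(0, L, length.out = nz + 1L)
  vertices <- cbind(
    rep(disk$xy[, 1L] * R, nz + 1L),
    rep(disk$xy[, 2L] * R, nz + 1L),
    rep(z, each = nd))
  # prisms: disk triangle extruded between consecutive layers
  ntri <- nrow(disk$tris)
  lay <- rep((0:(nz - 1L)) * nd, each = ntri)
  bot <- disk$tris[rep(seq_len(ntri), nz), , drop = FALSE] + lay
  prisms <- cbind(bot, bot + nd)
  tets <- split_prisms(prisms)
  # canonicalize orientation: positive signed volume
  tmp <- list(vertices = vertices, tets = tets)
  vol <- tet_volumes(tmp)
  neg <- vol < 0
  if (any(neg)) tets[neg, c(3L, 4L)] <- tets[neg, c(4L, 3L)]
  surface <- extract_surface(vertices, tets)
  mesh <- structure(list(
    vertices = vertices,
    tets = tets,
    surface_tris = surface,
    region = rep.int(1L, nrow(tets)),
    axis = c(0, 0, 1),
    origin = c(0, 0, 0),
    spec = spec), class = "tet_mesh")
  mesh
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("Tetrahedral mesh:", nrow(x$vertices), "vertices,",
      nrow(x$tets), "tets,", nrow(x$surface_tris), "surface triangles\n")
  cat("  regions:", paste(sort(unique(x$region)), collapse = " "),
      " total volume:", format(sum(tet_volumes(x)), digits = 8), "mm^3\n")
  invisible(x)
}

#' Label tetrahedra by axial region
#'
#' Each tetrahedron is assigned to the slab of `partition` that contains its
#' centroid's axial coordinate (as a fraction of the axial span).
#'
#' @param mesh A `tet_mesh`.
#' @param partition A [region_partition()].
#' @return The mesh with its `region` field replaced; a warning names any
#'   region left empty (slab thinner than the element layer).
#' @export
assign_axial_regions <- function(mesh, partition = region_partition()) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(partition, "region_partition"))
  t4 <- mesh$tets
  zc <- (mesh$vertices[t4[, 1L], 3L] + mesh$vertices[t4[, 2L], 3L] +
           mesh$vertices[t4[, 3L], 3L] + mesh$vertices[t4[, 4L], 3L]) / 4
  zr <- range(mesh$vertices[, 3L])
  frac <- (zc - zr[1L]) / (zr[2L] - zr[1L])
  reg <- findInterval(frac, partition$boundaries,
                      rightmost.closed = TRUE, all.inside = TRUE)
  missing <- setdiff(seq_len(partition$n_regions), unique(reg))
  if (length(missing))
    warning("empty region(s): ", paste(missing, collapse = ", "),
            " (slab thinner than one element layer)", call. = FALSE)
  mesh$region <- as.integer(reg)
  mesh$partition <- partition
  mesh
}

#' Mesh quality report
#'
#' @param mesh A `tet_mesh`.
#' @return List with `n_tets`, `min_volume`, `max_volume`, and
#'   `min_edge_ratio` (shortest/longest edge per tet, a dihedral-quality
#'   proxy). Errors if any tetrahedron is inverted, listing the offenders.
#' @export
mesh_quality <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  vol <- tet_volumes(mesh)
  bad <- which(vol <= 0)
  if (length(bad))
    stop("inverted/degenerate tetrahedra at indices: ",
         paste(utils::head(bad, 20L), collapse = ", "),
         if (length(bad) > 20L) " ..." else "", call. = FALSE)
  v <- mesh$vertices; t4 <- mesh$tets
  pairs <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L), c(3L, 4L))
  el <- sapply(pairs, function(p) {
    d <- v[t4[, p[1L]], , drop = FALSE] - v[t4[, p[2L]], , drop = FALSE]
    sqrt(rowSums(d * d))
  })
  list(n_tets = nrow(t4),
       min_volume = min(vol),
       max_volume = max(vol),
       min_edge_ratio = min(apply(el, 1L, min) / apply(el, 1L, max)))
}

#' Triangulated surface container
#'
#' @param vertices n x 3 numeric matrix of coordinates (mm).
#' @param triangles t x 3 integer matrix of vertex indices, consistently
#'   oriented (outward normals for a closed surface).
#' @return Object of class `tri_surface`.
#' @export
tri_surface <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L || ncol(triangles) != 3L)
    stop("vertices and triangles must have 3 columns", call. = FALSE)
  if (nrow(triangles) < 1L) stop("empty surface", call. = FALSE)
  if (max(triangles) > nrow(vertices) || min(triangles) < 1L)
    stop("triangle indices out of range", call. = FALSE)
  structure(list(vertices = vertices, triangles = triangles),
            class = "tri_surface")
}

#' @export
print.tri_surface <- function(x, ...) {
  cat("Triangulated surface:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles\n")
  invisible(x)
}

#' Boundary surface of a tet mesh as a `tri_surface`
#'
#' @param mesh A `tet_mesh`.
#' @return A `tri_surface` sharing the mesh's vertex array (all mesh vertices
#'   are kept; only boundary triangles reference them).
#' @export
mesh_surface <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  tri_surface(mesh$vertices, mesh$surface_tris)
}

# every edge of a closed triangulation must be shared by exactly 2 triangles
is_watertight <- function(surface) {
  tr <- surface$triangles
  e <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  all(table(key) == 2L)
}

#' Volume enclosed by a closed triangulated surface
#'
#' Divergence-theorem volume \eqn{\sum \det(v_1, v_2, v_3)/6}; positive for
#' outward-oriented triangles.
#'
#' @param surface A `tri_surface` (watertight, consistently oriented).
#' @return Enclosed volume (mm^3).
#' @export
enclosed_volume <- function(surface) {
  stopifnot(inherits(surface, "tri_surface"))
  if (!is_watertight(surface))
    stop("surface is not watertight: cannot compute enclosed volume",
         call. = FALSE)
  v <- surface$vertices; tr <- surface$triangles
  a <- v[tr[, 1L], , drop = FALSE]
  b <- v[tr[, 2L], , drop = FALSE]
  c_ <- v[tr[, 3L], , drop = FALSE]
  sum(rowSums(cross_rows(b, c_) * a)) / 6
}
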