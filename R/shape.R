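#' Axial diameter profile of a surface
#'
#' Bins the lateral-surface vertices along the bone axis and reports the
#' effective radius per bin (mean distance to the axis), the maximum radius
#' and the vertex count. Empty bins are kept with `NA` radii and flagged,
#' never interpolated.
#'
#' @param surface A `tri_surface`.
#' @param n_bins Number of axial bins.
#' @param axis,origin Bone axis definition (unit direction is enforced).
#' @param lateral Optional logical mask over surface vertices selecting the
#'   lateral wall; by default vertices within `cap_tol` of the two end planes
#'   are treated as cap vertices and excluded.
#' @param cap_tol End-plane tolerance (mm).
#' @return A `data.frame` of class `diameter_profile` with columns `center`,
#'   `radius_mean`, `radius_max`, `count`, and attributes `span` (axial
#'   range) and `n_lateral`.
#' @export
diameter_profile <- function(surface, n_bins = 50L, axis = c(0, 0, 1),
                             origin = c(0, 0, 0), lateral = NULL,
                             cap_tol = 1e-6) {
  stopifnot(inherits(surface, "tri_surface"))
  n_bins <- check_count(n_bins, "n_bins", min = 1L)
  axis <- unit_vector(axis)
  v <- surface$vertices
  s <- drop(sweep(v, 2L, origin) %*% axis)
  if (is.null(lateral)) {
    used <- rep(FALSE, nrow(v))
    used[unique(as.vector(surface$triangles))] <- TRUE
    lateral <- used & (s > min(s[used]) + cap_tol) & (s < max(s[used]) - cap_tol)
  }
  if (!any(lateral))
    stop("no lateral vertices: all vertices lie on the end caps", call. = FALSE)
  rel <- sweep(v, 2L, origin) - outer(s, axis)
  r <- sqrt(rowSums(rel^2))
  sl <- s[lateral]; rl <- r[lateral]
  breaks <- seq(min(sl), max(sl), length.out = n_bins + 1L)
  bin <- findInterval(sl, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  count <- tabulate(bin, nbins = n_bins)
  rmean <- rep(NA_real_, n_bins); rmax <- rep(NA_real_, n_bins)
  agg <- tapply(rl, bin, mean)
  rmean[as.integer(names(agg))] <- agg
  agg <- tapply(rl, bin, max)
  rmax[as.integer(names(agg))] <- agg
  if (any(count == 0L))
    warning(sum(count == 0L), " empty bin(s) in diameter profile",
            call. = FALSE)
  out <- data.frame(center = (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2,
                    radius_mean = rmean, radius_max = rmax, count = count)
  attr(out, "span") <- range(sl)
  attr(out, "n_lateral") <- sum(lateral)
  class(out) <- c("diameter_profile", "data.frame")
  out
}

#' Bulge index of a diameter profile
#'
#' The mid-shaft to end-band ratio of effective radius: mean effective radius
#' over the central `central_frac` of the axial span, divided by the average
#' of the mean effective radii over the two end bands of width `end_frac`.
#' 1 for a perfect cylinder, > 1 for a bulky (mid-inflated) rod, < 1 for a
#' tapered/waisted one. Bin means are weighted by their vertex counts.
#'
#' @param profile A [diameter_profile()] with at least 10 bins.
#' @param central_frac Fraction of the span forming the central band.
#' @param end_frac Fraction of the span forming each end band.
#' @return Dimensionless scalar.
#' @export
bulge_index <- function(profile, central_frac = 0.2, end_frac = 0.15) {
  stopifnot(inherits(profile, "diameter_profile"))
  if (nrow(profile) < 10L)
    stop("bulge_index needs a profile with at least 10 bins", call. = FALSE)
  span <- attr(profile, "span")
  len <- diff(span); mid <- mean(span)
  ctr <- profile$center
  band_mean <- function(sel) {
    sel <- sel & profile$count > 0L
    if (!any(sel)) stop("empty band in bulge_index", call. = FALSE)
    sum(profile$radius_mean[sel] * profile$count[sel]) / sum(profile$count[sel])
  }
  central <- band_mean(abs(ctr - mid) <= central_frac / 2 * len)
  lo <- band_mean(ctr <= span[1L] + end_frac * len)
  hi <- band_mean(ctr >= span[2L] - end_frac * len)
  central / mean(c(lo, hi))
}

# Per-triangle precomputation for closest-point queries
triangle_cache <- function(surface) {
  v <- surface$vertices; tr <- surface$triangles
  a <- v[tr[, 1L], , drop = FALSE]
  e0 <- v[tr[, 2L], , drop = FALSE] - a
  e1 <- v[tr[, 3L], , drop = FALSE] - a
  nrm <- cross_rows(e0, e1)
  nl <- sqrt(rowSums(nrm^2))
  degen <- nl < 1e-300
  nl[degen] <- 1
  list(a = a, b = v[tr[, 2L], , drop = FALSE], c = v[tr[, 3L], , drop = FALSE],
       e0 = e0, e1 = e1,
       aa = rowSums(e0 * e0), bb = rowSums(e0 * e1), cc = rowSums(e1 * e1),
       normal = nrm / nl)
}

# closest point on each segment (p0 + t*(p1-p0), t clamped to [0,1]) to p
seg_closest <- function(p, p0, p1) {
  d <- p1 - p0
  w <- sweep(-p0, 2L, p, `+`)          # p - p0 rowwise
  dd <- rowSums(d * d)
  t <- rowSums(w * d) / pmax(dd, 1e-300)
  t <- pmin(pmax(t, 0), 1)
  p0 + d * t
}

# Exact closest point on a triangle set for one query point. The closest
# point is either the interior plane projection (when its barycentric
# coordinates are admissible) or lies on one of the three edges.
closest_on_triangles <- function(p, cache) {
  d <- sweep(cache$a, 2L, p)           # a - p
  dp0 <- rowSums(cache$e0 * d)
  dp1 <- rowSums(cache$e1 * d)
  det <- cache$aa * cache$cc - cache$bb^2
  s <- cache$bb * dp1 - cache$cc * dp0
  t <- cache$bb * dp0 - cache$aa * dp1
  inside <- s >= 0 & t >= 0 & (s + t) <= det & det > 0
  cp <- matrix(NA_real_, nrow(cache$a), 3L)
  if (any(inside)) {
    si <- s[inside] / det[inside]; ti <- t[inside] / det[inside]
    cp[inside, ] <- cache$a[inside, , drop = FALSE] +
      cache$e0[inside, , drop = FALSE] * si +
      cache$e1[inside, , drop = FALSE] * ti
  }
  out <- which(!inside)
  if (length(out)) {
    c1 <- seg_closest(p, cache$a[out, , drop = FALSE], cache$b[out, , drop = FALSE])
    c2 <- seg_closest(p, cache$a[out, , drop = FALSE], cache$c[out, , drop = FALSE])
    c3 <- seg_closest(p, cache$b[out, , drop = FALSE], cache$c[out, , drop = FALSE])
    d1 <- rowSums(sweep(c1, 2L, p)^2)
    d2 <- rowSums(sweep(c2, 2L, p)^2)
    d3 <- rowSums(sweep(c3, 2L, p)^2)
    pick <- max.col(-cbind(d1, d2, d3), ties.method = "first")
    co <- c1
    co[pick == 2L, ] <- c2[pick == 2L, , drop = FALSE]
    co[pick == 3L, ] <- c3[pick == 3L, , drop = FALSE]
    cp[out, ] <- co
  }
  d2all <- rowSums(sweep(cp, 2L, p)^2)
  k <- which.min(d2all)
  list(distance = sqrt(d2all[k]), triangle = k, point = cp[k, ])
}

#' Closest-point distances from points to a triangulated surface
#'
#' Exact point-to-triangle-set distances (vertex, edge and face cases all
#' handled) for each query point, with the closest triangle index and the
#' closest point itself.
#'
#' @param points n x 3 matrix of query points.
#' @param surface Reference `tri_surface`.
#' @return List with `distance` (n), `triangle` (n), `closest` (n x 3) and
#'   `signed` (n; positive when the point lies on the outward-normal side of
#'   its closest triangle).
#' @export
surface_distance <- function(points, surface) {
  stopifnot(inherits(surface, "tri_surface"))
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be n x 3", call. = FALSE)
  cache <- triangle_cache(surface)
  n <- nrow(points)
  dist <- numeric(n); tri <- integer(n); cp <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    res <- closest_on_triangles(points[i, ], cache)
    dist[i] <- res$distance; tri[i] <- res$triangle; cp[i, ] <- res$point
  }
  side <- sign(rowSums((points - cp) * cache$normal[tri, , drop = FALSE]))
  list(distance = dist, triangle = tri, closest = cp,
       signed = side * dist)
}

#' Rigid pre-alignment of a surface to a reference
#'
#' Optional hook for imported surfaces that do not share a frame with the
#' reference: translates the test surface's centroid onto the reference's
#' and rotates its principal axes (eigenvectors of the vertex covariance,
#' sign-fixed towards the reference axes) into alignment. Simulated shapes
#' share a frame already, so [surface_deviation()] leaves this off by
#' default.
#'
#' @param surface Surface to move (`tri_surface`).
#' @param reference Target frame (`tri_surface`).
#' @return The rigidly transformed `surface`.
#' @export
align_surfaces <- function(surface, reference) {
  stopifnot(inherits(surface, "tri_surface"), inherits(reference, "tri_surface"))
  paxes <- function(v) {
    e <- eigen(stats::cov(v), symmetric = TRUE)
    e$vectors
  }
  cs <- colMeans(surface$vertices)
  cr <- colMeans(reference$vertices)
  Ps <- paxes(surface$vertices); Pr <- paxes(reference$vertices)
  # fix eigenvector signs so corresponding axes point the same way
  for (k in 1:3) if (sum(Ps[, k] * Pr[, k]) < 0) Ps[, k] <- -Ps[, k]
  R <- Pr %*% t(Ps)
  if (det(R) < 0) { Ps[, 3] <- -Ps[, 3]; R <- Pr %*% t(Ps) }
  v <- sweep(surface$vertices, 2L, cs)
  surface$vertices <- sweep(v %*% t(R), 2L, cr, `+`)
  surface
}

#' Nominal/actual surface-deviation map
#'
#' For every vertex of the test ("actual") surface, the exact closest-point
#' distance to the reference ("nominal") surface, with a sign (+ outside / -
#' inside the reference, by the side of the closest triangle's outward
#' normal). Summary statistics are computed over the lateral vertices (or all
#' vertices if no mask applies).
#'
#' @param test,reference `tri_surface` objects.
#' @param lateral Optional logical mask over test vertices for the summary
#'   statistics (defaults to vertices used by test triangles).
#' @param pre_align Rigidly align the test surface first (see
#'   [align_surfaces()]); off by default since simulated shapes share a
#'   frame.
#' @return Object of class `deviation_map`: per-vertex `distance` and
#'   `signed` (mm), closest `triangle`, and `summary` (mean, max, 95th
#'   percentile of unsigned distance).
#' @export
surface_deviation <- function(test, reference, lateral = NULL,
                              pre_align = FALSE) {
  stopifnot(inherits(test, "tri_surface"), inherits(reference, "tri_surface"))
  if (isTRUE(pre_align)) test <- align_surfaces(test, reference)
  used <- rep(FALSE, nrow(test$vertices))
  used[unique(as.vector(test$triangles))] <- TRUE
  res <- surface_distance(test$vertices, reference)
  res$distance[!used] <- NA_real_
  res$signed[!used] <- NA_real_
  sel <- if (is.null(lateral)) used else (lateral & used)
  d <- res$distance[sel]
  structure(list(distance = res$distance, signed = res$signed,
                 triangle = res$triangle,
                 lateral = sel,
                 summary = c(mean = mean(d), max = max(d),
                             p95 = unname(stats::quantile(d, 0.95)))),
            class = "deviation_map")
}

#' @export
print.deviation_map <- function(x, ...) {
  cat("Deviation map over", sum(!is.na(x$distance)), "test vertices\n")
  cat(sprintf("  mean %.5g  max %.5g  p95 %.5g (mm, unsigned, lateral)\n",
              x$summary["mean"], x$summary["max"], x$summary["p95"]))
  invisible(x)
}

#' Labeled 3-D raster volume
#'
#' Micro-CT-segmentation-like volume: an integer array with isotropic voxels
#' and the label convention 0 = background, 1 = cartilage, 2 = bone.
#'
#' @param data 3-D integer array.
#' @param voxel_mm Isotropic voxel edge length (mm), positive.
#' @param labels Named integer vector declaring the legal labels.
#' @return Object of class `labeled_volume`.
#' @export
labeled_volume <- function(data, voxel_mm,
                           labels = c(background = 0L, cartilage = 1L, bone = 2L)) {
  check_positive_scalar(voxel_mm, "voxel_mm")
  if (length(dim(data)) != 3L) stop("'data' must be a 3-D array", call. = FALSE)
  storage.mode(data) <- "integer"
  present <- unique(as.vector(data))
  illegal <- setdiff(present, as.integer(labels))
  if (length(illegal))
    stop("volume contains undeclared label(s): ",
         paste(illegal, collapse = ", "), call. = FALSE)
  structure(list(data = data, voxel_mm = voxel_mm, labels = labels),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat("Labeled volume", paste(dim(x$data), collapse = " x "),
      "voxels @", x$voxel_mm, "mm\n")
  for (nm in names(x$labels))
    cat(sprintf("  %-10s (%d): %d voxels\n", nm, x$labels[[nm]],
                sum(x$data == x$labels[[nm]])))
  invisible(x)
}

#' Quantify the volume occupied by one label
#'
#' Voxel-counting volume estimate `count(label) * voxel^3`, the raster
#' analogue of segmenting ossified bone and reading off its volume.
#'
#' @param volume A [labeled_volume()].
#' @param label Label value (or its declared name).
#' @return Volume in mm^3.
#' @export
labeled_volume_quantify <- function(volume, label) {
  stopifnot(inherits(volume, "labeled_volume"))
  if (is.character(label)) {
    if (!label %in% names(volume$labels))
      stop("unknown label name: ", label, call. = FALSE)
    label <- volume$labels[[label]]
  }
  if (!label %in% volume$labels)
    stop("label ", label, " is not declared for this volume", call. = FALSE)
  sum(volume$data == as.integer(label)) * volume$voxel_mm^3
}
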