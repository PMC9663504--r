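#' Moments and sampling of the truncated normal angle model
#'
#' Division-orientation angles are modelled as a normal distribution
#' truncated to the axial range [lo, hi] = [0, 90] degrees: a unimodal,
#' bounded family with closed-form moments, which makes every downstream
#' estimate checkable against an analytic ground truth.
#'
#' @param mean,sd Location and scale of the parent normal (degrees).
#' @param lo,hi Truncation bounds (degrees).
#' @return `truncated_normal_mean` returns the analytic mean of the truncated
#'   distribution; `rtruncated_normal` draws `n` samples by inverse-CDF
#'   transform (fully reproducible under `set.seed`).
#' @export
truncated_normal_mean <- function(mean, sd, lo = 0, hi = 90) {
  check_positive_scalar(sd, "sd")
  alpha <- (lo - mean) / sd
  beta <- (hi - mean) / sd
  z <- stats::pnorm(beta) - stats::pnorm(alpha)
  if (z <= 0) stop("degenerate truncation range", call. = FALSE)
  mean + sd * (stats::dnorm(alpha) - stats::dnorm(beta)) / z
}

#' @rdname truncated_normal_mean
#' @param n Number of draws.
#' @export
rtruncated_normal <- function(n, mean, sd, lo = 0, hi = 90) {
  check_positive_scalar(sd, "sd")
  pa <- stats::pnorm(lo, mean, sd)
  pb <- stats::pnorm(hi, mean, sd)
  if (pb <= pa) stop("degenerate truncation range", call. = FALSE)
  u <- stats::runif(n, pa, pb)
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic doublet set with controlled angular structure
#'
#' Emulates EdU-doublet data: polar angles to the bone axis drawn from a
#' normal(mean, sd) truncated to [0, 90] degrees, azimuths uniform, doublet
#' midpoints uniform inside the cylinder, and the two points placed half a
#' doublet length on either side of the midpoint along the sampled direction.
#' Identical seeds give byte-identical output.
#'
#' @param n Number of doublets.
#' @param mean_angle,sd_angle Truncated-normal parameters (degrees);
#'   `mean_angle` within [0, 90], `sd_angle > 0`.
#' @param doublet_length Distance between the two points (mm); default
#'   0.02 mm, the scale of two adjacent nuclei.
#' @param domain A [cylinder_spec()] defining the sampling cylinder.
#' @param group Group label stored with the records.
#' @param seed RNG seed (integer).
#' @return A [doublet_set()] with attributes `seed` and `analytic_mean` (the
#'   closed-form truncated-normal mean of the sampled angles).
#' @export
gen_doublets <- function(n, mean_angle = 70, sd_angle = 10,
                         doublet_length = 0.02,
                         domain = cylinder_spec(), group = "synthetic",
                         seed = 1L) {
  n <- check_count(n, "n", min = 1L)
  if (mean_angle < 0 || mean_angle > 90)
    stop("'mean_angle' must lie in [0, 90] degrees", call. = FALSE)
  check_positive_scalar(sd_angle, "sd_angle")
  check_positive_scalar(doublet_length, "doublet_length")
  stopifnot(inherits(domain, "cylinder_spec"))
  L <- domain$length_mm; R <- domain$radius_mm
  ds <- with_seed(seed, {
    theta <- rtruncated_normal(n, mean_angle, sd_angle, 0, 90) * pi / 180
    phi <- stats::runif(n, 0, 2 * pi)
    dir <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    rr <- R * sqrt(stats::runif(n))
    aa <- stats::runif(n, 0, 2 * pi)
    mid <- cbind(rr * cos(aa), rr * sin(aa), stats::runif(n, 0, L))
    doublet_set(mid - dir * (doublet_length / 2),
                mid + dir * (doublet_length / 2),
                group = group)
  })
  attr(ds, "seed") <- as.integer(seed)
  attr(ds, "analytic_mean") <- truncated_normal_mean(mean_angle, sd_angle, 0, 90)
  ds
}

# radius profile r(z) families for synthetic rods
profile_fun <- function(kind = c("constant", "gaussian_bulge",
                                 "gaussian_waist", "linear_taper"),
                        base_radius = 1, amplitude = 0.3, width = 2,
                        length = 10) {
  kind <- match.arg(kind)
  switch(kind,
         constant = function(z) rep_len(base_radius, length(z)),
         gaussian_bulge = function(z)
           base_radius + amplitude * exp(-((z - length / 2) / width)^2),
         gaussian_waist = function(z)
           base_radius - amplitude * exp(-((z - length / 2) / width)^2),
         linear_taper = function(z)
           base_radius + amplitude * (1 - 2 * z / length))
}

#' Triangulated surface of revolution for a radius profile
#'
#' @param r_fun Function of axial position z returning the radius (mm).
#' @param length Rod length (mm).
#' @param n_axial,n_angular Surface resolution.
#' @return Watertight, outward-oriented `tri_surface` with flat end caps.
#' @export
revolve_surface <- function(r_fun, length = 10, n_axial = 100L,
                            n_angular = 64L) {
  n_axial <- check_count(n_axial, "n_axial", min = 2L)
  n_angular <- check_count(n_angular, "n_angular", min = 6L)
  z <- seq(0, length, length.out = n_axial + 1L)
  r <- r_fun(z)
  if (any(r <= 0)) stop("radius profile non-positive along the axis",
                        call. = FALSE)
  ang <- 2 * pi * (seq_len(n_angular) - 1L) / n_angular
  nv <- (n_axial + 1L) * n_angular
  vertices <- cbind(rep(r, each = n_angular) * cos(ang),
                    rep(r, each = n_angular) * sin(ang),
                    rep(z, each = n_angular))
  vertices <- rbind(vertices, c(0, 0, 0), c(0, 0, length))
  vid <- function(layer, k) (layer - 1L) * n_angular + ((k - 1L) %% n_angular) + 1L
  k <- seq_len(n_angular)
  tris <- vector("list", n_axial + 2L)
  for (l in seq_len(n_axial)) {
    a <- vid(l, k); b <- vid(l, k + 1L)
    c_ <- vid(l + 1L, k); d <- vid(l + 1L, k + 1L)
    # outward for CCW rings viewed from +z
    tris[[l]] <- rbind(cbind(a, b, d), cbind(a, d, c_))
  }
  bot <- nv + 1L; top <- nv + 2L
  tris[[n_axial + 1L]] <- cbind(bot, vid(1L, k + 1L), vid(1L, k))   # -z cap
  tris[[n_axial + 2L]] <- cbind(top, vid(n_axial + 1L, k), vid(n_axial + 1L, k + 1L))
  tri_surface(vertices, do.call(rbind, tris))
}

#' Generate a labeled cylinder-like volume with an analytic radius profile
#'
#' Rasterizes the solid of revolution of `r(z)` into a labeled voxel volume
#' (voxel-center-in-solid inclusion rule) and returns the matching
#' triangulated surface and the analytic volume \eqn{\int_0^L \pi r(z)^2 dz}
#' so downstream quantification can be checked against closed form.
#'
#' @param kind Profile family: `"constant"`, `"gaussian_bulge"`,
#'   `"gaussian_waist"` or `"linear_taper"`.
#' @param base_radius,amplitude,width Profile parameters (mm).
#' @param length Rod length (mm).
#' @param voxel Isotropic voxel size (mm).
#' @param label Label to emit for the solid (1 = cartilage, 2 = bone).
#' @param n_axial,n_angular Resolution of the emitted surface.
#' @return List with `volume` (a [labeled_volume()]), `surface`
#'   (a `tri_surface`), `analytic_volume_mm3` and the profile function `r`.
#' @export
gen_profile_volume <- function(kind = "constant", base_radius = 1,
                               amplitude = 0.3, width = 2, length = 10,
                               voxel = 0.05, label = 1L,
                               n_axial = 100L, n_angular = 64L) {
  check_positive_scalar(voxel, "voxel")
  r_fun <- profile_fun(kind, base_radius, amplitude, width, length)
  zz <- seq(0, length, length.out = 4097L)
  if (any(r_fun(zz) <= 0))
    stop("radius profile non-positive along the axis", call. = FALSE)
  rmax <- max(r_fun(zz))
  nx <- ceiling(2 * (rmax + voxel) / voxel)
  nz <- max(1L, round(length / voxel))
  x <- (seq_len(nx) - (nx + 1) / 2) * voxel
  zc <- (seq_len(nz) - 0.5) * voxel
  r2xy <- outer(x^2, x^2, `+`)
  rz2 <- r_fun(zc)^2
  data <- array(0L, dim = c(nx, nx, nz))
  lab <- as.integer(label)
  for (kz in seq_len(nz)) {
    sl <- data[, , kz]
    sl[r2xy <= rz2[kz]] <- lab
    data[, , kz] <- sl
  }
  av <- stats::integrate(function(z) pi * r_fun(z)^2, 0, length,
                         rel.tol = 1e-10, subdivisions = 2000L)$value
  list(volume = labeled_volume(data, voxel),
       surface = revolve_surface(r_fun, length, n_axial, n_angular),
       analytic_volume_mm3 = av,
       r = r_fun)
}

#' Generate paired surfaces with a known deviation field
#'
#' Fixture pairs for exercising the nominal/actual comparison:
#' `"concentric"` builds coaxial cylinders differing by `delta_r` (expected
#' lateral deviation `delta_r` everywhere); `"bulge_vs_straight"` compares a
#' mid-shaft Gaussian bulge against the straight cylinder (expected deviation
#' peaks at `amplitude` mid-shaft, where the profile slope vanishes).
#'
#' @param kind `"concentric"` or `"bulge_vs_straight"`.
#' @param delta_r Radius offset for `"concentric"` (mm).
#' @param amplitude,width Bulge parameters (mm).
#' @param base_radius,length Cylinder geometry (mm).
#' @param n_axial,n_angular Surface resolution.
#' @return List with `test`, `reference` (`tri_surface`), `expected`
#'   (closed-form deviation at each lateral test vertex; `NA` on caps) and
#'   `lateral` (the test-vertex mask).
#' @export
gen_surface_pair <- function(kind = c("concentric", "bulge_vs_straight"),
                             delta_r = 0.2, amplitude = 0.3, width = 2,
                             base_radius = 1, length = 10,
                             n_axial = 100L, n_angular = 64L) {
  kind <- match.arg(kind)
  ref_fun <- profile_fun("constant", base_radius, length = length)
  reference <- revolve_surface(ref_fun, length, n_axial, n_angular)
  if (kind == "concentric") {
    if (base_radius + delta_r <= 0)
      stop("'delta_r' collapses the cylinder", call. = FALSE)
    test_fun <- profile_fun("constant", base_radius + delta_r, length = length)
    test <- revolve_surface(test_fun, length, n_axial, n_angular)
    lateral <- lateral_vertex_mask(test)
    expected <- ifelse(lateral, abs(delta_r), NA_real_)
  } else {
    test_fun <- profile_fun("gaussian_bulge", base_radius, amplitude, width,
                            length)
    test <- revolve_surface(test_fun, length, n_axial, n_angular)
    lateral <- lateral_vertex_mask(test)
    z <- test$vertices[, 3L]
    expected <- ifelse(lateral, test_fun(z) - base_radius, NA_real_)
  }
  list(test = test, reference = reference, expected = expected,
       lateral = lateral)
}
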