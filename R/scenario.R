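#' Build a named loading scenario
#'
#' Two configurations contrast how a rod-shaped skeletal element grows:
#'
#' * `"regeneration"` — every axial region receives the same axial and radial
#'   force densities (growth driven purely by cartilage expansion, with
#'   ossification delayed until after shaping).
#' * `"development"` — radial force densities ramp up symmetrically from the
#'   central region towards both ends: early cortical ossification in the
#'   mid-shaft mechanically suppresses transversal expansion there. Region k
#'   of K receives `f_radial0 * ramp(k)` where the ramp equals
#'   `center_fraction` at the central region and 1 at the two end regions,
#'   linear (default) or geometric in region index. Axial densities are the
#'   same everywhere in both configurations.
#'
#' @param name `"regeneration"`, `"development"` or `"custom"`.
#' @param f_axial0 Base axial force density (kPa/mm).
#' @param f_radial0 Base radial force density (kPa/mm).
#' @param partition A [region_partition()].
#' @param center_fraction For development: ramp value at the central region,
#'   in (0, 1]. `center_fraction = 1` degenerates to the uniform
#'   (regeneration) loading.
#' @param ramp `"linear"` or `"geometric"` ramp shape.
#' @param mat A [material()].
#' @param f_radial For `name = "custom"`: explicit per-region radial
#'   densities.
#' @param normalization Target maximum displacement as a fraction of the
#'   cylinder radius used when a simulation auto-scales the loads (keeps the
#'   small-strain assumption; default 0.2).
#' @return Object of class `scenario`.
#' @examples
#' make_scenario("development", center_fraction = 0.2)$loads$f_radial
#' @export
make_scenario <- function(name = c("regeneration", "development", "custom"),
                          f_axial0 = 0.1, f_radial0 = 1,
                          partition = region_partition(),
                          center_fraction = 0.2,
                          ramp = c("linear", "geometric"),
                          mat = material(),
                          f_radial = NULL,
                          normalization = 0.2) {
  name <- match.arg(name)
  ramp <- match.arg(ramp)
  stopifnot(inherits(partition, "region_partition"), inherits(mat, "material"))
  K <- partition$n_regions
  if (name == "development") {
    if (center_fraction <= 0 || center_fraction > 1)
      stop("'center_fraction' must lie in (0, 1]: got ",
           format(center_fraction), call. = FALSE)
    if (K < 3L)
      stop("development scenario needs at least 3 regions ",
           "(radial gradient undefined for ", K, ")", call. = FALSE)
    fr <- f_radial0 * region_ramp(K, center_fraction, ramp)
  } else if (name == "regeneration") {
    fr <- rep(f_radial0, K)
  } else {
    if (is.null(f_radial) || length(f_radial) != K)
      stop("custom scenario needs 'f_radial' with one value per region",
           call. = FALSE)
    fr <- as.numeric(f_radial)
  }
  structure(list(name = name,
                 partition = partition,
                 loads = region_loading(rep(f_axial0, K), fr),
                 material = mat,
                 constraints = "default",
                 normalization = normalization,
                 center_fraction = if (name == "development") center_fraction else NA_real_,
                 ramp = if (name == "development") ramp else NA_character_),
            class = "scenario")
}

# symmetric ramp over region index: value `c` at the center, 1 at both ends
region_ramp <- function(K, c, kind = "linear") {
  k <- seq_len(K)
  s <- abs(2 * k - (K + 1)) / (K - 1)   # 0 at center, 1 at the ends
  switch(kind,
         linear = c + (1 - c) * s,
         geometric = c^(1 - s),
         stop("unknown ramp kind: ", kind, call. = FALSE))
}

#' @export
print.scenario <- function(x, ...) {
  cat("Scenario '", x$name, "': ", x$partition$n_regions, " regions\n",
      sep = "")
  cat("  f_axial :", paste(format(x$loads$f_axial, digits = 4), collapse = " "), "\n")
  cat("  f_radial:", paste(format(x$loads$f_radial, digits = 4), collapse = " "), "\n")
  invisible(x)
}

# per-region tet volume totals, checked against the scenario partition
region_volumes <- function(mesh, n_regions) {
  if (max(mesh$region) > n_regions)
    stop("mesh regions do not match scenario partition (mesh has region ",
         max(mesh$region), ", scenario has ", n_regions, ")", call. = FALSE)
  vol <- tet_volumes(mesh)
  vapply(seq_len(n_regions),
         function(k) sum(vol[mesh$region == k]), numeric(1))
}

#' Total radial impulse of a scenario on a mesh
#'
#' \eqn{\sum_k |f_r(k)| V_k} over regions: the volume-weighted magnitude of
#' the radial loading, used to compare scenarios at matched radial "budget".
#'
#' @param scenario A [make_scenario()] result.
#' @param mesh A `tet_mesh` with regions assigned to the same partition.
#' @return Non-negative scalar (kPa mm^2); zero iff all radial densities are
#'   zero.
#' @export
total_radial_impulse <- function(scenario, mesh) {
  stopifnot(inherits(scenario, "scenario"), inherits(mesh, "tet_mesh"))
  V <- region_volumes(mesh, scenario$partition$n_regions)
  sum(abs(scenario$loads$f_radial) * V)
}

#' Rescale a scenario's radial loading to match a reference impulse
#'
#' Multiplies all radial densities by one factor so that
#' [total_radial_impulse()] equals that of `reference` on the same mesh,
#' enabling the matched-load development-versus-regeneration contrast.
#'
#' @param scenario Scenario to rescale.
#' @param reference Scenario providing the target impulse.
#' @param mesh The shared `tet_mesh`.
#' @return The rescaled scenario.
#' @export
match_radial_impulse <- function(scenario, reference, mesh) {
  target <- total_radial_impulse(reference, mesh)
  own <- total_radial_impulse(scenario, mesh)
  if (own == 0) stop("cannot match impulse: scenario has zero radial loading",
                     call. = FALSE)
  scenario$loads$f_radial <- scenario$loads$f_radial * (target / own)
  scenario
}

#' Write / read a scenario file (YAML)
#'
#' Declarative scenario files with `geometry`-independent loading tables:
#' regions, per-region axial/radial force densities, material and
#' normalization. Numbers are written with full precision so that
#' `read_scenario(write_scenario(s))` reproduces an identical object.
#'
#' @param scenario A `scenario`.
#' @param path Output file path.
#' @return `write_scenario` returns `path` invisibly; `read_scenario` returns
#'   the `scenario`.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario"))
  obj <- list(
    name = scenario$name,
    regions = list(boundaries = fmt_full(scenario$partition$boundaries)),
    loads = list(f_axial = fmt_full(scenario$loads$f_axial),
                 f_radial = fmt_full(scenario$loads$f_radial)),
    material = list(young_modulus = fmt_full(scenario$material$young_modulus),
                    poisson_ratio = fmt_full(scenario$material$poisson_ratio)),
    constraints = scenario$constraints,
    normalization = fmt_full(scenario$normalization),
    center_fraction = fmt_full(scenario$center_fraction),
    ramp = scenario$ramp)
  writeLines(yaml::as.yaml(obj), path)
  invisible(path)
}

# full-precision decimal strings survive the YAML round trip exactly
fmt_full <- function(x) {
  if (is.null(x)) return(NULL)
  ifelse(is.finite(x), sprintf("%.17g", x), "NA")
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  obj <- yaml::read_yaml(path)
  part <- region_partition(as.numeric(obj$regions$boundaries))
  cf <- suppressWarnings(as.numeric(obj$center_fraction))
  sc <- structure(list(
    name = obj$name,
    partition = part,
    loads = region_loading(as.numeric(obj$loads$f_axial),
                           as.numeric(obj$loads$f_radial)),
    material = material(as.numeric(obj$material$young_modulus),
                        as.numeric(obj$material$poisson_ratio)),
    constraints = obj$constraints,
    normalization = as.numeric(obj$normalization),
    center_fraction = cf,
    ramp = if (is.null(obj$ramp) || is.na(obj$ramp)) NA_character_ else obj$ramp),
    class = "scenario")
  sc
}
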