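#' Axial angle of a cell-division doublet
#'
#' Angle between the doublet axis (the segment joining the two daughter
#' nuclei) and the bone axis, folded into [0, 90] degrees: division direction
#' is sign-less (axial data), so a doublet and its reverse give the same
#' angle. 0 = longitudinal, 90 = transversal.
#'
#' @param point_a,point_b Length-3 coordinates (mm) of the two points, or
#'   n x 3 matrices for vectorized use.
#' @param axis Bone axis direction (normalized internally).
#' @return Angle(s) in degrees in [0, 90].
#' @examples
#' doublet_angle(c(0, 0, 0), c(1, 0, 1), c(0, 0, 1))  # 45
#' @export
doublet_angle <- function(point_a, point_b, axis = c(0, 0, 1)) {
  a <- rbind(point_a); b <- rbind(point_b)
  axis <- unit_vector(as.numeric(axis))
  d <- b - a
  nd <- sqrt(rowSums(d^2))
  if (any(nd == 0))
    stop("coincident doublet points (zero-length division axis)",
         call. = FALSE)
  cosang <- abs(drop(d %*% axis)) / nd
  unname(acos(pmin(pmax(cosang, 0), 1)) * 180 / pi)
}

#' Doublet point-pair set
#'
#' @param point_a,point_b n x 3 matrices of paired coordinates (mm); n x 2
#'   matrices (tissue-section data) are zero-padded in z, in which case the
#'   axis must lie in the section plane.
#' @param group Group label per record (e.g. developmental stage or cell
#'   type), recycled.
#' @param axis,origin Anatomical bone-axis definition.
#' @param id Optional record identifiers.
#' @return Object of class `doublet_set` (a data.frame with columns
#'   `id, ax, ay, az, bx, by, bz, group` and axis attributes).
#' @export
doublet_set <- function(point_a, point_b, group = "all",
                        axis = c(0, 0, 1), origin = c(0, 0, 0), id = NULL) {
  point_a <- as.matrix(point_a); point_b <- as.matrix(point_b)
  if (ncol(point_a) == 2L && ncol(point_b) == 2L) {
    if (length(axis) == 2L) axis <- c(axis, 0)
    if (length(origin) == 2L) origin <- c(origin, 0)
    if (abs(axis[3L]) > 1e-12)
      stop("2-D section doublets require an in-plane axis (zero z component)",
           call. = FALSE)
    point_a <- cbind(point_a, 0)
    point_b <- cbind(point_b, 0)
  }
  stopifnot(ncol(point_a) == 3L, ncol(point_b) == 3L,
            nrow(point_a) == nrow(point_b))
  if (any(rowSums((point_a - point_b)^2) == 0))
    stop("doublet with coincident points", call. = FALSE)
  n <- nrow(point_a)
  if (is.null(id)) id <- seq_len(n)
  df <- data.frame(id = id,
                   ax = point_a[, 1L], ay = point_a[, 2L], az = point_a[, 3L],
                   bx = point_b[, 1L], by = point_b[, 2L], bz = point_b[, 3L],
                   group = rep_len(as.character(group), n),
                   stringsAsFactors = FALSE)
  attr(df, "axis") <- unit_vector(as.numeric(axis))
  attr(df, "origin") <- as.numeric(origin)
  class(df) <- c("doublet_set", "data.frame")
  df
}

#' Angles of all doublets in a set
#'
#' @param doublets A [doublet_set()].
#' @return Numeric vector of axial angles (degrees).
#' @export
doublet_angles <- function(doublets) {
  stopifnot(inherits(doublets, "doublet_set"))
  doublet_angle(as.matrix(doublets[, c("ax", "ay", "az")]),
                as.matrix(doublets[, c("bx", "by", "bz")]),
                attr(doublets, "axis"))
}

#' Summarize division-orientation angles
#'
#' @param angles Numeric vector of axial angles in degrees, within [0, 90].
#' @param threshold Angle (degrees) above which a division counts as
#'   transversal; default 45 (the quadrant midpoint).
#' @return Object of class `orientation_summary` with `n`, `mean`, `median`,
#'   `q1`, `q3` (linear-interpolation quartiles), `sd` and
#'   `fraction_transversal`.
#' @export
summarize_orientations <- function(angles, threshold = 45) {
  if (!length(angles)) stop("empty angle vector", call. = FALSE)
  if (any(!is.finite(angles)) || any(angles < 0 | angles > 90))
    stop("angles must be finite and within [0, 90] degrees", call. = FALSE)
  q <- unname(stats::quantile(angles, c(0.25, 0.5, 0.75), type = 7))
  structure(list(n = length(angles),
                 mean = mean(angles),
                 median = q[2L], q1 = q[1L], q3 = q[3L],
                 sd = stats::sd(angles),
                 threshold = threshold,
                 fraction_transversal = mean(angles > threshold)),
            class = "orientation_summary")
}

#' @export
print.orientation_summary <- function(x, ...) {
  cat(sprintf(
    "Orientation summary: n = %d, mean %.2f deg, median %.2f (Q1 %.2f, Q3 %.2f), sd %.2f\n",
    x$n, x$mean, x$median, x$q1, x$q3, if (is.na(x$sd)) 0 else x$sd))
  cat(sprintf("  fraction transversal (> %g deg): %.3f\n",
              x$threshold, x$fraction_transversal))
  invisible(x)
}

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Two-group comparison of orientation angles
#'
#' Welch's unequal-variance two-tailed t-test (via [stats::t.test()]) or a
#' two-tailed permutation test on the Welch t statistic with the add-one
#' correction \eqn{p = (b + 1)/(m + 1)}, where b counts permuted statistics
#' at least as extreme as the observed one. The permutation test is the
#' distribution-free alternative appropriate for bounded angle data.
#'
#' @param angles_a,angles_b Numeric angle vectors (each n >= 2).
#' @param method `"welch_t"` or `"permutation"`.
#' @param n_perm Number of permutation resamples (>= 10000 recommended).
#' @param seed RNG seed for the permutation draw (required for
#'   reproducibility; ignored by `welch_t`).
#' @return Object of class `orientation_test`: `statistic`, `p_value`,
#'   `method`, `n` (group sizes), and for permutation `n_perm` and `seed`.
#' @export
compare_groups <- function(angles_a, angles_b,
                           method = c("welch_t", "permutation"),
                           n_perm = 10000L, seed = NULL) {
  method <- match.arg(method)
  a <- as.numeric(angles_a); b <- as.numeric(angles_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (method == "welch_t") {
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      if (isTRUE(all.equal(mean(a), mean(b))))
        return(structure(list(statistic = 0, p_value = 1,
                              method = "welch_t", n = c(length(a), length(b))),
                         class = "orientation_test"))
      stop("both groups have zero variance; Welch t is undefined - ",
           "use method = 'permutation'", call. = FALSE)
    }
    tt <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
    structure(list(statistic = unname(tt$statistic),
                   p_value = tt$p.value,
                   df = unname(tt$parameter),
                   method = "welch_t", n = c(length(a), length(b))),
              class = "orientation_test")
  } else {
    n_perm <- check_count(n_perm, "n_perm", min = 1L)
    na <- length(a); nb <- length(b)
    pooled <- c(a, b)
    obs <- welch_stat(a, b)
    # resamples drawn in bounded chunks so very large n_perm (needed to
    # resolve small p with the add-one correction) stays within memory
    bcount <- with_seed(seed, {
      n <- length(pooled)
      left <- n_perm; hits <- 0
      while (left > 0L) {
        m <- as.integer(min(left, 100000L))
        # one radix sort of column-offset keys yields m independent
        # permutations at once (much faster than per-column order())
        colid <- rep(seq_len(m), each = n)
        o <- order(colid + 0.5 * stats::runif(n * m), method = "radix")
        pos <- o - (colid - 1L) * n          # within-column permuted rows
        xp <- matrix(pooled[pos], nrow = n)
        xa <- xp[seq_len(na), , drop = FALSE]
        xb <- xp[na + seq_len(nb), , drop = FALSE]
        hits <- hits + sum(abs(welch_stat_cols(xa, xb)) >= abs(obs) - 1e-12)
        left <- left - m
      }
      hits
    })
    structure(list(statistic = obs,
                   p_value = (bcount + 1) / (n_perm + 1),
                   method = "permutation", n = c(na, nb),
                   n_perm = n_perm, seed = seed),
              class = "orientation_test")
  }
}

welch_stat <- function(a, b) {
  (mean(a) - mean(b)) /
    sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
}

# Welch t statistic per column of two matrices (groups in columns' rows)
welch_stat_cols <- function(xa, xb) {
  na <- nrow(xa); nb <- nrow(xb)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- (colSums(xa^2) - na * ma^2) / (na - 1)
  vb <- (colSums(xb^2) - nb * mb^2) / (nb - 1)
  (ma - mb) / sqrt(va / na + vb / nb)
}

#' @export
print.orientation_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %d vs %d)\n",
              x$method, x$statistic, x$p_value, x$n[1L], x$n[2L]))
  invisible(x)
}
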