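# Independent oracles used across the test files. These deliberately take
# different computational routes than the package implementation.

# P1 element stiffness via the explicit strain-displacement (B) matrix and
# the 6x6 Voigt elasticity matrix: K = V * B' D B.
oracle_element_stiffness <- function(coords, E, nu) {
  e2 <- coords[2, ] - coords[1, ]
  e3 <- coords[3, ] - coords[1, ]
  e4 <- coords[4, ] - coords[1, ]
  M <- cbind(e2, e3, e4)
  V <- det(M) / 6
  G <- solve(t(M))                       # columns: grad lambda_2..4
  g <- cbind(-rowSums(G), G)             # grad lambda_1 = -sum
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- g[1, a]
    B[2, c0 + 2] <- g[2, a]
    B[3, c0 + 3] <- g[3, a]
    B[4, c0 + 1] <- g[2, a]; B[4, c0 + 2] <- g[1, a]
    B[5, c0 + 2] <- g[3, a]; B[5, c0 + 3] <- g[2, a]
    B[6, c0 + 1] <- g[3, a]; B[6, c0 + 3] <- g[1, a]
  }
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D) <- c(rep(lam + 2 * mu, 3), rep(mu, 3))
  V * t(B) %*% D %*% B
}

# Exact closest point on one triangle by Eberly's region decomposition of
# the quadratic |A + s E0 + t E1 - P|^2 over the simplex.
oracle_point_triangle <- function(p, a, b, c) {
  e0 <- b - a; e1 <- c - a; d <- a - p
  A <- sum(e0 * e0); B <- sum(e0 * e1); C <- sum(e1 * e1)
  D <- sum(e0 * d); E <- sum(e1 * d)
  det <- A * C - B * B
  s <- B * E - C * D; t <- B * D - A * E
  if (s + t <= det) {
    if (s < 0) {
      if (t < 0) {           # region 4
        if (D < 0) { t <- 0; s <- min(max(-D / A, 0), 1) }
        else { s <- 0; t <- min(max(-E / C, 0), 1) }
      } else {               # region 3
        s <- 0; t <- min(max(-E / C, 0), 1)
      }
    } else if (t < 0) {      # region 5
      t <- 0; s <- min(max(-D / A, 0), 1)
    } else {                 # region 0
      s <- s / det; t <- t / det
    }
  } else {
    if (s < 0) {             # region 2
      tmp0 <- B + D; tmp1 <- C + E
      if (tmp1 > tmp0) {
        numer <- tmp1 - tmp0
        s <- min(max(numer / (A - 2 * B + C), 0), 1); t <- 1 - s
      } else { s <- 0; t <- min(max(-E / C, 0), 1) }
    } else if (t < 0) {      # region 6
      tmp0 <- B + E; tmp1 <- A + D
      if (tmp1 > tmp0) {
        numer <- tmp1 - tmp0
        t <- min(max(numer / (A - 2 * B + C), 0), 1); s <- 1 - t
      } else { t <- 0; s <- min(max(-D / A, 0), 1) }
    } else {                 # region 1
      numer <- (C + E) - (B + D)
      s <- min(max(numer / (A - 2 * B + C), 0), 1); t <- 1 - s
    }
  }
  cp <- a + s * e0 + t * e1
  sqrt(sum((p - cp)^2))
}

# brute-force distance from points to every triangle of a surface
oracle_surface_distance <- function(points, surface) {
  v <- surface$vertices; tr <- surface$triangles
  apply(points, 1, function(p) {
    min(vapply(seq_len(nrow(tr)), function(k) {
      oracle_point_triangle(p, v[tr[k, 1], ], v[tr[k, 2], ], v[tr[k, 3], ])
    }, numeric(1)))
  })
}

# truncated-normal mean by numerical integration (independent of the
# package's closed form)
oracle_truncnorm_mean <- function(mean, sd, lo = 0, hi = 90) {
  z <- stats::integrate(function(x) stats::dnorm(x, mean, sd), lo, hi,
                        rel.tol = 1e-12)$value
  stats::integrate(function(x) x * stats::dnorm(x, mean, sd), lo, hi,
                   rel.tol = 1e-12)$value / z
}

# small structured meshes shared across tests
small_mesh <- function(n_axial = 8, n_radial = 2, n_angular = 8,
                       L = 10, R = 1) {
  build_cylinder_mesh(cylinder_spec(L, R, n_axial, n_radial, n_angular))
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_q) < 0) qr_q[, 1] <- -qr_q[, 1]
  qr_q
}
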