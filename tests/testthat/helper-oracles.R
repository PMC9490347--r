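# Small independent oracles used across the suite. Everything here is
# deliberately written from first principles (plain loops, no reuse of the
# package's vectorized/compiled paths) so that agreement is meaningful.

# central finite differences of the total energy
fd_gradient <- function(params, theta, h = 1e-6) {
  g <- theta * 0
  for (i in seq_len(nrow(theta))) {
    for (j in seq_len(ncol(theta))) {
      tp <- theta; tp[i, j] <- tp[i, j] + h
      tm <- theta; tm[i, j] <- tm[i, j] - h
      g[i, j] <- (bundle_energy(params, tp)$total -
                    bundle_energy(params, tm)$total) / (2 * h)
    }
  }
  g
}

# node coordinates by direct per-filament accumulation
oracle_coords <- function(params, theta) {
  l <- params$L / params$n
  d0 <- params$W / (params$m - 1)
  x <- matrix(0, params$m, params$n + 1)
  y <- matrix(0, params$m, params$n + 1)
  for (i in seq_len(params$m)) {
    y[i, 1] <- (i - 1) * d0
    for (j in seq_len(params$n)) {
      x[i, j + 1] <- x[i, j] + l * cos(theta[i, j])
      y[i, j + 1] <- y[i, j] + l * sin(theta[i, j])
    }
  }
  list(x = x, y = y)
}

# shoelace triangle area from three vertices
shoelace <- function(p0, p1, p2) {
  abs(p0[1] * (p1[2] - p2[2]) + p1[1] * (p2[2] - p0[2]) +
        p2[1] * (p0[2] - p1[2])) / 2
}

# interaction energy computed directly from a coordinate list (used to
# finite-difference the pressure field with respect to node positions)
oracle_interaction_energy <- function(params, coords) {
  m <- params$m; n <- params$n
  l <- params$L / params$n
  Ks <- params$K / params$L
  d0 <- params$W / (m - 1)
  dd <- sqrt(d0^2 + l^2)
  A0 <- l / (2 * (m - 1))
  E <- 0
  for (i in seq_len(m - 1)) {
    for (j in 0:n) {
      d <- sqrt((coords$x[i + 1, j + 1] - coords$x[i, j + 1])^2 +
                  (coords$y[i + 1, j + 1] - coords$y[i, j + 1])^2)
      E <- E + l * Ks / 2 * ((d - d0) / d0)^2
    }
    for (j in 0:(n - 1)) {  # "+" diagonal
      d <- sqrt((coords$x[i + 1, j + 2] - coords$x[i, j + 1])^2 +
                  (coords$y[i + 1, j + 2] - coords$y[i, j + 1])^2)
      E <- E + l * Ks / 2 * ((d - dd) / dd)^2
    }
    for (j in 1:n) {  # "-" diagonal
      d <- sqrt((coords$x[i + 1, j] - coords$x[i, j + 1])^2 +
                  (coords$y[i + 1, j] - coords$y[i, j + 1])^2)
      E <- E + l * Ks / 2 * ((d - dd) / dd)^2
    }
    for (j in 0:(n - 1)) {  # overlap triangles of quad (i, j)
      p0 <- c(coords$x[i, j + 1], coords$y[i, j + 1])
      p1 <- c(coords$x[i + 1, j + 1], coords$y[i + 1, j + 1])
      p2 <- c(coords$x[i + 1, j + 2], coords$y[i + 1, j + 2])
      p3 <- c(coords$x[i, j + 2], coords$y[i, j + 2])
      A1 <- shoelace(p0, p1, p2)
      A2 <- abs((p2[1] - p3[1]) * (p2[2] - p0[2]) -
                  (p2[2] - p3[2]) * (p2[1] - p0[1])) / 2
      E <- E + params$C1 * exp(-params$C2 * A1 / A0) +
        params$C1 * exp(-params$C2 * A2 / A0)
    }
  }
  E
}

# quadrature oracle for the kink spring energy: 6n copies of the half-flank
# integral of the per-unit-length Hookean density, d(x) linear in x; the
# m_factor scales both the deformation and the rest separation (lateral
# neighbour decay), which must cancel in the strain ratio
kink_spring_quadrature <- function(Delta, K, L, n, m_factor = 1) {
  d0 <- 1 / 2
  D <- sqrt(Delta * (2 * L - Delta)) / (2 * n)
  lt <- (L - Delta) / (2 * n)
  integrand <- function(x) {
    d <- x * 2 * n * D / (L - Delta) * m_factor + d0 * m_factor
    (K / 2) * ((d - d0 * m_factor) / (d0 * m_factor))^2 / L
  }
  6 * n * stats::integrate(integrand, 0, lt, rel.tol = 1e-12)$value
}

# a small random state drawn reproducibly without touching the global RNG
random_state <- function(params, amplitude = 0.1, seed = 1) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  matrix(stats::runif(params$m * params$n, -amplitude, amplitude),
         params$m, params$n)
}

small_params <- function(...) {
  bundle_params(m = 4, n = 12, L = 5, K = 2, ...)
}
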