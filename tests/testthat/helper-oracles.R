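# Independent brute-force oracles used across the solver tests. These
# deliberately re-derive the physics with plain dense linear algebra so
# they share no code with the FFT/Krylov implementation they check.

# Retarded (or static) point-dipole field tensor, 3x3, Gaussian
# convention: E = G(r) p for a dipole p at the origin observed at r.
dense_green <- function(d, k, static = FALSE) {
  r <- sqrt(sum(d^2))
  if (r == 0) return(matrix(0 + 0i, 3, 3))
  u <- d / r
  if (static) {
    ff <- 0 + 0i
    fn <- 1 / r^3
  } else {
    ph <- exp(1i * k * r)
    ff <- ph * k^2 / r
    fn <- ph * (1 / r^3 - 1i * k / r^2)
  }
  ff * (diag(3) - outer(u, u)) + fn * (3 * outer(u, u) - diag(3))
}

# Direct dense solve of the coupled-dipole system (with optional
# quasi-static image term for an interface at z = z0 with reflection
# factor refl): returns the n x 3 dipole moments.
dense_dda_solve <- function(coords, alpha, k, Einc, refl = 0, z0 = NULL) {
  n <- nrow(coords)
  A <- matrix(0 + 0i, 3 * n, 3 * n)
  M <- diag(c(-1, -1, 1)) * refl
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      blk <- if (i == j) matrix(0 + 0i, 3, 3)
             else dense_green(coords[i, ] - coords[j, ], k)
      if (!is.null(z0) && refl != 0) {
        di <- c(coords[i, 1] - coords[j, 1], coords[i, 2] - coords[j, 2],
                coords[i, 3] + coords[j, 3] - 2 * z0)
        blk <- blk + dense_green(di, k, static = TRUE) %*% M
      }
      A[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)] <-
        -alpha[i] * blk + if (i == j) diag(3) else 0
    }
  }
  ev <- as.vector(t(Einc))
  pv <- solve(A, ev)
  t(matrix(pv, nrow = 3)) * alpha
}

# Rayleigh-limit cross sections of a small sphere (radius nm, k in the
# ambient medium 1/nm, epsr relative to the ambient) in nm2.
rayleigh_cross_sections <- function(radius, epsr, k) {
  pol <- radius^3 * (epsr - 1) / (epsr + 2)
  list(C_scat = (8 / 3) * pi * k^4 * Mod(pol)^2,
       C_abs = 4 * pi * k * Im(pol))
}

# Monte-Carlo volume of a membership predicate within a bounding box.
mc_volume <- function(contains, center, half, n = 4e5, seed = 42) {
  withr::with_seed(seed, {
    pts <- cbind(stats::runif(n, center[1] - half, center[1] + half),
                 stats::runif(n, center[2] - half, center[2] + half),
                 stats::runif(n, center[3] - half, center[3] + half))
  })
  mean(contains(pts)) * (2 * half)^3
}

# analytic Lorentzian helper
lorentz <- function(wl, l0, g, a, b = 0) {
  b + a * (g / 2)^2 / ((wl - l0)^2 + (g / 2)^2)
}

# shared small settings for solver tests
fast_settings <- function(tol = 1e-5) solver_settings(tol = tol)
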