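# Shared fixtures, built once per test run.

# Gauss-Legendre nodes/weights on [-1, 1] via Golub-Welsch; used as the
# independent quadrature oracle for sphere integrals.
gauss_legendre <- function(n) {
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

# Product quadrature over the sphere: integrates f(theta, phi) dOmega.
sphere_quadrature <- function(n_theta = 40, n_phi = 80) {
  gl <- gauss_legendre(n_theta)
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  grid <- expand.grid(x = gl$nodes, phi = phi)
  list(theta = acos(grid$x), phi = grid$phi,
       w = rep(gl$weights, times = n_phi) * (2 * pi / n_phi))
}

# Small shared meshes/fixtures (memoised at file scope).
param_small <- icosphere_param(2)   # 162 vertices / hemisphere
param_tiny <- icosphere_param(1)    # 42 vertices / hemisphere

# A band-limited random surface with positive radius, for round trips.
random_surface <- function(param, degree, seed = 1, sigma = 0) {
  set.seed(seed)
  k <- (degree + 1L)^2
  co <- array(rnorm(2 * 3 * k, sd = 2), c(2, 3, k))
  co[, , 1] <- co[, , 1] + 70 * 2 * sqrt(pi)   # keep hemispheres offset/round
  co[1, 1, 1] <- -70 * 2 * sqrt(pi)
  reconstruct(wfs_coefficients(co, degree, sigma), param)
}

small_library <- function(Nb = 8, degree = 8, seed = 3, param = param_tiny) {
  generate_library(Nb = Nb, degree = degree, seed = seed, param = param)
}
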