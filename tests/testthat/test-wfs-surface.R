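# Spherical-harmonic basis and WFS fitting/reconstruction.

test_that("closed-form harmonic values and domain errors", {
  expect_equal(sph_harm_real(0, 0, 0.7, 2.1), 1 / (2 * sqrt(pi)))
  expect_equal(sph_harm_real(1, 0, 0, 0), sqrt(3 / (4 * pi)))
  # explicit l=1 forms at a generic angle
  th <- 1.1; ph <- -0.6
  expect_equal(sph_harm_real(1, 1, th, ph),
               sqrt(3 / (4 * pi)) * sin(th) * cos(ph))
  expect_equal(sph_harm_real(1, -1, th, ph),
               sqrt(3 / (4 * pi)) * sin(th) * sin(ph))
  expect_error(sph_harm_real(1, 2, 0, 0), "\\|m\\|")
})

test_that("basis is orthonormal under the quadrature oracle", {
  q <- sphere_quadrature(30, 60)
  lmax <- 8
  B <- vapply(0:((lmax + 1)^2 - 1), function(k) {
    l <- floor(sqrt(k)); m <- k - l^2 - l
    sph_harm_real(l, m, q$theta, q$phi)
  }, numeric(length(q$theta)))
  G <- crossprod(B * q$w, B)   # integral Y_i Y_j dOmega
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-6)
})

test_that("basis_matrix layout, counts and Gram structure", {
  p <- param_small
  B0 <- basis_matrix(p, 0)
  expect_equal(dim(B0), c(p$vertex_count, 1L))
  expect_true(all(abs(B0 - 1 / (2 * sqrt(pi))) < 1e-15))
  expect_equal(ncol(basis_matrix(p, 20)), 441L)
  # lexicographic layout: column l^2+l+m+1 equals the scalar evaluator
  B <- basis_matrix(p, 4)
  for (lm in list(c(2, -1), c(3, 2), c(4, -4))) {
    expect_equal(B[, lm[1]^2 + lm[1] + lm[2] + 1],
                 sph_harm_real(lm[1], lm[2], p$theta, p$phi))
  }
  # near-uniform mesh: B'B ~ (Nd / 4 pi) I, off-diagonal leakage < 5%
  p2 <- icosphere_param(3)
  B <- basis_matrix(p2, 6)
  G <- crossprod(B) * 4 * pi / p2$vertex_count
  expect_lt(max(abs(G - diag(diag(G)))), 0.05)
  expect_lt(max(abs(diag(G) - 1)), 0.05)
  expect_error(basis_matrix(p, -1), "degree")
})

test_that("count_coefficients follows 6(c+1)^2", {
  expect_identical(count_coefficients(20), 2646L)
  expect_identical(count_coefficients(0), 6L)
  expect_identical(count_coefficients(9), 600L)
  for (c in 0:30) expect_identical(count_coefficients(c), as.integer(6 * (c + 1)^2))
  expect_error(count_coefficients(-1))
})

test_that("sphere fits are pure degree-1 plus centre monopole", {
  # a hemisphere sphere of radius r centred at c: f_00 = c * 2 sqrt(pi)
  # per axis, |f_1m| = r * sqrt(4 pi / 3) on the matching axis
  p <- param_small
  r <- 10; ctr <- c(4, -7, 11)
  v <- sweep(r * cbind(sin(p$theta) * cos(p$phi), sin(p$theta) * sin(p$phi),
                       cos(p$theta)), 2, ctr, `+`)
  s <- cortical_surface(rbind(v, v), p)
  f <- fit_wfs(s, p, 4, sigma = 0)
  for (ax in 1:3) {
    expect_equal(f$coeff[1, ax, 1], ctr[ax] * 2 * sqrt(pi), tolerance = 1e-9)
  }
  expect_equal(f$coeff[1, 1, lm_index(1, 1)], r * sqrt(4 * pi / 3), tolerance = 1e-9)
  expect_equal(f$coeff[1, 2, lm_index(1, -1)], r * sqrt(4 * pi / 3), tolerance = 1e-9)
  expect_equal(f$coeff[1, 3, lm_index(1, 0)], r * sqrt(4 * pi / 3), tolerance = 1e-9)
  # everything above degree 1 vanishes
  expect_lt(max(abs(f$coeff[, , 5:25])), 1e-9)
})

test_that("fit/reconstruct round trip is exact on band-limited surfaces", {
  p <- param_small
  s <- random_surface(p, 6, seed = 2)
  f <- fit_wfs(s, p, 6, sigma = 0)
  s2 <- reconstruct(f, p)
  expect_lt(max(abs(s2$vertices - s$vertices)), 1e-8)
  # nesting: residual never increases with degree; under-fitting larger
  s25 <- random_surface(p, 10, seed = 5)
  res <- vapply(c(4, 6, 8, 10), function(cdeg) {
    r <- reconstruct(fit_wfs(s25, p, cdeg, sigma = 0), p)
    sqrt(mean((r$vertices - s25$vertices)^2))
  }, numeric(1))
  expect_true(all(diff(res) < 1e-12))
  expect_gt(res[1], res[4])
})

test_that("smoothing weights act at reconstruction and degree limits error", {
  p <- param_tiny
  s <- random_surface(p, 4, seed = 7)
  f0 <- fit_wfs(s, p, 4, sigma = 0)
  fs <- fit_wfs(s, p, 4, sigma = 1e-3)
  # weighted fit compensates the weight: reconstruction agrees either way
  expect_lt(max(abs(reconstruct(fs, p)$vertices - reconstruct(f0, p)$vertices)), 1e-6)
  # stored coefficients differ by the inverse heat-kernel factor
  l <- 4
  w <- exp(-l * (l + 1) * 1e-3)
  expect_equal(fs$coeff[1, 1, 25], f0$coeff[1, 1, 25] / w, tolerance = 1e-6)
  expect_error(fit_wfs(s, p, 7, sigma = 0), "underdetermined")
})

test_that("reconstruct warns on all-zero coefficients", {
  z <- wfs_coefficients(array(0, c(2, 3, 4)), 1, 0)
  expect_warning(s <- reconstruct(z, param_tiny), "degenerate")
  expect_true(all(s$vertices == 0))
})

test_that("OBJ round trip preserves vertices", {
  p <- param_tiny
  s <- random_surface(p, 3, seed = 9)
  f <- tempfile(fileext = ".obj")
  write_obj(s, f)
  s2 <- read_obj(f, p)
  expect_identical(s2$vertices, unname(s$vertices))
  unlink(f)
})
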