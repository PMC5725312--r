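# Weighted Fourier series (WFS) representation of cortical surfaces.
#
# Each hemisphere-axis coordinate function is expanded in real spherical
# harmonics up to degree c. The heat-kernel weight exp(-l(l+1) sigma) is
# applied at reconstruction; fitting minimises the squared reconstruction
# error, so sigma = 0 reduces to plain least squares.

#' WFS coefficient set of a two-hemisphere surface
#'
#' @param coeff numeric array `2 x 3 x (degree+1)^2`
#'   (hemisphere L/R, axis x/y/z, (l,m)-lexicographic coefficient index).
#' @param degree harmonic degree `c`.
#' @param sigma non-negative smoothing parameter of the heat-kernel weight.
#' @return object of class `wfs_coefficients`.
#' @export
wfs_coefficients <- function(coeff, degree, sigma = 0) {
  degree <- as.integer(degree)
  k <- (degree + 1L)^2
  coeff <- array(as.numeric(coeff), dim = c(2L, 3L, k),
                 dimnames = list(c("L", "R"), c("x", "y", "z"), NULL))
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  structure(list(coeff = coeff, degree = degree, sigma = sigma),
            class = "wfs_coefficients")
}

#' @export
print.wfs_coefficients <- function(x, ...) {
  cat(sprintf("wfs_coefficients: degree %d, sigma %g, %d coefficients\n",
              x$degree, x$sigma, length(x$coeff)))
  invisible(x)
}

# Heat-kernel reconstruction weights per basis column.
wfs_weights <- function(degree, sigma) {
  l <- degree_of_column(degree)
  exp(-l * (l + 1) * sigma)
}

#' Fit a weighted Fourier series to a cortical surface
#'
#' Solves, independently per hemisphere and coordinate axis, the least
#' squares problem `min_f || v - B W f ||^2` where `B` is the harmonic
#' design matrix of the shared sphere parameterisation and
#' `W = diag(exp(-l(l+1) sigma))` is the reconstruction weight. A
#' rank-revealing (pivoted) QR is used; a condition number above `1e8`
#' triggers a warning.
#'
#' @param surface a [cortical_surface] sharing topology with `param`.
#' @param param the [sphere_param].
#' @param degree harmonic degree `c`; must satisfy `(c+1)^2 <=` vertices
#'   per hemisphere.
#' @param sigma smoothing parameter (default 1e-4; use 0 for exact
#'   round-trips on band-limited surfaces).
#' @return a [wfs_coefficients].
#' @export
fit_wfs <- function(surface, param, degree, sigma = 1e-4) {
  stopifnot(inherits(surface, "cortical_surface"), inherits(param, "sphere_param"))
  degree <- as.integer(degree)
  k <- (degree + 1L)^2
  if (k > param$vertex_count) {
    stop(sprintf("degree %d needs %d columns > %d vertices per hemisphere: underdetermined",
                 degree, k, param$vertex_count), call. = FALSE)
  }
  B <- basis_matrix(param, degree)
  W <- wfs_weights(degree, sigma)
  BW <- sweep(B, 2, W, `*`)
  qr_bw <- qr(BW, LAPACK = TRUE)
  cond <- kappa(qr.R(qr_bw), exact = FALSE)
  if (is.finite(cond) && cond > 1e8) {
    warning(sprintf("ill-conditioned WFS design (condition number %.3g)", cond))
  }
  hemis <- intersect(c("L", "R"), unique(surface$hemisphere))
  coeff <- array(0, dim = c(2L, 3L, k))
  dimnames(coeff) <- list(c("L", "R"), c("x", "y", "z"), NULL)
  for (h in hemis) {
    v <- surface$vertices[surface$hemisphere == h, , drop = FALSE]
    if (nrow(v) != param$vertex_count) stop("surface/param topology mismatch", call. = FALSE)
    coeff[h, , ] <- t(qr.coef(qr_bw, v))
  }
  wfs_coefficients(coeff, degree, sigma)
}

#' Reconstruct a cortical surface from WFS coefficients
#'
#' Evaluates, per hemisphere and axis, `v = B W f` with the heat-kernel
#' weights `W` of the coefficient set, and recomputes outward normals.
#'
#' @param coeffs a [wfs_coefficients].
#' @param param the [sphere_param] to evaluate on.
#' @return a [cortical_surface] with `2 * vertex_count` vertices.
#' @export
reconstruct <- function(coeffs, param) {
  stopifnot(inherits(coeffs, "wfs_coefficients"), inherits(param, "sphere_param"))
  if (all(coeffs$coeff == 0)) {
    warning("all-zero coefficients: reconstructing a degenerate surface")
  }
  B <- basis_matrix(param, coeffs$degree)
  W <- wfs_weights(coeffs$degree, coeffs$sigma)
  BW <- sweep(B, 2, W, `*`)
  nv <- param$vertex_count
  v <- matrix(0, 2L * nv, 3)
  for (hi in 1:2) {
    v[seq_len(nv) + (hi - 1L) * nv, ] <- BW %*% t(coeffs$coeff[hi, , ])
  }
  cortical_surface(v, param)
}
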