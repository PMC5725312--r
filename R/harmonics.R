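# Real (tesseral) spherical harmonics, orthonormal under the uniform
# measure dOmega on the unit sphere:
#   Y_{l,0}        = Pbar_{l,0}(cos theta)
#   Y_{l, m>0}     = sqrt(2) Pbar_{l,m}(cos theta) cos(m phi)
#   Y_{l,-m}, m>0  = sqrt(2) Pbar_{l,m}(cos theta) sin(m phi)
# where Pbar is the fully normalised associated Legendre function (no
# Condon-Shortley phase). Computed with the standard stable three-term
# recursion, vectorised over evaluation points.

#' Fully normalised associated Legendre functions
#'
#' Computes \eqn{\bar P_{lm}(\cos\theta)} for all degrees `l = m, ..., lmax`
#' at fixed order `m`, normalised so that the tesseral harmonics built from
#' them are orthonormal on the sphere.
#'
#' @param lmax maximum degree.
#' @param m order, `0 <= m <= lmax`.
#' @param x numeric vector of `cos(theta)` values in `[-1, 1]`.
#' @return matrix `length(x) x (lmax - m + 1)`, columns `l = m, ..., lmax`.
#' @keywords internal
legendre_normalised <- function(lmax, m, x) {
  stopifnot(m >= 0, lmax >= m)
  n <- length(x)
  out <- matrix(0, n, lmax - m + 1L)
  sin_t <- sqrt(pmax(0, 1 - x^2))
  # Pbar_{m,m}: start at Pbar_{0,0} = 1/sqrt(4*pi) and climb the diagonal
  pmm <- rep(1 / sqrt(4 * pi), n)
  if (m > 0) {
    for (k in seq_len(m)) {
      pmm <- pmm * sqrt((2 * k + 1) / (2 * k)) * sin_t
    }
  }
  out[, 1L] <- pmm
  if (lmax > m) {
    pm1 <- sqrt(2 * m + 3) * x * pmm          # Pbar_{m+1,m}
    out[, 2L] <- pm1
    if (lmax > m + 1L) {
      pl2 <- pmm
      pl1 <- pm1
      for (l in (m + 2L):lmax) {
        a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
        b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
        pl <- a * (x * pl1 - b * pl2)
        out[, l - m + 1L] <- pl
        pl2 <- pl1
        pl1 <- pl
      }
    }
  }
  out
}

#' Real spherical harmonic
#'
#' Evaluates the real (tesseral) spherical harmonic \eqn{Y_{lm}} at the
#' given spherical angles. The basis is orthonormal under the uniform
#' sphere measure: \eqn{\int Y_{lm} Y_{l'm'} \, d\Omega = \delta_{ll'}
#' \delta_{mm'}}.
#'
#' @param l degree (order of spatial detail), integer `>= 0`.
#' @param m index, integer with `|m| <= l`. Positive `m` pair with
#'   `cos(m phi)`, negative with `sin(|m| phi)`.
#' @param theta polar angle(s), radians in `[0, pi]`.
#' @param phi azimuth(s), radians.
#' @return numeric vector of harmonic values, recycled over angles.
#' @examples
#' sph_harm_real(0, 0, 1, 2)            # constant 1/(2*sqrt(pi))
#' sph_harm_real(1, 0, 0, 0)            # sqrt(3/(4*pi)) at the pole
#' @export
sph_harm_real <- function(l, m, theta, phi) {
  if (length(l) != 1L || length(m) != 1L || l < 0 || abs(m) > l) {
    stop("require scalar l >= 0 and |m| <= l", call. = FALSE)
  }
  ang <- cbind(theta = as.numeric(theta), phi = as.numeric(phi))
  am <- abs(m)
  p <- legendre_normalised(l, am, cos(ang[, "theta"]))[, l - am + 1L]
  out <- if (m == 0) {
    p
  } else if (m > 0) {
    sqrt(2) * p * cos(m * ang[, "phi"])
  } else {
    sqrt(2) * p * sin(am * ang[, "phi"])
  }
  unname(out)
}

#' Coefficient layout helpers
#'
#' `lm_index` gives the column of harmonic `(l, m)` in the
#' (l, m)-lexicographic layout (m running -l..l) used by [basis_matrix]
#' and [wfs_coefficients]; `degree_of_column` gives the degree of each of
#' the `(degree + 1)^2` columns.
#'
#' @param l,m harmonic degree and index.
#' @param degree maximum degree of the layout.
#' @return integer column index / integer vector of degrees.
#' @export
lm_index <- function(l, m) as.integer(l^2 + l + m + 1)

#' @rdname lm_index
#' @export
degree_of_column <- function(degree) {
  rep.int(0:degree, times = 2 * (0:degree) + 1)
}

#' Spherical-harmonic design matrix for a sphere parameterisation
#'
#' Evaluates all real harmonics up to `degree` at the parameterisation's
#' vertex angles. Column order is (l, m) lexicographic with m running
#' -l..l, i.e. column `l^2 + l + m + 1` holds \eqn{Y_{lm}}; there are
#' `(degree + 1)^2` columns. The result is deterministic for a given
#' parameterisation.
#'
#' @param param a [sphere_param] object.
#' @param degree maximum harmonic degree `c >= 0`.
#' @return numeric matrix `vertex_count x (degree + 1)^2`.
#' @export
basis_matrix <- function(param, degree) {
  stopifnot(inherits(param, "sphere_param"))
  if (length(degree) != 1L || degree < 0) stop("degree must be >= 0", call. = FALSE)
  degree <- as.integer(degree)
  if (param$vertex_count == 0L) stop("empty mesh", call. = FALSE)
  n <- param$vertex_count
  x <- cos(param$theta)
  B <- matrix(0, n, (degree + 1L)^2)
  for (m in 0:degree) {
    P <- legendre_normalised(degree, m, x)
    if (m == 0) {
      for (l in 0:degree) B[, lm_index(l, 0L)] <- P[, l + 1L]
    } else {
      cm <- sqrt(2) * cos(m * param$phi)
      sm <- sqrt(2) * sin(m * param$phi)
      for (l in m:degree) {
        B[, lm_index(l, m)] <- P[, l - m + 1L] * cm
        B[, lm_index(l, -m)] <- P[, l - m + 1L] * sm
      }
    }
  }
  B
}

#' Number of Fourier coefficients of a whole-brain surface model
#'
#' A surface of degree `c` needs `(c + 1)^2` coefficients per coordinate
#' axis per hemisphere, hence `6 (c + 1)^2` in total for a two-hemisphere
#' brain.
#'
#' @param degree harmonic degree `c >= 0`.
#' @return integer, `6 * (degree + 1)^2`.
#' @examples
#' count_coefficients(20)  # 2646
#' @export
count_coefficients <- function(degree) {
  if (length(degree) != 1L || is.na(degree) || degree < 0) {
    stop("degree must be a non-negative integer", call. = FALSE)
  }
  as.integer(6 * (as.integer(degree) + 1L)^2)
}
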