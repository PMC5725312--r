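# Single-sphere MEG forward model (Sarvas solution).
#
# The magnetic field outside a spherically symmetric volume conductor due
# to a current dipole has the closed form
#   B(r) = mu0 / (4 pi F^2) * ( F (Q x r0) - ((Q x r0) . r) grad F )
# with r0 the dipole position, r the sensor position (both relative to
# the sphere centre), a = r - r0, a = |a|, r = |r|,
#   F      = a (r a + r^2 - r0 . r)
#   grad F = (a^2/r + (a . r)/a + 2 a + 2 r) r - (a + 2 r + (a . r)/a) r0.
# Radially oriented dipoles are magnetically silent. SI units throughout
# (positions m, moments A*m, fields T).

MU0_OVER_4PI <- 1e-7

#' MEG sensor array
#'
#' @param positions numeric `Nc x 3`, metres.
#' @param orientations numeric `Nc x 3` unit sensing directions.
#' @param sphere_centre conductor sphere centre, metres (default origin).
#' @param names optional channel names.
#' @return object of class `sensor_array`.
#' @export
sensor_array <- function(positions, orientations, sphere_centre = c(0, 0, 0),
                         names = NULL) {
  positions <- as.matrix(positions); orientations <- as.matrix(orientations)
  stopifnot(ncol(positions) == 3, identical(dim(positions), dim(orientations)))
  len <- sqrt(rowSums(orientations^2))
  if (any(abs(len - 1) > 1e-9)) stop("sensor orientations must be unit vectors", call. = FALSE)
  if (is.null(names)) names <- sprintf("MEG%03d", seq_len(nrow(positions)))
  structure(list(count = nrow(positions), positions = positions,
                 orientations = orientations,
                 sphere_centre = as.numeric(sphere_centre), names = names),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("sensor_array: %d channels, sphere centre (%.3g, %.3g, %.3g) m\n",
              x$count, x$sphere_centre[1], x$sphere_centre[2], x$sphere_centre[3]))
  invisible(x)
}

#' Default synthetic helmet: radial magnetometers on a spherical cap
#'
#' Quasi-uniform (Fibonacci lattice) point magnetometers on the upper
#' half of a sphere of radius `radius`, sensing along the outward radial
#' direction — an idealisation of a whole-head axial MEG helmet.
#'
#' @param n number of channels (default 274).
#' @param radius helmet radius in metres (default 0.12).
#' @param centre sphere centre, metres.
#' @return a [sensor_array].
#' @export
default_sensor_array <- function(n = 274, radius = 0.12, centre = c(0, 0, 0)) {
  i <- seq_len(n)
  z <- 1 - (i - 0.5) / n          # upper hemisphere: z in (0, 1)
  golden <- pi * (3 - sqrt(5))
  az <- golden * i
  rho <- sqrt(pmax(0, 1 - z^2))
  u <- cbind(rho * cos(az), rho * sin(az), z)
  sensor_array(sweep(radius * u, 2, centre, `+`), u, sphere_centre = centre)
}

#' Least-squares sphere fit to a surface
#'
#' Fits centre and radius to the surface vertices by linear least squares
#' (the algebraic sphere fit). Used to place the conductor sphere, the
#' only anatomical information the single-sphere forward model consumes.
#'
#' @param surface a [cortical_surface] (vertices mm) or an `N x 3` matrix.
#' @param units `"mm"` (default, converted to metres) or `"m"`.
#' @return list with `centre` (m), `radius` (m).
#' @export
fit_sphere_centre <- function(surface, units = c("mm", "m")) {
  units <- match.arg(units)
  v <- if (inherits(surface, "cortical_surface")) surface$vertices else as.matrix(surface)
  if (units == "mm") v <- v / 1000
  A <- cbind(2 * v, 1)
  if (qr(A)$rank < 4) stop("degenerate (coplanar) vertex set: cannot fit a sphere", call. = FALSE)
  b <- rowSums(v^2)
  sol <- qr.coef(qr(A), b)
  centre <- sol[1:3]
  radius <- sqrt(sol[4] + sum(centre^2))
  list(centre = unname(centre), radius = unname(radius))
}

#' Magnetic field of a current dipole in a spherical conductor
#'
#' Evaluates the closed-form single-sphere field at each sensor and
#' projects it on the sensor orientation.
#'
#' @param r_dip dipole position, metres (3-vector, absolute coordinates).
#' @param q dipole moment, A*m (3-vector).
#' @param sensors a [sensor_array]; its `sphere_centre` defines the
#'   conductor.
#' @return numeric vector of length `Nc`, tesla.
#' @export
dipole_field_sphere <- function(r_dip, q, sensors) {
  stopifnot(inherits(sensors, "sensor_array"))
  r0 <- as.numeric(r_dip) - sensors$sphere_centre
  if (sqrt(sum(r0^2)) < 1e-9) stop("dipole at the sphere centre is singular", call. = FALSE)
  R <- sweep(sensors$positions, 2, sensors$sphere_centre)
  rn <- sqrt(rowSums(R^2))
  if (any(rn <= sqrt(sum(r0^2)))) {
    stop("dipole must lie strictly inside the sensor sphere", call. = FALSE)
  }
  A <- sweep(R, 2, r0)
  an <- sqrt(rowSums(A^2))
  ar <- rowSums(A * R)
  r0_dot_r <- R %*% r0
  Fv <- an * (rn * an + rn^2 - drop(r0_dot_r))
  if (any(abs(Fv) < 1e-30)) stop("singular geometry (F = 0)", call. = FALSE)
  coef_r <- an^2 / rn + ar / an + 2 * an + 2 * rn
  coef_r0 <- an + 2 * rn + ar / an
  gradF <- R * coef_r - tcrossprod(coef_r0, r0)
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  B <- (outer(Fv, qxr0) - gradF * drop(R %*% qxr0)) * (MU0_OVER_4PI / Fv^2)
  rowSums(B * sensors$orientations)
}

#' Lead field of a cortical surface under the single-sphere model
#'
#' Column `i` is the sensor field of a unit dipole (1 A*m) at vertex `i`,
#' oriented along the outward vertex normal (current flows normal to the
#' cortical surface). Vertices are converted mm -> m; any vertex within
#' 1 mm of the sensor sphere is shrunk radially by 1 mm with a warning.
#'
#' @param surface a [cortical_surface] (mm).
#' @param sensors a [sensor_array]. If `sphere_centre` is `NULL` in
#'   `centre`, it is fitted to the surface with [fit_sphere_centre].
#' @param centre optional conductor centre (m); default fits the surface.
#' @return object of class `lead_field`: `L` (`Nc x Nd`, T per A*m),
#'   `surface_hash`, `sensor_hash`, `centre`.
#' @export
surface_leadfield <- function(surface, sensors, centre = NULL) {
  stopifnot(inherits(surface, "cortical_surface"), inherits(sensors, "sensor_array"))
  if (is.null(centre)) centre <- fit_sphere_centre(surface)$centre
  sens <- sensors
  sens$sphere_centre <- centre
  v <- surface$vertices / 1000
  R <- sweep(sens$positions, 2, centre)
  r_min <- min(sqrt(rowSums(R^2)))
  vc <- sweep(v, 2, centre)
  vr <- sqrt(rowSums(vc^2))
  bad <- vr > r_min - 1e-3
  if (any(vr >= r_min)) {
    outside <- which(vr >= r_min)
    stop(sprintf("%d vertices outside the sensor sphere (first: %d)",
                 length(outside), outside[1]), call. = FALSE)
  }
  if (any(bad)) {
    warning(sprintf("%d vertices within 1 mm of the sensor sphere; shrunk radially by 1 mm",
                    sum(bad)))
    vc[bad, ] <- vc[bad, ] * ((vr[bad] - 1e-3) / vr[bad])
    v <- sweep(vc, 2, centre, `+`)
  }
  nd <- nrow(v)
  L <- matrix(0, sens$count, nd)
  for (i in seq_len(nd)) {
    L[, i] <- dipole_field_sphere(v[i, ], surface$normals[i, ], sens)
  }
  structure(list(L = L, centre = centre,
                 surface_hash = digest::digest(surface$vertices),
                 sensor_hash = digest::digest(sens$positions)),
            class = "lead_field")
}
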