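# Sphere parameterisations and cortical surface meshes.
#
# A brain is represented as two hemisphere meshes sharing one unit-sphere
# topology: vertices 1..Nv are the left hemisphere, Nv+1..2Nv the right,
# both indexed by the same sphere_param. Coordinates are millimetres.

#' Unit-sphere parameterisation shared by a surface library
#'
#' @param theta polar angles, radians in `[0, pi]`, one per vertex.
#' @param phi azimuths, radians in `[-pi, pi)`, one per vertex.
#' @param faces integer matrix `Nf x 3` of 0-based triangle vertex indices.
#' @return object of class `sphere_param` with fields `vertex_count`,
#'   `theta`, `phi`, `faces`.
#' @export
sphere_param <- function(theta, phi, faces) {
  theta <- as.numeric(theta); phi <- as.numeric(phi)
  if (length(theta) != length(phi)) stop("theta/phi length mismatch", call. = FALSE)
  if (any(theta < -1e-12 | theta > pi + 1e-12)) stop("theta out of [0, pi]", call. = FALSE)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) && (min(faces) < 0L || max(faces) >= length(theta))) {
    stop("faces reference invalid vertex indices", call. = FALSE)
  }
  structure(list(vertex_count = length(theta), theta = theta, phi = phi,
                 faces = faces),
            class = "sphere_param")
}

# Cartesian unit vectors of the parameterisation points.
sphere_points <- function(param) {
  st <- sin(param$theta)
  cbind(st * cos(param$phi), st * sin(param$phi), cos(param$theta))
}

#' Icosphere parameterisation
#'
#' Builds a quasi-uniform triangulated unit sphere by repeated 4-way
#' subdivision of an icosahedron; `level` 0..4 gives 12, 42, 162, 642 or
#' 2562 vertices.
#'
#' @param level subdivision level, non-negative integer.
#' @return a [sphere_param].
#' @export
icosphere_param <- function(level = 3) {
  g <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  g, 0), c(1,  g, 0), c(-1, -g, 0), c(1, -g, 0),
    c(0, -1,  g), c(0, 1,  g), c(0, -1, -g), c(0, 1, -g),
    c( g, 0, -1), c(g, 0,  1), c(-g, 0, -1), c(-g, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
    c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
    c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
    c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1)) + 1L
  for (it in seq_len(level)) {
    edge_key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
    midpoints <- new.env(parent = emptyenv())
    get_mid <- function(a, b) {
      k <- edge_key(a, b)
      i <- midpoints[[k]]
      if (is.null(i)) {
        p <- v[a, ] + v[b, ]
        p <- p / sqrt(sum(p^2))
        v <<- rbind(v, p)
        i <- nrow(v)
        assign(k, i, envir = midpoints)
      }
      i
    }
    nf <- matrix(0L, 4 * nrow(f), 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, c); ca <- get_mid(c, a)
      nf[4 * i - 3, ] <- c(a, ab, ca)
      nf[4 * i - 2, ] <- c(b, bc, ab)
      nf[4 * i - 1, ] <- c(c, ca, bc)
      nf[4 * i, ]     <- c(ab, bc, ca)
    }
    f <- nf
  }
  theta <- acos(pmin(1, pmax(-1, v[, 3])))
  phi <- atan2(v[, 2], v[, 1])
  sphere_param(theta, phi, f - 1L)
}

# Faces (0-based) of a two-hemisphere surface over one sphere_param.
brain_faces <- function(param) {
  rbind(param$faces, param$faces + param$vertex_count)
}

#' Cortical surface mesh
#'
#' Constructs a surface from vertex coordinates in millimetres. The first
#' `Nv` vertices belong to the left hemisphere and the next `Nv` to the
#' right, where `Nv` is the vertex count of `param`; a single-hemisphere
#' surface (`Nv` vertices, all labelled `L`) is also accepted. Outward
#' vertex normals are recomputed unless supplied.
#'
#' @param vertices numeric matrix `Nd x 3`, millimetres.
#' @param param the shared [sphere_param].
#' @param normals optional `Nd x 3` unit normals.
#' @return object of class `cortical_surface` with fields `vertices`,
#'   `faces` (0-based), `hemisphere` (`"L"`/`"R"` per vertex), `normals`,
#'   `param`.
#' @export
cortical_surface <- function(vertices, param, normals = NULL) {
  stopifnot(inherits(param, "sphere_param"))
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3) stop("vertices must be Nd x 3", call. = FALSE)
  nv <- param$vertex_count
  if (nrow(vertices) == 2L * nv) {
    hemisphere <- rep(c("L", "R"), each = nv)
    faces <- brain_faces(param)
  } else if (nrow(vertices) == nv) {
    hemisphere <- rep("L", nv)
    faces <- param$faces
  } else {
    stop("vertex count must match the sphere parameterisation (Nv or 2*Nv)",
         call. = FALSE)
  }
  if (is.null(normals)) normals <- vertex_normals(vertices, faces, hemisphere)
  structure(list(vertices = vertices, faces = faces, hemisphere = hemisphere,
                 normals = normals, param = param),
            class = "cortical_surface")
}

#' @export
print.cortical_surface <- function(x, ...) {
  cat(sprintf("cortical_surface: %d vertices (%d L / %d R), %d faces\n",
              nrow(x$vertices), sum(x$hemisphere == "L"),
              sum(x$hemisphere == "R"), nrow(x$faces)))
  invisible(x)
}

# Area-weighted vertex normals, oriented away from the hemisphere centroid
# so that a star-shaped hemisphere gets outward normals.
vertex_normals <- function(vertices, faces, hemisphere) {
  n <- matrix(0, nrow(vertices), 3)
  f1 <- faces[, 1] + 1L; f2 <- faces[, 2] + 1L; f3 <- faces[, 3] + 1L
  e1 <- vertices[f2, , drop = FALSE] - vertices[f1, , drop = FALSE]
  e2 <- vertices[f3, , drop = FALSE] - vertices[f1, , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  acc <- rowsum(rbind(fn, fn, fn), group = c(f1, f2, f3))
  n[as.integer(rownames(acc)), ] <- acc
  # orient per hemisphere: positive dot with direction from centroid
  for (h in unique(hemisphere)) {
    sel <- hemisphere == h
    ctr <- colMeans(vertices[sel, , drop = FALSE])
    out_dir <- sweep(vertices[sel, , drop = FALSE], 2, ctr)
    s <- sign(rowSums(n[sel, , drop = FALSE] * out_dir))
    s[s == 0] <- 1
    flip <- mean(s) < 0   # consistent winding: flip all, not per-vertex
    if (flip) n[sel, ] <- -n[sel, ]
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Star-shapedness check of a brain surface
#'
#' A cheap validity test for synthetic brains: each hemisphere must be
#' star-shaped about its centroid (every outward normal makes a positive
#' angle with the ray from the centroid), which rules out folds that pass
#' through themselves.
#'
#' @param surface a [cortical_surface].
#' @return logical scalar.
#' @export
surface_is_valid <- function(surface) {
  stopifnot(inherits(surface, "cortical_surface"))
  if (!all(is.finite(surface$vertices))) return(FALSE)
  ok <- TRUE
  for (h in unique(surface$hemisphere)) {
    sel <- surface$hemisphere == h
    v <- surface$vertices[sel, , drop = FALSE]
    ctr <- colMeans(v)
    ray <- sweep(v, 2, ctr)
    ok <- ok && all(rowSums(surface$normals[sel, , drop = FALSE] * ray) > 0)
  }
  ok
}

#' Read / write Wavefront OBJ surface meshes
#'
#' Minimal OBJ support for exchanging library surfaces: `v` and `f`
#' records only, vertex order preserved exactly.
#'
#' @param surface a [cortical_surface].
#' @param path file path.
#' @param param a [sphere_param] whose topology the file must match.
#' @return `write_obj` returns `path` invisibly; `read_obj` returns a
#'   [cortical_surface].
#' @export
write_obj <- function(surface, path) {
  stopifnot(inherits(surface, "cortical_surface"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.17g %.17g %.17g", surface$vertices[, 1],
                     surface$vertices[, 2], surface$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", surface$faces[, 1] + 1L,
                     surface$faces[, 2] + 1L, surface$faces[, 3] + 1L), con)
  invisible(path)
}

#' @rdname write_obj
#' @export
read_obj <- function(path, param) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x) as.numeric(x[2:4])))
  cortical_surface(v, param)
}
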