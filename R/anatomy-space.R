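# The 2-D space of candidate brains: per-order SVD model reduction of a
# brain library, eigenmode stepping, and mesh distance metrics.

#' Library of WFS-parameterised brains
#'
#' @param coeffs list of [wfs_coefficients], all sharing degree and sigma.
#' @param param the shared [sphere_param].
#' @param ids optional subject identifiers.
#' @return object of class `brain_library`.
#' @export
brain_library <- function(coeffs, param, ids = NULL) {
  if (length(coeffs) < 2) stop("a brain library needs Nb >= 2 subjects", call. = FALSE)
  stopifnot(all(vapply(coeffs, inherits, logical(1), "wfs_coefficients")),
            inherits(param, "sphere_param"))
  deg <- unique(vapply(coeffs, `[[`, integer(1), "degree"))
  sig <- unique(vapply(coeffs, `[[`, numeric(1), "sigma"))
  if (length(deg) != 1 || length(sig) != 1) {
    stop("all library members must share degree and sigma", call. = FALSE)
  }
  if (is.null(ids)) ids <- sprintf("sub-%02d", seq_along(coeffs))
  structure(list(coeffs = coeffs, param = param, degree = deg, sigma = sig,
                 ids = ids),
            class = "brain_library")
}

#' @export
print.brain_library <- function(x, ...) {
  cat(sprintf("brain_library: %d subjects, degree %d, %d vertices/hemisphere\n",
              length(x$coeffs), x$degree, x$param$vertex_count))
  invisible(x)
}

#' Library mean coefficient set
#' @param library a [brain_library].
#' @return a [wfs_coefficients] averaging all subjects.
#' @export
library_mean <- function(library) {
  stopifnot(inherits(library, "brain_library"))
  acc <- Reduce(`+`, lapply(library$coeffs, `[[`, "coeff"))
  wfs_coefficients(acc / length(library$coeffs), library$degree, library$sigma)
}

# Harmonic order j <-> spherical-harmonic degree l. The printed counting
# Nw = 6(2j-1) matches 2l+1 coefficients per degree only if l = j-1; the
# "degree" convention (l = j) is kept as an option.
order_to_degree <- function(j, convention = c("order", "degree")) {
  convention <- match.arg(convention)
  l <- if (convention == "order") as.integer(j) - 1L else as.integer(j)
  if (l < 0) stop("harmonic order out of range", call. = FALSE)
  l
}

# Flat column indices (hemisphere-major, then axis, then m = -l..l) of one
# order block inside a wfs_coefficients array.
order_block_layout <- function(l) {
  m_cols <- lm_index(l, -l:l)  # coefficient index within (c+1)^2
  expand.grid(m_col = m_cols, axis = 1:3, hemi = 1:2)[, c("hemi", "axis", "m_col")]
}

#' Extract the coefficient block of one harmonic order across a library
#'
#' Collects the `Nw = 6(2j - 1)` coefficients of harmonic order `j`
#' (spherical-harmonic degree `l = j - 1` under the default convention)
#' for every subject into a matrix with one row per subject. Columns are
#' hemisphere-major, then axis, then `m = -l..l`.
#'
#' @param library a [brain_library].
#' @param j harmonic order, `1 <= j <= degree + 1`.
#' @param convention `"order"` (default, `l = j - 1`) or `"degree"`
#'   (`l = j`).
#' @return object of class `order_block` with fields `order`, `degree_l`,
#'   `G` (`Nb x Nw`), `layout`.
#' @export
extract_order_block <- function(library, j, convention = c("order", "degree")) {
  stopifnot(inherits(library, "brain_library"))
  convention <- match.arg(convention)
  l <- order_to_degree(j, convention)
  if (l > library$degree) stop("harmonic order exceeds library degree", call. = FALSE)
  layout <- order_block_layout(l)
  G <- t(vapply(library$coeffs, function(cf) {
    cf$coeff[cbind(layout$hemi, layout$axis, layout$m_col)]
  }, numeric(nrow(layout))))
  structure(list(order = as.integer(j), degree_l = l, G = G, layout = layout),
            class = "order_block")
}

#' First eigenmode of shape variation within one harmonic order
#'
#' Removes the across-subject mean from each coefficient column
#' (`Ghat = G - Gbar`) and takes the leading eigenvector `u1` of
#' `Ghat' Ghat` with eigenvalue `S11`. The sign of `u1` is fixed so its
#' largest-magnitude entry is positive. `step_scale` is the standard
#' deviation of the library along `u1`, `sqrt(S11 / (Nb - 1))`, used as
#' the unit of the deformation step `delta`.
#'
#' @param block an [extract_order_block] result.
#' @return object of class `principal_mode` with fields `order`,
#'   `degree_l`, `mean_row`, `u1`, `S11`, `step_scale`, `layout`.
#' @export
principal_mode <- function(block) {
  stopifnot(inherits(block, "order_block"))
  G <- block$G
  if (nrow(G) < 2) stop("Nb >= 2 subjects required", call. = FALSE)
  gbar <- colMeans(G)
  ghat <- sweep(G, 2, gbar)
  e <- eigen(crossprod(ghat), symmetric = TRUE)
  s11 <- max(0, e$values[1])
  u1 <- e$vectors[, 1]
  if (s11 <= .Machine$double.eps * nrow(G) * ncol(G)) {
    warning("zero-variance order block: S11 = 0")
    s11 <- 0
  }
  imax <- which.max(abs(u1))
  if (u1[imax] < 0) u1 <- -u1
  structure(list(order = block$order, degree_l = block$degree_l,
                 mean_row = gbar, u1 = u1, S11 = s11,
                 step_scale = sqrt(s11 / (nrow(G) - 1)),
                 layout = block$layout),
            class = "principal_mode")
}

#' Displace one harmonic order along its principal eigenmode
#'
#' Returns a coefficient set equal to `base` except that the coefficients
#' of the mode's harmonic order are replaced by `X = s u1' + Gbar`, where
#' `s = delta * step_scale` (one `delta` unit = one library standard
#' deviation along the mode). With `step_mode = "literal"` the raw
#' eigenvalue is used instead (`s = delta * S11`).
#'
#' @param mode a [principal_mode].
#' @param delta step in units of normal shape variation.
#' @param base the [wfs_coefficients] supplying all other orders
#'   (typically [library_mean]).
#' @param step_mode `"sd"` (default) or `"literal"`.
#' @return a [wfs_coefficients].
#' @export
apply_deformation <- function(mode, delta, base, step_mode = c("sd", "literal")) {
  stopifnot(inherits(mode, "principal_mode"), inherits(base, "wfs_coefficients"))
  step_mode <- match.arg(step_mode)
  s <- delta * switch(step_mode, sd = mode$step_scale, literal = mode$S11)
  x <- s * mode$u1 + mode$mean_row
  out <- base
  out$coeff[cbind(mode$layout$hemi, mode$layout$axis, mode$layout$m_col)] <- x
  out
}

#' Build the 2-D deformation grid of candidate brains
#'
#' Steps the principal eigenmodes of two harmonic orders by the given
#' `delta` multiples of normal shape variation around the library mean,
#' and reconstructs one candidate surface per cell. All orders other than
#' the two selected stay at the library mean, so the `(0, 0)` cell is the
#' mean brain exactly.
#'
#' @param library a [brain_library].
#' @param orders length-2 integer vector of distinct harmonic orders
#'   (default `c(6, 9)`).
#' @param deltas_a,deltas_b step lists for the two orders. The default
#'   coarse set is `-2:2`; the fine set `seq(-2, 2, 0.5)` gives a 9 x 9
#'   (81-cell) grid.
#' @param step_mode,convention passed to [apply_deformation] /
#'   [extract_order_block].
#' @return object of class `deformation_grid` with fields `orders`,
#'   `deltas_a`, `deltas_b`, `modes`, `base`, `coeffs` (list-matrix),
#'   `surfaces` (list-matrix of [cortical_surface]), `param`.
#' @export
build_grid <- function(library, orders = c(6, 9),
                       deltas_a = -2:2, deltas_b = -2:2,
                       step_mode = c("sd", "literal"),
                       convention = c("order", "degree")) {
  stopifnot(inherits(library, "brain_library"))
  step_mode <- match.arg(step_mode)
  convention <- match.arg(convention)
  if (length(orders) != 2 || orders[1] == orders[2]) {
    stop("orders must be two distinct harmonic orders", call. = FALSE)
  }
  base <- library_mean(library)
  modes <- lapply(orders, function(j) {
    principal_mode(extract_order_block(library, j, convention))
  })
  na <- length(deltas_a); nb <- length(deltas_b)
  coeffs <- vector("list", na * nb)
  dim(coeffs) <- c(na, nb)
  surfaces <- coeffs
  for (ia in seq_len(na)) {
    ca <- apply_deformation(modes[[1]], deltas_a[ia], base, step_mode)
    for (ib in seq_len(nb)) {
      cab <- apply_deformation(modes[[2]], deltas_b[ib], ca, step_mode)
      coeffs[[ia, ib]] <- cab
      surfaces[[ia, ib]] <- reconstruct(cab, library$param)
    }
  }
  structure(list(orders = as.integer(orders), deltas_a = deltas_a,
                 deltas_b = deltas_b, modes = modes, base = base,
                 coeffs = coeffs, surfaces = surfaces, param = library$param,
                 step_mode = step_mode, convention = convention),
            class = "deformation_grid")
}

#' @export
print.deformation_grid <- function(x, ...) {
  cat(sprintf("deformation_grid: orders (%d, %d), %d x %d = %d candidate brains\n",
              x$orders[1], x$orders[2], length(x$deltas_a), length(x$deltas_b),
              length(x$surfaces)))
  invisible(x)
}

#' Grid manifest
#'
#' Serialises a deformation grid's provenance (orders, deltas, step mode,
#' library hash) and optionally writes each candidate surface as OBJ.
#'
#' @param grid a [deformation_grid].
#' @param path manifest file path (JSON).
#' @param surfaces_dir optional directory for per-cell OBJ files.
#' @return the manifest list, invisibly.
#' @export
write_grid_manifest <- function(grid, path, surfaces_dir = NULL) {
  stopifnot(inherits(grid, "deformation_grid"))
  files <- NULL
  if (!is.null(surfaces_dir)) {
    dir.create(surfaces_dir, showWarnings = FALSE, recursive = TRUE)
    files <- matrix("", length(grid$deltas_a), length(grid$deltas_b))
    for (ia in seq_along(grid$deltas_a)) for (ib in seq_along(grid$deltas_b)) {
      f <- file.path(surfaces_dir, sprintf("cell_%+g_%+g.obj",
                                           grid$deltas_a[ia], grid$deltas_b[ib]))
      write_obj(grid$surfaces[[ia, ib]], f)
      files[ia, ib] <- f
    }
  }
  manifest <- list(orders = grid$orders, deltas_a = grid$deltas_a,
                   deltas_b = grid$deltas_b, step_mode = grid$step_mode,
                   convention = grid$convention,
                   library_hash = digest::digest(grid$base$coeff),
                   surfaces = files)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# ---- distance metrics -------------------------------------------------

#' Index-matched mean vertex distance between two surfaces (mm)
#'
#' Mean over vertices of the Euclidean distance between index-matched
#' vertex pairs: both surfaces must be deformations of the same sphere
#' parameterisation. Symmetric, and sensitive to folding pattern
#' differences.
#'
#' @param a,b [cortical_surface] objects with identical topology.
#' @return distance in millimetres.
#' @export
rms_vertex_distance <- function(a, b) {
  stopifnot(inherits(a, "cortical_surface"), inherits(b, "cortical_surface"))
  if (nrow(a$vertices) != nrow(b$vertices) || !identical(dim(a$faces), dim(b$faces))) {
    stop("surfaces do not share topology", call. = FALSE)
  }
  d <- a$vertices - b$vertices
  mean(sqrt(rowSums(d^2)))
}

# Pairwise Euclidean distance matrix between two vertex sets (chunked to
# bound memory on large meshes).
cross_dist <- function(va, vb, chunk = 2048L) {
  na <- nrow(va)
  out <- matrix(0, na, nrow(vb))
  nb2 <- rowSums(vb^2)
  for (i0 in seq(1L, na, by = chunk)) {
    i1 <- min(na, i0 + chunk - 1L)
    blk <- va[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), nb2, `+`) - 2 * tcrossprod(blk, vb)
    out[i0:i1, ] <- sqrt(pmax(0, d2))
  }
  out
}

#' Nearest-neighbour and Hausdorff distances between surfaces (mm)
#'
#' `nn_distance` is the symmetric mean of the per-vertex minimum distance
#' to the other surface, averaged over both directions.
#' `hausdorff_distance` is the maximum over both directed max-min
#' distances. Topologies may differ.
#'
#' @param a,b [cortical_surface] objects.
#' @return distance in millimetres.
#' @export
nn_distance <- function(a, b) {
  stopifnot(inherits(a, "cortical_surface"), inherits(b, "cortical_surface"))
  if (!nrow(a$vertices) || !nrow(b$vertices)) stop("empty surface", call. = FALSE)
  d <- cross_dist(a$vertices, b$vertices)
  (mean(apply(d, 1, min)) + mean(apply(d, 2, min))) / 2
}

#' @rdname nn_distance
#' @export
hausdorff_distance <- function(a, b) {
  stopifnot(inherits(a, "cortical_surface"), inherits(b, "cortical_surface"))
  if (!nrow(a$vertices) || !nrow(b$vertices)) stop("empty surface", call. = FALSE)
  d <- cross_dist(a$vertices, b$vertices)
  max(max(apply(d, 1, min)), max(apply(d, 2, min)))
}
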