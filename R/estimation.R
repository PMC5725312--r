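# Scoring the deformation grid and forming the posterior over anatomy.

#' Score every candidate brain in a deformation grid by free energy
#'
#' For each grid cell: compute the single-sphere lead field of the
#' candidate surface, estimate the EBB prior from the data, run ReML and
#' record the free energy. Cells are independent (the map is invariant to
#' evaluation order); a cell whose inversion fails is flagged `NA` with a
#' warning and excluded from the posterior downstream.
#'
#' @param Y a [meg_data] or matrix.
#' @param grid a [deformation_grid].
#' @param sensors a [sensor_array].
#' @param leadfields optional pre-computed list-matrix of [lead_field]s
#'   (from [grid_leadfields]); computed on the fly when `NULL`.
#' @param temporal_modes number of dominant temporal SVD modes the data
#'   are projected onto before inversion (default 16, the conventional
#'   choice in evoked-response source inversion; `NULL` disables the
#'   projection). The same projection is applied for every cell, so free
#'   energies remain comparable across the grid, and concentrating the
#'   evoked signal into few modes makes the data-driven beamformer prior
#'   far less noisy at low SNR.
#' @param ... passed to [reml_optimise].
#' @return object of class `anatomy_score_map` with fields `F`
#'   (matrix `|deltas_a| x |deltas_b|`), `deltas_a`, `deltas_b`,
#'   `lambda`, `iterations`, `converged`, `grid` (reference).
#' @export
score_grid <- function(Y, grid, sensors, leadfields = NULL,
                       temporal_modes = 16, ...) {
  stopifnot(inherits(grid, "deformation_grid"), inherits(sensors, "sensor_array"))
  Y <- as_meg(Y)
  if (!is.null(temporal_modes) && temporal_modes < Y$Nt) {
    r <- min(temporal_modes, Y$Nc)
    v <- svd(Y$Y, nu = 0, nv = r)$v
    Y <- meg_data(Y$Y %*% v, Y$fs)
  }
  if (is.null(leadfields)) leadfields <- grid_leadfields(grid, sensors)
  na <- length(grid$deltas_a); nb <- length(grid$deltas_b)
  Fm <- matrix(NA_real_, na, nb)
  lam <- array(NA_real_, c(na, nb, 2))
  iters <- matrix(NA_integer_, na, nb)
  conv <- matrix(NA, na, nb)
  for (ia in seq_len(na)) for (ib in seq_len(nb)) {
    L <- leadfields[[ia, ib]]$L
    L <- L / sqrt(sum(L^2))       # per-cell gain normalisation
    res <- tryCatch(reml_optimise(Y, L, ...), error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("cell (%g, %g) failed inversion: %s; excluded",
                      grid$deltas_a[ia], grid$deltas_b[ib], conditionMessage(res)))
      next
    }
    Fm[ia, ib] <- res$F
    lam[ia, ib, ] <- res$lambda
    iters[ia, ib] <- res$iterations
    conv[ia, ib] <- res$converged
  }
  if (all(is.na(Fm))) stop("all grid cells failed inversion", call. = FALSE)
  structure(list(F = Fm, deltas_a = grid$deltas_a, deltas_b = grid$deltas_b,
                 lambda = lam, iterations = iters, converged = conv,
                 grid = grid),
            class = "anatomy_score_map")
}

#' Lead fields for every candidate surface of a grid
#'
#' @param grid a [deformation_grid].
#' @param sensors a [sensor_array].
#' @param centre optional shared conductor centre (m); default fits the
#'   mean (origin-cell) surface once, so all candidates share one
#'   conductor, as in a fixed head model.
#' @return list-matrix of [lead_field] objects.
#' @export
grid_leadfields <- function(grid, sensors, centre = NULL) {
  stopifnot(inherits(grid, "deformation_grid"))
  if (is.null(centre)) {
    i0 <- which.min(abs(grid$deltas_a)); j0 <- which.min(abs(grid$deltas_b))
    centre <- fit_sphere_centre(grid$surfaces[[i0, j0]])$centre
  }
  lf <- grid$surfaces
  for (k in seq_along(lf)) lf[[k]] <- surface_leadfield(grid$surfaces[[k]], sensors, centre)
  lf
}

#' @export
print.anatomy_score_map <- function(x, ...) {
  pk <- peak_cell(x)
  cat(sprintf("anatomy_score_map: %d x %d cells, F in [%.2f, %.2f]\n",
              nrow(x$F), ncol(x$F), min(x$F, na.rm = TRUE), max(x$F, na.rm = TRUE)))
  cat(sprintf("  peak at delta = (%g, %g)\n",
              x$deltas_a[pk[1]], x$deltas_b[pk[2]]))
  invisible(x)
}

#' Grid cell attaining the maximum free energy
#' @param map an [score_grid] result or an F matrix.
#' @return integer vector `(ia, ib)` (row, column indices).
#' @export
peak_cell <- function(map) {
  Fm <- if (inherits(map, "anatomy_score_map")) map$F else as.matrix(map)
  idx <- which(Fm == max(Fm, na.rm = TRUE), arr.ind = TRUE)
  as.integer(idx[1, ])   # ties broken by grid index
}

#' Posterior probability over candidate anatomies
#'
#' Softmax of the free energies, `p_r` proportional to
#' `exp(F_r - max F) * prior_r`, under a uniform model prior by default.
#' Computed in log space with max subtraction; failed (`NA`) cells get
#' zero probability and the rest renormalise.
#'
#' @param map an [score_grid] result or an F matrix.
#' @param prior optional per-cell prior weights (matrix or vector, need
#'   not be normalised).
#' @return matrix of posterior probabilities summing to 1.
#' @export
model_posterior <- function(map, prior = NULL) {
  Fm <- if (inherits(map, "anatomy_score_map")) map$F else as.matrix(map)
  if (!any(is.finite(Fm))) stop("no finite free energies", call. = FALSE)
  if (is.null(prior)) prior <- array(1, dim(Fm))
  prior <- array(as.numeric(prior), dim(Fm))
  lp <- Fm - max(Fm, na.rm = TRUE) + log(prior)
  w <- exp(lp)
  w[!is.finite(w)] <- 0
  w / sum(w)
}

#' Smallest credible set of candidate anatomies
#'
#' Cells sorted by decreasing posterior probability are accumulated until
#' their mass reaches `level`; ties are broken by grid (column-major)
#' index.
#'
#' @param p posterior probability matrix (from [model_posterior]).
#' @param level credibility level (default 0.95).
#' @return data.frame with `ia`, `ib`, `delta_a` (if available), `p`,
#'   ordered by decreasing probability; attribute `"mass"` holds the
#'   attained cumulative probability.
#' @export
credible_region <- function(p, level = 0.95) {
  p <- as.matrix(p)
  ord <- order(-p, seq_along(p))
  cum <- cumsum(p[ord])
  k <- which(cum >= level - 1e-12)[1]
  if (is.na(k)) k <- length(ord)
  sel <- ord[seq_len(k)]
  idx <- arrayInd(sel, dim(p))
  out <- data.frame(ia = idx[, 1], ib = idx[, 2], p = p[sel])
  attr(out, "mass") <- cum[k]
  out
}

#' Compare a score map to a known true surface
#'
#' Computes the chosen distance metric between every candidate surface
#' and `truth`, and summarises: distance at the free-energy peak, the
#' distance-minimising cell, and the Spearman rank correlation between F
#' and distance (expected strongly negative when the free-energy surface
#' tracks anatomical error).
#'
#' @param map an [score_grid] result.
#' @param truth a [cortical_surface].
#' @param metric `"rms"` (index-matched; needs shared topology), `"nn"`
#'   or `"hausdorff"`.
#' @return list with `distance` (matrix, mm), `peak_cell`,
#'   `distance_at_peak`, `min_cell`, `min_distance`, `spearman_F_dist`.
#' @export
compare_to_truth <- function(map, truth, metric = c("rms", "nn", "hausdorff")) {
  stopifnot(inherits(map, "anatomy_score_map"), inherits(truth, "cortical_surface"))
  metric <- match.arg(metric)
  fun <- switch(metric, rms = rms_vertex_distance, nn = nn_distance,
                hausdorff = hausdorff_distance)
  D <- map$F
  D[] <- NA_real_
  for (k in seq_along(map$grid$surfaces)) D[k] <- fun(map$grid$surfaces[[k]], truth)
  pk <- peak_cell(map)
  mn <- which(D == min(D), arr.ind = TRUE)[1, ]
  ok <- is.finite(map$F) & is.finite(D)
  rho <- if (sum(ok) > 2) stats::cor(map$F[ok], D[ok], method = "spearman") else NA_real_
  list(distance = D, peak_cell = pk, distance_at_peak = D[pk[1], pk[2]],
       min_cell = as.integer(mn), min_distance = min(D),
       spearman_F_dist = rho, metric = metric)
}

#' Export a score map as contour-ready TSV and JSON
#'
#' @param map an [score_grid] result.
#' @param path_tsv output TSV path (columns `delta_a`, `delta_b`, `F`,
#'   `p`, and `dist` when `truth` is given).
#' @param truth optional [cortical_surface] for the distance column.
#' @param path_json optional JSON summary path.
#' @return the exported data.frame, invisibly.
#' @export
export_score_map <- function(map, path_tsv, truth = NULL, path_json = NULL) {
  stopifnot(inherits(map, "anatomy_score_map"))
  p <- model_posterior(map)
  df <- expand.grid(delta_a = map$deltas_a, delta_b = map$deltas_b)
  df$F <- as.vector(map$F)
  df$p <- as.vector(p)
  cmp <- NULL
  if (!is.null(truth)) {
    cmp <- compare_to_truth(map, truth)
    df$dist <- as.vector(cmp$distance)
  }
  utils::write.table(df, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_json)) {
    pk <- peak_cell(map)
    cr <- credible_region(p)
    summ <- list(peak = list(delta_a = map$deltas_a[pk[1]],
                             delta_b = map$deltas_b[pk[2]], F = max(map$F, na.rm = TRUE)),
                 credible_95 = data.frame(delta_a = map$deltas_a[cr$ia],
                                          delta_b = map$deltas_b[cr$ib], p = cr$p),
                 distance_at_peak = if (is.null(cmp)) NULL else cmp$distance_at_peak,
                 spearman_F_dist = if (is.null(cmp)) NULL else cmp$spearman_F_dist)
    jsonlite::write_json(summ, path_json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(df)
}
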