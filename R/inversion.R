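# Empirical Bayes Beamformer source inversion.
#
# Generative model at the sensors: Y = L J + eps, with Gaussian priors
# J ~ N(0, Q_a), eps ~ N(0, Q_eps). The model sensor covariance is
#   Sigma_a = exp(lambda_1) I_Nc + exp(lambda_2) L Qtilde L'
# where Qtilde is the (unit-trace) beamformer variance prior estimated
# from the data. The log-scale hyperparameters lambda are optimised by
# Fisher-scoring ReML with Gaussian hyperpriors N(upsilon, Pi^-1), using
# the negative variational free energy
#   F = -Nt/2 tr(Sigma_Y Sigma_a^-1) - Nt/2 log|Sigma_a|
#       - Nt Nc/2 log(2 pi) - 1/2 (lambda - upsilon)' Pi (lambda - upsilon)
#       + 1/2 log|Sigma_lambda Pi|
# as the objective; F approximates log p(Y | anatomy) and is the model
# score used for anatomy selection.

#' MEG sensor dataset
#'
#' @param Y numeric matrix `Nc x Nt` (channels x samples).
#' @param fs sampling rate, Hz.
#' @param window optional description of the analysis window.
#' @return object of class `meg_data`.
#' @export
meg_data <- function(Y, fs = 600, window = NULL) {
  Y <- as.matrix(Y)
  if (!all(is.finite(Y))) stop("Y must be finite", call. = FALSE)
  if (ncol(Y) < 2) stop("need Nt >= 2 samples", call. = FALSE)
  structure(list(Y = Y, fs = fs, window = window,
                 Nc = nrow(Y), Nt = ncol(Y)),
            class = "meg_data")
}

#' @export
print.meg_data <- function(x, ...) {
  cat(sprintf("meg_data: %d channels x %d samples @ %g Hz\n", x$Nc, x$Nt, x$fs))
  invisible(x)
}

as_meg <- function(Y, fs = 600) if (inherits(Y, "meg_data")) Y else meg_data(Y, fs)

# Regularised data covariance C = YY'/Nt (+ eps I when rank-deficient).
data_covariance <- function(Y, ridge = 1e-8) {
  Y <- as_meg(Y)
  C <- tcrossprod(Y$Y) / Y$Nt
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) {
    C <- C + diag(ridge * sum(diag(C)) / Y$Nc, Y$Nc)
  }
  C
}

#' Empirical Bayes Beamformer source prior
#'
#' Estimates the per-vertex source variance under beamforming
#' (uncorrelated-source) assumptions: `q_ii = 1 / (l_i' C^-1 l_i)` with
#' `C = Y Y' / Nt` the (regularised) data covariance, normalised to unit
#' trace. Scale changes of `Y` leave the normalised prior unchanged.
#'
#' @param L a [lead_field] or `Nc x Nd` matrix.
#' @param Y a [meg_data] or matrix.
#' @param ridge relative ridge added to a rank-deficient covariance.
#' @return list of class `ebb_prior` with `q` (length `Nd`, unit-trace
#'   diagonal) and `C`.
#' @export
ebb_prior <- function(L, Y, ridge = 1e-8) {
  Lm <- if (inherits(L, "lead_field")) L$L else as.matrix(L)
  Y <- as_meg(Y)
  if (Y$Nt < Y$Nc) {
    # still well-defined thanks to the ridge, but warn: C is rank Nt
    if (ridge <= 0) stop("rank-deficient covariance: supply a positive ridge", call. = FALSE)
  }
  C <- data_covariance(Y, ridge)
  CiL <- solve(C, Lm)
  w <- colSums(Lm * CiL)
  if (any(w <= 0)) stop("non-positive beamformer power denominator", call. = FALSE)
  q <- 1 / w
  q <- q / sum(q)
  structure(list(q = q, C = C), class = "ebb_prior")
}

#' Negative variational free energy of a sensor-level model
#'
#' Evaluates the five-term free energy of a zero-mean Gaussian model with
#' sensor covariance `Sigma_a` for data with covariance
#' `Sigma_Y = Y Y' / Nt`, plus the hyperparameter complexity penalty. The
#' returned decomposition labels the first three (data) terms `accuracy`
#' and the last two (hyperparameter) terms `complexity`.
#'
#' @param Sigma_Y data covariance `Nc x Nc`.
#' @param Sigma_a model covariance `Nc x Nc` (positive definite).
#' @param Nt number of time samples.
#' @param lambda,upsilon,Pi hyperparameter estimate, hyperprior mean and
#'   hyperprior precision matrix.
#' @param Sigma_lambda posterior covariance of the hyperparameters.
#' @return list with `F`, `accuracy`, `complexity`, and the five terms.
#' @export
free_energy <- function(Sigma_Y, Sigma_a, Nt, lambda, upsilon, Pi, Sigma_lambda) {
  Nc <- nrow(Sigma_a)
  ch <- tryCatch(chol(Sigma_a), error = function(e) NULL)
  if (is.null(ch)) stop("singular model covariance Sigma_a", call. = FALSE)
  logdet_a <- 2 * sum(log(diag(ch)))
  tr_term <- sum(diag(chol2inv(ch) %*% Sigma_Y))
  dl <- as.numeric(lambda - upsilon)
  t1 <- -Nt / 2 * tr_term
  t2 <- -Nt / 2 * logdet_a
  t3 <- -Nt * Nc / 2 * log(2 * pi)
  t4 <- -0.5 * drop(t(dl) %*% Pi %*% dl)
  t5 <- 0.5 * determinant(Sigma_lambda %*% Pi, logarithm = TRUE)$modulus
  attributes(t5) <- NULL
  list(F = t1 + t2 + t3 + t4 + t5,
       accuracy = t1 + t2 + t3, complexity = t4 + t5,
       terms = c(trace = t1, logdet = t2, const = t3,
                 hyper_penalty = t4, hyper_entropy = t5))
}

#' Posterior mean source estimate
#'
#' The conditional expectation of the source currents,
#' `Jhat = Q_a L' (L Q_a L' + Q_eps)^-1 Y`, computed with a linear solve
#' (never an explicit inverse).
#'
#' @param Y a [meg_data] or matrix.
#' @param L a [lead_field] or matrix.
#' @param Q_a source prior covariance: scalar, length-`Nd` diagonal, or
#'   matrix.
#' @param Q_eps sensor noise covariance: scalar (times identity) or
#'   matrix.
#' @return `Nd x Nt` matrix of posterior mean currents.
#' @export
posterior_sources <- function(Y, L, Q_a, Q_eps) {
  Y <- as_meg(Y)
  Lm <- if (inherits(L, "lead_field")) L$L else as.matrix(L)
  nd <- ncol(Lm)
  QaLt <- if (is.matrix(Q_a)) Q_a %*% t(Lm) else t(Lm) * rep_len(as.numeric(Q_a), nd)
  S <- Lm %*% QaLt
  S <- S + (if (is.matrix(Q_eps)) Q_eps else diag(rep_len(as.numeric(Q_eps), Y$Nc)))
  sol <- tryCatch(solve(S, Y$Y), error = function(e) {
    stop("singular sensor covariance (L Q_a L' + Q_eps)", call. = FALSE)
  })
  QaLt %*% sol
}

#' ReML optimisation of the EBB model
#'
#' Fisher-scoring ascent on the log-scale hyperparameters of
#' `Sigma_a = exp(lambda_1) I + exp(lambda_2) L Qtilde L'`, with Gaussian
#' hyperpriors, monitored and step-halved on the free energy so that the
#' `F` sequence is non-decreasing. Deterministic given the data.
#'
#' @param Y a [meg_data] or matrix.
#' @param L a [lead_field] or matrix.
#' @param q_diag unit-trace EBB prior variances (from [ebb_prior]); if
#'   `NULL`, computed from `Y` and `L`.
#' @param upsilon hyperprior mean (default -32, an uninformative shrink).
#' @param Pi_diag hyperprior precisions (default 1e-10: effectively flat).
#' @param tol convergence tolerance on `delta F` in nats (default 1e-2).
#' @param max_iter iteration cap (default 128).
#' @param compute_sources if `TRUE`, also return `J_hat`.
#' @return object of class `inversion_result`: `F`, `accuracy`,
#'   `complexity`, `lambda`, `Sigma_lambda`, `Sigma_a`, `F_trace`,
#'   `iterations`, `converged`, and optionally `J_hat`.
#' @export
reml_optimise <- function(Y, L, q_diag = NULL, upsilon = -32, Pi_diag = 1e-10,
                          tol = 1e-2, max_iter = 128, compute_sources = FALSE) {
  Y <- as_meg(Y)
  Lm <- if (inherits(L, "lead_field")) L$L else as.matrix(L)
  if (nrow(Lm) != Y$Nc) stop("lead field / data channel mismatch", call. = FALSE)
  if (is.null(q_diag)) q_diag <- ebb_prior(Lm, Y)$q
  Nc <- Y$Nc; Nt <- Y$Nt
  Sigma_Y <- tcrossprod(Y$Y) / Nt
  # scale data covariance to unit mean eigenvalue so lambda ~ O(1)
  scale_y <- sum(diag(Sigma_Y)) / Nc
  if (scale_y <= 0) stop("degenerate (all-zero) data", call. = FALSE)
  Sigma_Y <- Sigma_Y / scale_y
  A <- Lm %*% (t(Lm) * q_diag)          # L Qtilde L'
  A <- (A + t(A)) / 2
  A <- A / (sum(diag(A)) / Nc)          # unit mean eigenvalue, like Q1 = I
  nk <- 2L
  upsilon <- rep_len(upsilon, nk)
  Pi <- diag(rep_len(Pi_diag, nk), nk)
  lambda <- rep(0, nk)
  Qk <- list(diag(Nc), A)
  fe_at <- function(lambda, Sigma_lambda) {
    Sg <- exp(lambda[1]) * Qk[[1]] + exp(lambda[2]) * Qk[[2]]
    free_energy(Sigma_Y, Sg, Nt, lambda, upsilon, Pi, Sigma_lambda)
  }
  grad_hess <- function(lambda) {
    Sg <- exp(lambda[1]) * Qk[[1]] + exp(lambda[2]) * Qk[[2]]
    iS <- chol2inv(chol(Sg))
    P <- iS - iS %*% Sigma_Y %*% iS     # d(-2F/Nt)/dSigma direction
    g <- numeric(nk); H <- matrix(0, nk, nk)
    iSQ <- lapply(1:nk, function(k) iS %*% (exp(lambda[k]) * Qk[[k]]))
    for (k in 1:nk) {
      g[k] <- -Nt / 2 * sum(P * t(exp(lambda[k]) * Qk[[k]]))
      for (j in k:nk) {
        H[k, j] <- H[j, k] <- Nt / 2 * sum(iSQ[[k]] * t(iSQ[[j]]))
      }
    }
    g <- g - Pi %*% (lambda - upsilon)
    H <- H + Pi
    list(g = as.numeric(g), H = H)
  }
  gh <- grad_hess(lambda)
  Sigma_lambda <- solve(gh$H)
  fe <- fe_at(lambda, Sigma_lambda)
  F_trace <- fe$F
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    step <- drop(solve(gh$H, gh$g))
    sn <- sqrt(sum(step^2))
    if (sn > 8) step <- step * (8 / sn)   # trust region on log scale
    accepted <- FALSE
    for (half in 0:16) {
      cand <- pmax(-32, lambda + step / 2^half)
      gh_c <- tryCatch(grad_hess(cand), error = function(e) NULL)
      if (is.null(gh_c)) next
      Sl_c <- tryCatch(solve(gh_c$H), error = function(e) NULL)
      if (is.null(Sl_c)) next
      fe_c <- tryCatch(fe_at(cand, Sl_c), error = function(e) NULL)
      if (is.null(fe_c) || !is.finite(fe_c$F)) next
      if (fe_c$F >= fe$F) {
        dF <- fe_c$F - fe$F
        lambda <- cand; gh <- gh_c; Sigma_lambda <- Sl_c; fe <- fe_c
        accepted <- TRUE
        F_trace <- c(F_trace, fe$F)
        if (abs(dF) < tol) converged <- TRUE
        break
      }
    }
    if (!accepted || converged) {
      converged <- converged || !accepted
      break
    }
  }
  if (!is.finite(fe$F)) {
    stop(sprintf("non-finite free energy (lambda = %s)",
                 paste(signif(lambda, 4), collapse = ", ")), call. = FALSE)
  }
  Sigma_a <- (exp(lambda[1]) * Qk[[1]] + exp(lambda[2]) * Qk[[2]]) * scale_y
  res <- structure(list(F = fe$F, accuracy = fe$accuracy,
                        complexity = fe$complexity, terms = fe$terms,
                        lambda = lambda, Sigma_lambda = Sigma_lambda,
                        Sigma_a = Sigma_a, scale_y = scale_y,
                        F_trace = F_trace, iterations = it,
                        converged = converged),
                   class = "inversion_result")
  if (compute_sources) {
    # map the unit-scale hyperparameters back to data units
    tr_a <- sum(diag(Lm %*% (t(Lm) * q_diag))) / Nc
    res$J_hat <- posterior_sources(Y, Lm,
                                   Q_a = exp(lambda[2]) * scale_y / tr_a * q_diag,
                                   Q_eps = exp(lambda[1]) * scale_y)
  }
  res
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf("inversion_result: F = %.2f nats (accuracy %.2f, complexity %.2f)\n",
              x$F, x$accuracy, x$complexity))
  cat(sprintf("  lambda = (%.3f, %.3f), %d iterations, converged: %s\n",
              x$lambda[1], x$lambda[2], x$iterations, x$converged))
  invisible(x)
}

#' Inversion report
#'
#' Writes the scalar summaries of an inversion (free energy and its
#' decomposition, hyperparameters, convergence) to JSON.
#'
#' @param result an [reml_optimise] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_inversion_report <- function(result, path) {
  stopifnot(inherits(result, "inversion_result"))
  jsonlite::write_json(
    list(F = result$F, accuracy = result$accuracy,
         complexity = result$complexity, lambda = result$lambda,
         iterations = result$iterations, converged = result$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
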