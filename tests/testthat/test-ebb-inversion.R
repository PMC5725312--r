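# EBB prior, posterior sources, free energy, ReML.

make_problem <- function(Nc = 20, Nd = 50, Nt = 300, seed = 1) {
  set.seed(seed)
  L <- matrix(rnorm(Nc * Nd), Nc, Nd)
  list(L = L / sqrt(sum(L^2)), Nc = Nc, Nd = Nd, Nt = Nt)
}

test_that("EBB prior localises a strong uncorrelated source", {
  pb <- make_problem(seed = 21)
  set.seed(22)
  k <- 33
  J <- matrix(0, pb$Nd, pb$Nt)
  J[k, ] <- rnorm(pb$Nt)
  Y0 <- pb$L %*% J
  eps <- matrix(rnorm(pb$Nc * pb$Nt), pb$Nc)
  Y <- Y0 + eps * sqrt(sum(Y0^2) / sum(eps^2)) / 10   # 20 dB
  pr <- ebb_prior(pb$L, Y)
  expect_equal(which.max(pr$q), k)
  expect_equal(sum(pr$q), 1, tolerance = 1e-12)
  # scale invariance of the normalised prior
  pr10 <- ebb_prior(pb$L, 10 * Y)
  expect_equal(pr$q, pr10$q, tolerance = 1e-10)
})

test_that("EBB prior is flat for white noise with equal lead-field norms", {
  set.seed(23)
  Nc <- 24; Nd <- 30
  L <- matrix(rnorm(Nc * Nd), Nc, Nd)
  L <- sweep(L, 2, sqrt(colSums(L^2)), `/`)   # identical column norms
  Y <- matrix(rnorm(Nc * 20000), Nc)
  q <- ebb_prior(L, Y)$q
  expect_lt((max(q) - min(q)) / mean(q), 0.05)
})

test_that("posterior sources reproduce the printed estimator identities", {
  pb <- make_problem(Nc = 5, Nd = 8, Nt = 12, seed = 31)
  set.seed(32)
  Y <- matrix(rnorm(5 * 12), 5)
  qa <- runif(8, 0.5, 2)
  qe <- 0.3
  J1 <- posterior_sources(Y, pb$L, qa, qe)
  # Tikhonov normal-equation form (matrix identity oracle)
  Lm <- pb$L
  J2 <- solve(diag(1 / qa) + t(Lm) %*% Lm / qe, t(Lm) %*% Y / qe)
  expect_equal(J1, J2, tolerance = 1e-10)
  # Q_a = 0 gives zero currents
  expect_true(all(posterior_sources(Y, Lm, 0, qe) == 0))
  # noiseless limit with square full-rank L tends to L^-1 Y
  set.seed(33)
  Ls <- matrix(rnorm(25), 5)
  Jn <- posterior_sources(Y, Ls, rep(1, 5), 1e-14)
  expect_equal(Jn, solve(Ls, Y), tolerance = 1e-5)
})

test_that("free energy closed form, KL monotonicity, and hand oracle", {
  Nt <- 10; Nc <- 3
  fe <- free_energy(diag(Nc), diag(Nc), Nt, lambda = 0, upsilon = 0,
                    Pi = matrix(1), Sigma_lambda = matrix(1))
  expect_equal(fe$F, -(Nt * Nc / 2) * (1 + log(2 * pi)), tolerance = 1e-12)
  # for fixed data, accuracy peaks where scalar model variance matches
  sy <- diag(c(2, 2, 2))
  acc <- vapply(c(0.5, 1, 2, 4, 8), function(a) {
    free_energy(sy, a * diag(3), Nt, 0, 0, matrix(1), matrix(1))$accuracy
  }, numeric(1))
  expect_equal(which.max(acc), 3L)  # alpha = 2 matches exactly
  expect_true(all(diff(acc[1:3]) > 0) && all(diff(acc[3:5]) < 0))
  # independent hand computation on a 3-channel toy
  set.seed(41)
  A <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  Sy <- crossprod(matrix(rnorm(9), 3)) / 3 + diag(3)
  lam <- c(0.3, -0.2); up <- c(0, 0)
  Pi <- diag(c(2, 3)); Sl <- diag(c(0.5, 0.25))
  fe2 <- free_energy(Sy, A, Nt, lam, up, Pi, Sl)
  manual <- -Nt / 2 * sum(diag(Sy %*% solve(A))) -
    Nt / 2 * log(det(A)) - Nt * 3 / 2 * log(2 * pi) -
    0.5 * t(lam - up) %*% Pi %*% (lam - up) + 0.5 * log(det(Sl %*% Pi))
  expect_equal(fe2$F, as.numeric(manual), tolerance = 1e-10)
  expect_equal(fe2$F, fe2$accuracy + fe2$complexity, tolerance = 1e-12)
  expect_error(free_energy(Sy, matrix(0, 3, 3), Nt, lam, up, Pi, Sl), "singular")
})

test_that("ReML recovers known hyperparameters within 3 posterior SDs", {
  pb <- make_problem(Nc = 15, Nd = 40, seed = 51)
  q <- rep(1 / pb$Nd, pb$Nd)
  A <- pb$L %*% (t(pb$L) * q)
  A <- A / (sum(diag(A)) / pb$Nc)
  lam_true <- c(-1, 0.5)
  Sg <- exp(lam_true[1]) * diag(pb$Nc) + exp(lam_true[2]) * A
  set.seed(52)
  Y <- t(chol(Sg)) %*% matrix(rnorm(pb$Nc * 10000), pb$Nc)
  res <- reml_optimise(Y, pb$L, q_diag = q, tol = 1e-4, max_iter = 256)
  # reported lambdas live on the internally rescaled problem (data scaled
  # to unit mean variance); the component CONTRAST is scale-invariant
  d_hat <- res$lambda[2] - res$lambda[1]
  sd_d <- sqrt(res$Sigma_lambda[1, 1] + res$Sigma_lambda[2, 2] -
                 2 * res$Sigma_lambda[1, 2])
  expect_lt(abs(d_hat - (lam_true[2] - lam_true[1])), 3 * sd_d + 0.05)
  # and the fitted sensor covariance matches the truth in data units
  expect_lt(norm(res$Sigma_a - Sg, "F") / norm(Sg, "F"), 0.1)
  expect_true(res$converged)
})

test_that("ReML shuts the source component off for noise-only data", {
  pb <- make_problem(Nc = 25, Nd = 60, seed = 61)
  set.seed(62)
  Y <- matrix(rnorm(25 * 2000), 25)
  res <- reml_optimise(Y, pb$L)
  expect_lt(exp(res$lambda[2] - res$lambda[1]), 0.05)
})

test_that("free energy is non-decreasing across ReML iterations", {
  set.seed(71)
  for (rep in 1:10) {
    Nc <- sample(8:20, 1); Nd <- sample(20:50, 1); Nt <- sample(50:200, 1)
    L <- matrix(rnorm(Nc * Nd), Nc, Nd)
    Y <- matrix(rnorm(Nc * Nt), Nc)
    if (rep %% 2 == 0) {    # half the problems carry real signal
      J <- matrix(0, Nd, Nt); J[sample(Nd, 2), ] <- rnorm(2 * Nt)
      Y <- Y + L %*% J / sqrt(sum((L %*% J)^2)) * sqrt(sum(Y^2))
    }
    res <- reml_optimise(Y, L / sqrt(sum(L^2)))
    expect_true(all(diff(res$F_trace) >= -1e-6))
  }
})

test_that("free energy approximates log evidence on a 1-hyperparameter toy", {
  # Sigma = exp(lambda) I_2, flat-ish Gaussian hyperprior; log p(Y) by
  # dense 1-D quadrature over lambda
  Nc <- 2; Nt <- 40
  set.seed(81)
  Y <- matrix(rnorm(Nc * Nt, sd = 1.3), Nc)
  up <- 0; Pi <- matrix(0.1)
  Sy <- tcrossprod(Y) / Nt
  loglik <- function(lam) {
    -Nt / 2 * sum(diag(Sy)) / exp(lam) - Nt / 2 * Nc * lam -
      Nt * Nc / 2 * log(2 * pi)
  }
  lgrid <- seq(-6, 6, length.out = 20001)
  lp <- vapply(lgrid, function(l) {
    loglik(l) + stats::dnorm(l, up, sqrt(1 / Pi[1]), log = TRUE)
  }, numeric(1))
  log_evidence <- log(sum(exp(lp - max(lp))) * diff(lgrid[1:2])) + max(lp)
  # Laplace/ReML counterpart: optimise lambda for the same model
  neg <- function(lam) -(loglik(lam) - 0.5 * Pi[1] * (lam - up)^2)
  opt <- stats::optimize(neg, c(-6, 6))
  lam_hat <- opt$minimum
  h <- 1e-4
  curv <- (neg(lam_hat + h) - 2 * neg(lam_hat) + neg(lam_hat - h)) / h^2
  Sl <- matrix(1 / curv)
  Fa <- free_energy(Sy, exp(lam_hat) * diag(Nc), Nt, lam_hat, up, Pi, Sl)$F
  expect_lt(abs(Fa - log_evidence), 0.5)
})

test_that("lead-field scale changes do not move the free-energy optimum", {
  pb <- make_problem(Nc = 12, Nd = 30, seed = 91)
  set.seed(92)
  J <- matrix(0, pb$Nd, 100); J[7, ] <- rnorm(100)
  Y0 <- pb$L %*% J
  eps <- matrix(rnorm(pb$Nc * 100), pb$Nc)
  Y <- Y0 + eps * sqrt(sum(Y0^2) / sum(eps^2))
  r1 <- reml_optimise(Y, pb$L)
  r2 <- reml_optimise(Y, 100 * pb$L)
  expect_equal(r1$F, r2$F, tolerance = 1e-6)
})
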