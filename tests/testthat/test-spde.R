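test_that("SPDE precision is symmetric PD and scales as tau squared", {
  mesh <- suppressWarnings(build_mesh(matrix(rnorm(80), 40, 2)))
  fem <- fem_matrices(mesh)
  for (alpha in c(1, 2)) {
    Q <- spde_precision(kappa = 3, tau = 0.5, fem, alpha = alpha)
    expect_lt(max(abs(Q - Matrix::t(Q))), 1e-10 * max(abs(Q)))
    expect_silent(Matrix::Cholesky(Q, LDL = FALSE))
    Q4 <- spde_precision(kappa = 3, tau = 1, fem, alpha = alpha)
    expect_equal(as.matrix(Q4), 4 * as.matrix(Q), tolerance = 1e-12)
  }
})

test_that("Matern covariance: limits and special cases", {
  expect_equal(matern_covariance(0, sigma = 2, kappa = 3, nu = 1), 4)
  d <- seq(0.01, 3, length.out = 50)
  expect_equal(matern_covariance(d, 1.5, 2, nu = 0.5),
               1.5^2 * exp(-2 * d), tolerance = 1e-12)
  # nu = 1, kappa * d = 1: value is K_1(1) (approx 0.6019)
  expect_equal(matern_covariance(1, 1, 1, nu = 1), besselK(1, 1))
  expect_equal(round(matern_covariance(1, 1, 1, nu = 1), 4), 0.6019)
})

test_that("SPDE field matches the Matern covariance and variance identity on a fine mesh", {
  # unit square meshed finely; kappa = 10 so the range fits well inside
  grid <- as.matrix(expand.grid(seq(0, 1, 0.25), seq(0, 1, 0.25)))
  mesh <- build_mesh(grid, inner_offset_frac = 0.05, outer_offset_frac = 0.45,
                     max_edge_inner = 0.025)
  fem <- fem_matrices(mesh)
  kappa <- 10
  sigma <- 1
  tau <- evppi:::spde_tau_for_sigma(sigma, kappa)
  Q <- spde_precision(kappa, tau, fem)
  V <- mesh$vertices
  ctr <- which.min((V[, 1] - 0.5)^2 + (V[, 2] - 0.5)^2)
  e <- rep(0, nrow(V)); e[ctr] <- 1
  col <- as.numeric(Matrix::solve(Q, e))
  expect_equal(col[ctr], sigma^2, tolerance = 0.1)
  d <- sqrt((V[, 1] - V[ctr, 1])^2 + (V[, 2] - V[ctr, 2])^2)
  sel <- which(d >= 0.5 / kappa & d <= 2 / kappa)
  cm <- matern_covariance(d[sel], sigma, kappa, nu = 1)
  expect_lt(max(abs(col[sel] / cm - 1)), 0.1)
})

test_that("latent model reduces to generalized least squares when the field is absent", {
  set.seed(8)
  n <- 300
  z <- matrix(rnorm(2 * n), n, 2)
  mesh <- build_mesh(z)
  fem <- fem_matrices(mesh)
  A <- projector(mesh, z)
  H <- cbind(intercept = 1, z1 = z[, 1], z2 = z[, 2])
  y <- drop(H %*% c(1, 2, -1)) + rnorm(n, 0, 0.5)
  gls <- fitted(lm(y ~ z))
  # with the field scale pinned to (numerically) zero, the posterior mean of
  # the linear coefficients is exactly the least-squares fit
  pinned <- evppi:::lgm_log_marginal(
    kappa = 5, tau = evppi:::spde_tau_for_sigma(1e-6, 5), s2 = 0.25,
    y = y, A = A, fem = fem, H = H, want_mean = TRUE)
  fitted_pinned <- as.numeric(H %*% pinned$beta_mean + A %*% pinned$omega_mean)
  expect_lt(max(abs(fitted_pinned - gls)) / sd(y), 1e-3)
  # the empirical-Bayes fit may keep a whisper of field, but stays close
  fit <- lgm_fit(y, A, fem, H, mesh = mesh)
  expect_lt(max(abs(fit$fitted - gls)) / sd(y), 0.1)
  expect_gt(cor(fit$fitted, gls), 0.995)
})

test_that("log marginal matches a dense Gaussian evaluation on a tiny instance", {
  set.seed(9)
  n <- 30
  z <- matrix(runif(2 * n), n, 2)
  mesh <- suppressWarnings(build_mesh(z, max_edge_inner = 0.4))   # small vertex count
  fem <- fem_matrices(mesh)
  A <- projector(mesh, z)
  H <- cbind(1, z)
  y <- rnorm(n)
  kappa <- 4; tau <- 0.3; s2 <- 0.2
  got <- evppi:::lgm_log_marginal(kappa, tau, s2, y, A, fem, H)$log_marginal
  # dense oracle: y ~ N(0, A Q^-1 A' + H H' / beta_prec + s2 I)
  Q <- as.matrix(spde_precision(kappa, tau, fem))
  Ad <- as.matrix(A)
  Sy <- Ad %*% solve(Q, t(Ad)) + H %*% t(H) / 1e-6 + diag(s2, n)
  dense <- -0.5 * determinant(Sy)$modulus - 0.5 * drop(t(y) %*% solve(Sy, y)) -
    n / 2 * log(2 * pi)
  expect_equal(got, as.numeric(dense), tolerance = 1e-6)
})

test_that("hyperparameters are recovered from simulated fields", {
  kappa_true <- 6
  hits <- 0
  reps <- 10
  for (r in seq_len(reps)) {
    set.seed(300 + r)
    n <- 500
    z <- matrix(runif(2 * n), n, 2)
    mesh <- build_mesh(z, max_edge_inner = 0.06)
    fem <- fem_matrices(mesh)
    Q <- spde_precision(kappa_true, evppi:::spde_tau_for_sigma(1, kappa_true), fem)
    L <- Matrix::Cholesky(Q, LDL = FALSE, perm = TRUE)
    zn <- rnorm(nrow(Q))
    om <- as.numeric(Matrix::solve(
      L, Matrix::solve(L, zn, system = "Lt"), system = "Pt"))
    A <- projector(mesh, z)
    H <- cbind(1, z)
    y <- as.numeric(A %*% om) + drop(H %*% c(0.5, 1, -1)) + rnorm(n, 0, 0.2)
    fit <- lgm_fit(y, A, fem, H, mesh = mesh)
    if (abs(log(fit$kappa) - log(kappa_true)) < 0.5) hits <- hits + 1
  }
  expect_gte(hits, 0.8 * reps)
})
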