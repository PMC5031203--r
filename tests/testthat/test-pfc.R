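test_that("response basis spans the centred powers and rejects degenerate input", {
  y <- c(-1, 0, 1, 2, 4)
  b1 <- response_basis(y, 1)
  expect_equal(ncol(b1$basis), 1L)
  expect_lt(abs(sum(b1$basis[, 1])), 1e-12)
  b2 <- response_basis(y, 2)
  # span equals span{y - mean, y^2 - mean}: projecting either onto the basis
  # reproduces it
  raw <- scale(cbind(y, y^2), scale = FALSE)
  proj <- b2$basis %*% crossprod(b2$basis, raw)
  expect_equal(proj, raw, ignore_attr = TRUE)
  expect_error(response_basis(rep(2, 5), 1), "constant")
  expect_error(response_basis(y, 5), "smaller")
})

test_that("fit_pfc recovers the true direction on the d = 1 testbed", {
  tb <- sample_pfc_testbed(pfc_testbed_spec(P = 10, d = 1, h = 1, sigma = 0.5),
                           S = 1000, seed = 42)
  for (str in c("isotropic", "diagonal")) {
    # fit on the raw scale: the testbed's truth is expressed there, and
    # per-column rescaling would rotate the target span
    m <- fit_pfc(as.matrix(tb$phi), tb$y, d = 1, h = 1, structure = str)
    expect_lt(subspace_angle(m$W[, 1, drop = FALSE], tb$Upsilon), 5)
  }
  # the unstructured fit estimates P(P+1)/2 covariance parameters on top,
  # so its direction noise shrinks more slowly; test at a matched n
  tb2 <- sample_pfc_testbed(pfc_testbed_spec(P = 10, d = 1, h = 1, sigma = 0.5),
                            S = 4000, seed = 48)
  mu_ <- fit_pfc(as.matrix(tb2$phi), tb2$y, d = 1, h = 1,
                 structure = "unstructured")
  expect_lt(subspace_angle(mu_$W[, 1, drop = FALSE], tb2$Upsilon), 5)
  noiseless <- sample_pfc_testbed(
    pfc_testbed_spec(P = 10, d = 1, h = 1, sigma = 1e-9), S = 500, seed = 43)
  m0 <- fit_pfc(as.matrix(noiseless$phi), noiseless$y, d = 1, h = 1,
                structure = "isotropic")
  expect_lt(subspace_angle(m0$W[, 1, drop = FALSE], noiseless$Upsilon), 0.1)
})

test_that("a null direction matrix yields a leading eigenvalue at the permutation null", {
  tb <- sample_pfc_testbed(pfc_testbed_spec(P = 6, d = 1, h = 1,
                                            Upsilon = matrix(0, 6, 1), sigma = 1),
                           S = 500, seed = 44)
  X <- scale(as.matrix(tb$phi))
  m <- fit_pfc(X, tb$y, d = 1, h = 1, structure = "isotropic")
  set.seed(45)
  null_ev <- replicate(100, {
    fit_pfc(X, sample(tb$y), d = 1, h = 1, structure = "isotropic")$evals[1]
  })
  expect_lt(m$evals[1], 3 * quantile(null_ev, 0.95))
})

test_that("AIC selection finds the true dimension and degree", {
  hits_d <- 0
  for (r in 1:10) {
    tb <- sample_pfc_testbed(pfc_testbed_spec(P = 8, d = 1, h = 1, sigma = 0.5),
                             S = 600, seed = 100 + r)
    m <- select_pfc(scale(as.matrix(tb$phi)), tb$y)
    hits_d <- hits_d + (m$d == 1)
  }
  expect_gte(hits_d, 8)

  # quadratic link: selected degree at least 2
  hits_h <- 0
  for (r in 1:10) {
    set.seed(200 + r)
    y <- rnorm(600)
    U <- qr.Q(qr(matrix(rnorm(8), 8, 1)))
    phi <- scale(y^2 - mean(y^2), scale = FALSE) %*% t(U) +
      matrix(rnorm(600 * 8, 0, 0.5), 600)
    m <- select_pfc(scale(phi), y)
    hits_h <- hits_h + (m$h >= 2)
  }
  expect_gte(hits_h, 8)
})

test_that("a true 3-dimensional structure trips the sufficiency flag", {
  tb <- sample_pfc_testbed(pfc_testbed_spec(P = 10, d = 3, h = 3, sigma = 0.3),
                           S = 800, seed = 46)
  m <- select_pfc(scale(as.matrix(tb$phi)), tb$y)
  expect_false(m$sufficiency_ok)
})

test_that("projection is standardized, deterministic, and tracks the response when exact", {
  tb <- sample_pfc_testbed(pfc_testbed_spec(P = 6, d = 1, h = 1, sigma = 1e-9),
                           S = 400, seed = 47)
  X <- as.matrix(tb$phi)
  m <- fit_pfc(X, tb$y, d = 1, h = 1, structure = "isotropic")
  z <- project(m, X)
  expect_equal(dim(z), c(400L, 2L))
  expect_equal(apply(z, 2, stats::var), c(z1 = 1, z2 = 1), tolerance = 1e-12)
  expect_identical(z, project(m, X))
  # noiseless d = 1: first coordinate is a monotone transform of f(y)
  expect_gt(abs(cor(z[, 1], tb$y, method = "spearman")), 0.999)
})
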