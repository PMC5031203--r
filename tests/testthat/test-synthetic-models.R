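test_that("influenza arms coincide when the intervention is free and ineffective", {
  # rho = 1 (no risk reduction) and xi = 0 (no cost): NB1 == NB0 exactly
  psa <- sample_influenza(influenza_spec(rho = 1, xi = 0), S = 200, seed = 3)
  expect_equal(psa$nb$t0, psa$nb$t1)
  expect_equal(evpi_mc(psa)$value, 0)
})

test_that("influenza sampling is reproducible and matches its prior moments", {
  a <- sample_influenza(S = 500, seed = 9)
  b <- sample_influenza(S = 500, seed = 9)
  expect_identical(as.matrix(a$draws), as.matrix(b$draws))
  big <- sample_influenza(S = 1e5, seed = 10)
  means <- evppi:::influenza_prior_means(influenza_spec())
  for (p in names(means)) {
    se <- sd(big$draws[[p]]) / sqrt(1e5)
    expect_lt(abs(mean(big$draws[[p]]) - means[[p]]), 4 * se)
  }
})

test_that("influenza conditional expectation is exact in the closed-form cases", {
  spec <- influenza_spec()
  psa <- sample_influenza(spec, S = 100, seed = 4)
  # full focal set: the conditional expectation is the net benefit itself
  full <- influenza_conditional_expectation(spec, psa$draws,
                                            focal = spec$par_names)
  expect_equal(as.matrix(full), as.matrix(psa$nb))
  # empty focal set: constant prior-mean net benefits
  none <- influenza_conditional_expectation(spec, psa$draws, focal = character())
  expect_equal(length(unique(none$t1)), 1L)
  m <- evppi:::influenza_prior_means(spec)
  expect_equal(none$t0[1], spec$k * (-m["pi"] * m["lambda"]) -
                 m[["pi"]] * m[["gamma"]] * m[["lambda"]],
               ignore_attr = TRUE)
})

test_that("influenza conditional expectation matches brute-force inner MC", {
  spec <- influenza_spec()
  focal <- c("pi", "lambda", "rho")
  psa <- sample_influenza(spec, S = 4, seed = 5)
  ce <- influenza_conditional_expectation(spec, psa$draws, focal)
  set.seed(99)
  S_psi <- 1e5
  for (s in 1:4) {
    inner <- sample_nuisance_conditional(spec, psa$draws[s, ], focal, S_psi)
    nb_inner <- net_benefit(spec, inner)
    for (t in c("t0", "t1")) {
      se <- sd(nb_inner[[t]]) / sqrt(S_psi)
      expect_lt(abs(mean(nb_inner[[t]]) - ce[[t]][s]), 3 * se + 1e-9)
    }
  }
})

test_that("law of total expectation holds for the conditional-expectation table", {
  spec <- influenza_spec()
  psa <- sample_influenza(spec, S = 2e4, seed = 6)
  ce <- influenza_conditional_expectation(spec, psa$draws, c("pi", "lambda", "rho"))
  for (t in c("t0", "t1")) {
    se <- sd(psa$nb[[t]]) / sqrt(nrow(psa$nb))
    expect_lt(abs(mean(ce[[t]]) - mean(psa$nb[[t]])), 4 * se)
  }
})

test_that("gaussian-linear generator: identical arms give zero EVPI, seeds reproduce", {
  P <- 3
  spec <- gaussian_linear_spec(mean = 1:3, cov = diag(3),
                               coef = cbind(c(1, 2, 3), c(1, 2, 3)),
                               intercept = c(5, 5))
  psa <- sample_gaussian_linear(spec, S = 300, seed = 2)
  expect_equal(evpi_mc(psa)$value, 0)
  expect_identical(as.matrix(sample_gaussian_linear(spec, 100, seed = 3)$draws),
                   as.matrix(sample_gaussian_linear(spec, 100, seed = 3)$draws))
  expect_error(gaussian_linear_spec(mean = 1:2, cov = matrix(c(1, 2, 2, 1), 2),
                                    coef = cbind(1:2, 2:3), intercept = c(0, 0)),
               "positive definite")
})

test_that("gaussian sample moments converge to the specified moments", {
  spec <- savi_like_spec()
  psa <- sample_gaussian_linear(spec, S = 1e5, seed = 8)
  X <- as.matrix(psa$draws)
  for (j in c(1, 7, 19)) {
    se <- sd(X[, j]) / sqrt(nrow(X))
    expect_lt(abs(mean(X[, j]) - spec$mean[j]), 4 * se)
  }
  expect_lt(abs(cor(X[, 1], X[, 2]) - 0.6), 0.02)
})

test_that("gaussian conditional expectation: independence and identity limits", {
  cov <- diag(c(1, 2, 3))
  spec <- gaussian_linear_spec(mean = c(1, 2, 3), cov = cov,
                               coef = cbind(c(1, 0, 0), c(0, 1, 1)),
                               intercept = c(0, 0))
  psa <- sample_gaussian_linear(spec, S = 50, seed = 3)
  # independent blocks: conditional mean of the nuisance = marginal mean
  ce <- gaussian_linear_conditional_expectation(spec, psa$draws, "theta1")
  expect_equal(ce$t1, rep(2 + 3, 50))
  expect_equal(ce$t0, psa$draws$theta1)
  # focal = all: identity on the net benefits
  full <- gaussian_linear_conditional_expectation(spec, psa$draws,
                                                  spec$par_names)
  expect_equal(as.matrix(full), as.matrix(psa$nb))
})

test_that("correlated gaussian conditional expectation matches nested MC", {
  spec <- savi_like_spec()
  focal <- fixture_focal(5)
  psa <- sample_gaussian_linear(spec, S = 3, seed = 13)
  ce <- gaussian_linear_conditional_expectation(spec, psa$draws, focal)
  set.seed(100)
  S_psi <- 1e5
  for (s in 1:3) {
    inner <- sample_nuisance_conditional(spec, psa$draws[s, ], focal, S_psi)
    nb_inner <- net_benefit(spec, inner)
    for (t in c("t0", "t1")) {
      se <- sd(nb_inner[[t]]) / sqrt(S_psi)
      expect_lt(abs(mean(nb_inner[[t]]) - ce[[t]][s]), 3 * se)
    }
  }
})

test_that("bilinear net-benefit terms are handled exactly via conditional second moments", {
  cov <- matrix(c(1, 0.5, 0.5, 2), 2)
  bl <- data.frame(treatment = 2L, i = 1L, j = 2L, w = 1.5)
  spec <- gaussian_linear_spec(mean = c(0.3, -0.2), cov = cov,
                               coef = cbind(c(1, 1), c(0.5, 2)),
                               intercept = c(0, 1), bilinear = bl)
  psa <- sample_gaussian_linear(spec, S = 5, seed = 21)
  ce <- gaussian_linear_conditional_expectation(spec, psa$draws, "theta1")
  # manual: E[NB1|th1] = 0.5 th1 + 2 E[th2|th1] + 1 + 1.5 th1 E[th2|th1]
  m2 <- -0.2 + 0.5 / 1 * (psa$draws$theta1 - 0.3)
  expect_equal(ce$t1, 0.5 * psa$draws$theta1 + 2 * m2 + 1 +
                 1.5 * (psa$draws$theta1 * m2), tolerance = 1e-12)
  # focal = all: equals the realized net benefit including the product term
  full <- gaussian_linear_conditional_expectation(spec, psa$draws,
                                                  spec$par_names)
  expect_equal(as.matrix(full), as.matrix(psa$nb))
})

test_that("pfc testbed: null direction, noiseless line, reproducibility", {
  null_tb <- sample_pfc_testbed(pfc_testbed_spec(P = 5, d = 1, h = 1,
                                                 Upsilon = matrix(0, 5, 1)),
                                S = 400, seed = 1)
  expect_lt(max(abs(cor(as.matrix(null_tb$phi), null_tb$y))), 0.15)

  line_tb <- sample_pfc_testbed(pfc_testbed_spec(P = 4, d = 1, h = 1,
                                                 sigma = 1e-12), S = 50, seed = 2)
  # noiseless d = 1, h = 1: predictors lie exactly on a line indexed by y
  fit <- lm(as.matrix(line_tb$phi) ~ scale(line_tb$y, scale = FALSE))
  expect_lt(max(abs(residuals(fit))), 1e-9)

  expect_identical(sample_pfc_testbed(S = 100, seed = 3)$phi,
                   sample_pfc_testbed(S = 100, seed = 3)$phi)
})
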