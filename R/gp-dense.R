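#' GP design matrix
#'
#' Linear-trend design used by both regression routes: a leading column of
#' ones followed by the focal parameter values, so the Gaussian process is
#' fitted around a linear mean `H beta`.
#'
#' @param phi data frame or matrix of (standardized) focal draws, `S x P`.
#' @return An `S x (P + 1)` numeric matrix.
#' @export
design_matrix <- function(phi) {
  phi <- as.matrix(phi)
  if (nrow(phi) == 0) stop("empty input")
  H <- cbind(intercept = 1, phi)
  storage.mode(H) <- "double"
  H
}

#' Squared-exponential covariance
#'
#' `C(r, s) = sigma2 * exp(-sum_p ((phi_rp - phi_sp) / delta_p)^2)`, with one
#' smoothness parameter `delta_p` per focal dimension. Larger `delta_p`
#' means a flatter kernel in dimension `p` (higher correlation between
#' distant points); the value at zero distance is `sigma2`.
#'
#' @param phi_r `n_r x P` matrix of input locations.
#' @param phi_s optional `n_s x P` matrix; defaults to `phi_r`.
#' @param delta length-`P` positive smoothness parameters.
#' @param sigma2 marginal variance.
#' @return The `n_r x n_s` covariance matrix.
#' @export
sqexp_cov <- function(phi_r, phi_s = NULL, delta, sigma2 = 1) {
  phi_r <- as.matrix(phi_r)
  if (is.null(phi_s)) phi_s <- phi_r else phi_s <- as.matrix(phi_s)
  P <- ncol(phi_r)
  stopifnot(length(delta) == P, ncol(phi_s) == P)
  if (any(delta <= 0)) stop("`delta` must be strictly positive")
  if (sigma2 <= 0) stop("`sigma2` must be strictly positive")
  expo <- matrix(0, nrow(phi_r), nrow(phi_s))
  for (p in seq_len(P)) {
    expo <- expo + (outer(phi_r[, p], phi_s[, p], "-") / delta[p])^2
  }
  sigma2 * exp(-expo)
}

# Cholesky with escalating diagonal jitter: 1e-10 relative, x10 up to 1e-6.
chol_jitter <- function(A) {
  scale <- mean(diag(A))
  for (j in c(0, 1e-10, 1e-9, 1e-8, 1e-7, 1e-6)) {
    ch <- tryCatch(chol(A + diag(j * scale, nrow(A))), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
  }
  stop("covariance matrix numerically singular even after jitter up to 1e-6")
}

# squared per-dimension distances, cached once per optimisation
sq_dists <- function(phi) {
  lapply(seq_len(ncol(phi)), function(p) outer(phi[, p], phi[, p], "-")^2)
}

# Negative log marginal posterior of (log delta, log eta) with beta (flat
# prior) and sigma^2 (scale-invariant prior) integrated analytically:
#   0.5 log|St| + 0.5 log|H' St^-1 H| + ((n-q)/2) log(y' Pm y),
# St = R(delta) + eta I (correlation scale), Pm the projected precision.
# Returns value and, if grad = TRUE, the analytic gradient, using
# d(obj) = 0.5 tr(Pm dSt) - c (u' dSt u)/S2 with u = Pm y.
gp_nlm_core <- function(par, y, H, D2, grad = FALSE) {
  P <- length(D2)
  delta <- exp(par[seq_len(P)])
  eta <- exp(par[P + 1])
  n <- length(y); q <- ncol(H)
  expo <- matrix(0, n, n)
  for (p in seq_len(P)) expo <- expo + D2[[p]] / delta[p]^2
  R <- exp(-expo)
  St <- R
  diag(St) <- diag(St) + eta
  ch <- chol_jitter(St)
  CiH <- backsolve(ch, forwardsolve(t(ch), H))
  Ciy <- backsolve(ch, forwardsolve(t(ch), y))
  M <- crossprod(H, CiH)
  chM <- chol_jitter(M)
  Hy <- crossprod(H, Ciy)
  w <- backsolve(chM, forwardsolve(t(chM), Hy))
  S2 <- max(drop(crossprod(y, Ciy) - crossprod(Hy, w)), 1e-300)
  cc <- (n - q) / 2
  val <- sum(log(diag(ch))) + sum(log(diag(chM))) + cc * log(S2)
  if (!grad) return(list(value = val, S2 = S2))
  Ci <- chol2inv(ch)
  CiHMi <- CiH %*% backsolve(chM, forwardsolve(t(chM), t(CiH)))
  Pm <- Ci - CiHMi
  u <- drop(Ciy - CiH %*% w)
  g <- numeric(P + 1)
  for (p in seq_len(P)) {
    D <- R * (2 * D2[[p]] / delta[p]^2)
    g[p] <- 0.5 * sum(Pm * D) - cc * drop(crossprod(u, D %*% u)) / S2
  }
  g[P + 1] <- eta * (0.5 * sum(diag(Pm)) - cc * sum(u^2) / S2)
  list(value = val, grad = g, S2 = S2)
}

#' Negative log marginal posterior of the GP hyperparameters
#'
#' The model is `y ~ Normal(H beta, sigma2 (R(delta) + eta I))` with
#' `eta = nugget/sigma2`. With a flat prior on `beta` and `p(sigma2) ~
#' 1/sigma2`, both are integrated analytically, leaving a 2-parameter-class
#' objective in `(log delta, log eta)` whose mode is found numerically.
#' Invariant to adding a constant to `y` (absorbed by the intercept) and to
#' jointly permuting the rows of `y` and `phi`.
#'
#' @param par numeric vector `c(log(delta), log(eta))`, length `P + 1`.
#' @param y response vector (one treatment contrast).
#' @param phi standardized focal draws, `n x P`.
#' @return The scalar value, up to an additive constant.
#' @export
gp_neg_log_marginal <- function(par, y, phi) {
  phi <- as.matrix(phi)
  stopifnot(length(par) == ncol(phi) + 1, nrow(phi) == length(y))
  if (length(y) <= ncol(phi) + 2) stop("need n > P + 2 observations")
  gp_nlm_core(par, y, design_matrix(phi), sq_dists(phi))$value
}

#' Fit a dense squared-exponential GP to one net-benefit contrast
#'
#' Hyperparameters `(delta, eta)` are estimated by multi-start L-BFGS
#' optimisation (analytic gradients) of [gp_neg_log_marginal()] on a seeded
#' random subsample of the draws — estimating hyperparameters on a subset
#' caps the `O(n^3)` cost while the fitted values still use every draw. The
#' fitted conditional expectations on all `S` draws are the GP posterior
#' mean `ghat = H beta + C (C + nugget I)^{-1} (y - H beta)` with `beta` the
#' generalized-least-squares coefficient under the optimized covariance.
#'
#' @param y response vector, length `S`.
#' @param phi standardized focal draws, `S x P`.
#' @param subsample_size draws used for hyperparameter estimation
#'   (default 500); the full sample is used when `S` is smaller, or on
#'   request via `subsample_size = Inf`.
#' @param seed seed for the subsample and the random starts.
#' @param starts number of random starts in addition to the moment-based
#'   start (`delta_p` = column range).
#' @return An object of class `gp_fit`: hyperparameters, fitted values,
#'   subsample index, convergence flag and optimizer trace.
#' @export
gp_fit <- function(y, phi, subsample_size = 500, seed = 1, starts = 3) {
  phi <- as.matrix(phi)
  S <- length(y)
  stopifnot(nrow(phi) == S)
  P <- ncol(phi)
  n_sub <- min(subsample_size, S)
  set.seed(seed)
  idx <- sort(sample.int(S, n_sub))
  # degenerate case: response numerically in the span of the linear trend;
  # the GP adds nothing and the marginal posterior is flat in (delta, eta)
  H0 <- design_matrix(phi)
  ls_fit <- stats::lm.fit(H0, y)
  if (stats::sd(ls_fit$residuals) <= 1e-10 * max(stats::sd(y), 1)) {
    fitted <- drop(H0 %*% ls_fit$coefficients)
    return(structure(
      list(delta = apply(phi, 2, function(x) diff(range(x))),
           sigma2 = 1e-300, nugget = 0, eta = 0,
           beta = ls_fit$coefficients, fitted = fitted,
           residuals = y - fitted, subsample_index = idx, converged = TRUE,
           objective = NA_real_,
           trace = list(note = "exact linear response: least-squares shortcut"),
           n = S, P = P),
      class = "gp_fit"))
  }
  phi_s <- phi[idx, , drop = FALSE]
  y_s <- y[idx]
  H_s <- design_matrix(phi_s)
  D2 <- sq_dists(phi_s)
  rng <- apply(phi_s, 2, function(x) diff(range(x)))
  rng[rng == 0] <- 1
  start_list <- c(
    list(c(log(rng), log(0.25))),
    lapply(seq_len(starts), function(i) {
      c(log(rng * stats::runif(P, 0.1, 2)), log(10^stats::runif(1, -4, 0)))
    })
  )
  lower <- c(rep(log(1e-2), P), log(1e-9))
  upper <- c(rep(log(1e4), P), log(1e3))
  best <- NULL
  trace <- list()
  for (st in start_list) {
    opt <- tryCatch(
      stats::optim(st,
                   fn = function(p) gp_nlm_core(p, y_s, H_s, D2)$value,
                   gr = function(p) gp_nlm_core(p, y_s, H_s, D2, grad = TRUE)$grad,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 100)),
      error = function(e) NULL)
    if (is.null(opt)) next
    trace[[length(trace) + 1]] <- c(value = opt$value, convergence = opt$convergence)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all optimizer starts failed for the GP hyperparameters")
  delta <- exp(best$par[seq_len(P)])
  eta <- exp(best$par[P + 1])
  S2 <- gp_nlm_core(best$par, y_s, H_s, D2)$S2
  sigma2 <- S2 / (n_sub - P - 1)
  # fitted values on the full sample at the optimized hyperparameters
  H <- design_matrix(phi)
  R <- sqexp_cov(phi, delta = delta, sigma2 = 1)
  St <- R
  diag(St) <- diag(St) + eta
  ch <- chol_jitter(St)
  CiH <- backsolve(ch, forwardsolve(t(ch), H))
  Ciy <- backsolve(ch, forwardsolve(t(ch), y))
  M <- crossprod(H, CiH)
  beta <- solve(M, crossprod(H, Ciy))
  resid0 <- y - drop(H %*% beta)
  fitted <- y - eta * drop(backsolve(ch, forwardsolve(t(ch), resid0)))
  structure(
    list(delta = delta, sigma2 = sigma2, nugget = eta * sigma2, eta = eta,
         beta = drop(beta), fitted = fitted, residuals = y - fitted,
         subsample_index = idx, converged = best$convergence == 0,
         objective = best$value, trace = trace, n = S, P = P),
    class = "gp_fit"
  )
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("<gp_fit> n = %d, P = %d, converged: %s\n", x$n, x$P, x$converged))
  cat("  delta:", paste(signif(x$delta, 3), collapse = ", "), "\n")
  cat(sprintf("  sigma2 = %.4g, nugget = %.4g\n", x$sigma2, x$nugget))
  invisible(x)
}

#' @export
glance.gp_fit <- function(x, ...) {
  tibble::tibble(n = x$n, P = x$P, sigma2 = x$sigma2, nugget = x$nugget,
                 eta = x$eta, objective = x$objective, converged = x$converged)
}

#' EVPPI by dense Gaussian-process regression
#'
#' The reference non-parametric-regression estimator. Each treatment's net
#' benefit is regarded as a noisy observation of its conditional expectation
#' given the focal parameters; those conditional-expectation surfaces are
#' estimated by GP regression with a squared-exponential kernel and the
#' fitted values feed [evppi_from_fitted()].
#'
#' The responses are re-parameterized as incremental net benefits
#' `NB_t - NB_0` (with the reference fit identically zero): subtracting a
#' common function of the focal parameters from all arms leaves the
#' mean-of-maxima minus max-of-means combiner unchanged, so this halves the
#' number of fits for two-arm models without changing the estimate.
#'
#' @param psa a [psa_dataset].
#' @param focal focal parameter names.
#' @param subsample_size,seed,starts passed to [gp_fit()].
#' @return A list with `estimate` (a [voi_estimate]) and `fits` (one
#'   [gp_fit] per contrast).
#' @export
gp_evppi <- function(psa, focal, subsample_size = 500, seed = 1, starts = 3) {
  stopifnot(inherits(psa, "psa_dataset"))
  phi <- select_parameters(psa, focal, standardize = TRUE)
  keep <- vapply(phi, function(x) stats::sd(x) > 0, TRUE)
  if (!all(keep)) {
    warning("dropping constant focal column(s): ",
            paste(names(phi)[!keep], collapse = ", "))
    phi <- phi[keep]
  }
  nb <- as.matrix(psa$nb)
  Tn <- ncol(nb)
  S <- nrow(nb)
  ghat <- matrix(0, S, Tn, dimnames = list(NULL, psa$treatments))
  fits <- list()
  non_conv <- character()
  for (t in 2:Tn) {
    y <- nb[, t] - nb[, 1]
    if (stats::sd(y) == 0 || ncol(phi) == 0) {
      ghat[, t] <- mean(y)
      next
    }
    fit <- gp_fit(y, phi, subsample_size = subsample_size, seed = seed,
                  starts = starts)
    if (!fit$converged) non_conv <- c(non_conv, psa$treatments[t])
    fits[[psa$treatments[t]]] <- fit
    ghat[, t] <- fit$fitted
  }
  if (length(non_conv)) {
    warning("GP optimisation did not converge for contrast(s): ",
            paste(non_conv, collapse = ", "))
  }
  est <- evppi_from_fitted(
    ghat, method = "gp", focal_names = focal, k = psa$k, S = S, seed = seed,
    diagnostics = list(subsample_size = min(subsample_size, S),
                       non_converged = non_conv))
  list(estimate = est, fits = fits)
}
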