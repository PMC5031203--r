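#' Polynomial response basis for inverse regression
#'
#' Builds the centred polynomial basis `f(y) = (y, y^2, ..., y^h)` used by
#' the principal-fitted-components model, orthogonalized degree by degree
#' for numerical conditioning (the column span — the only thing the fit
#' depends on — is unchanged).
#'
#' @param y response vector (a net-benefit contrast).
#' @param h polynomial degree, `1 <= h < length(y)`.
#' @return An object of class `response_basis` with the `n x h` orthonormal
#'   basis matrix.
#' @export
response_basis <- function(y, h) {
  n <- length(y)
  if (h < 1) stop("`h` must be at least 1")
  if (h >= n) stop("`h` must be smaller than the number of observations")
  if (!all(is.finite(y))) stop("`y` contains non-finite values")
  if (stats::sd(y) == 0) stop("constant response: inverse-regression basis is identically zero")
  raw <- sapply(seq_len(h), function(j) y^j)
  raw <- scale(raw, scale = FALSE)
  qr_ <- qr(raw)
  if (qr_$rank < h) stop("response powers are numerically collinear at degree ", h)
  basis <- qr.Q(qr_)[, seq_len(h), drop = FALSE]
  structure(list(basis = basis, degree = h), class = "response_basis")
}

# symmetric inverse square root with an eigenvalue floor
sym_inv_sqrt <- function(A, floor_frac = 1e-10) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, floor_frac * max(e$values))
  list(inv_sqrt = e$vectors %*% (t(e$vectors) / sqrt(vals)),
       logdet = sum(log(vals)))
}

#' Fit a principal-fitted-components model
#'
#' Model-based inverse regression: the focal parameters are modelled as
#' `phi = mu + Upsilon f(y) + eps` with a polynomial basis `f` of degree `h`
#' and Gaussian errors. The maximum-likelihood reduction
#' `R(phi) = Upsilon' Delta^{-1} phi` is spanned by the top-`d` eigenvectors
#' of the fitted covariance in the error-covariance inner product; under the
#' model, the net benefit is independent of `phi` given `R(phi)`.
#'
#' Three error structures are supported. `"isotropic"` (`Delta = sigma2 I`)
#' and `"diagonal"` (independent heteroskedastic errors, fitted by
#' alternating updates) are cheap but their reduction ignores correlation
#' among the parameters; `"unstructured"` (the default) estimates the full
#' error covariance in closed form and is the one that stays sufficient for
#' correlated PSA draws — the common case — at the price of `P(P+1)/2`
#' covariance parameters, harmless while `P` is well below the number of
#' draws.
#'
#' @param phi `n x P` data frame or matrix of (standardized) focal draws.
#' @param y response vector.
#' @param d structural dimension, `1 <= d <= min(P, h)`.
#' @param h polynomial basis degree.
#' @param structure `"unstructured"`, `"diagonal"` or `"isotropic"`.
#' @return An object of class `pfc_model` with the direction matrix, the
#'   projection weights, the error-structure estimate, the maximized
#'   log-likelihood and the AIC (parameters counted as `P` for `mu`,
#'   `d(P-d)` for the direction span on its Grassmann manifold, `d h` basis
#'   coefficients, plus 1, `P` or `P(P+1)/2` error parameters).
#' @export
fit_pfc <- function(phi, y, d, h,
                    structure = c("unstructured", "diagonal", "isotropic")) {
  structure_ <- match.arg(structure)
  X <- as.matrix(phi)
  n <- nrow(X); p <- ncol(X)
  stopifnot(d >= 1, d <= min(p, h))
  if (n <= p) stop("need more observations than parameters (n > P)")
  Fb <- response_basis(y, h)$basis
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  Sig <- crossprod(Xc) / n
  fit_part <- Fb %*% crossprod(Fb, Xc)     # P_F Xc
  Sfit <- crossprod(fit_part) / n
  n_coord <- min(max(d, 2), p)             # directions kept for projection

  if (structure_ == "isotropic") {
    ev <- eigen(Sfit, symmetric = TRUE)
    V <- ev$vectors[, seq_len(n_coord), drop = FALSE]
    rss <- n * (sum(diag(Sig)) - sum(ev$values[seq_len(d)]))
    sigma2 <- max(rss / (n * p), 1e-300)
    loglik <- -(n * p / 2) * (log(2 * pi * sigma2) + 1)
    W <- V
    Delta_hat <- sigma2
    evals <- ev$values
  } else if (structure_ == "diagonal") {
    Dd <- pmax(colMeans(Xc^2), 1e-12)
    for (it in 1:25) {
      xs <- sweep(Xc, 2, sqrt(Dd), "/")
      fs <- Fb %*% crossprod(Fb, xs)
      evs <- eigen(crossprod(fs) / n, symmetric = TRUE)
      V <- evs$vectors[, seq_len(d), drop = FALSE]
      fitted_s <- fs %*% V %*% t(V)
      resid <- Xc - sweep(fitted_s, 2, sqrt(Dd), "*")
      Dd_new <- pmax(colMeans(resid^2), 1e-12)
      if (max(abs(log(Dd_new / Dd))) < 1e-8) { Dd <- Dd_new; break }
      Dd <- Dd_new
    }
    xs <- sweep(Xc, 2, sqrt(Dd), "/")
    fs <- Fb %*% crossprod(Fb, xs)
    evs <- eigen(crossprod(fs) / n, symmetric = TRUE)
    V <- evs$vectors[, seq_len(n_coord), drop = FALSE]
    fitted_s <- fs %*% evs$vectors[, seq_len(d), drop = FALSE] %*%
      t(evs$vectors[, seq_len(d), drop = FALSE])
    resid <- Xc - sweep(fitted_s, 2, sqrt(Dd), "*")
    loglik <- -(n * p / 2) * log(2 * pi) - (n / 2) * sum(log(Dd)) -
      0.5 * sum(sweep(resid^2, 2, Dd, "/"))
    W <- V / sqrt(Dd)                       # coords = Xc %*% W
    Delta_hat <- Dd
    evals <- evs$values
  } else {
    Sres <- Sig - Sfit
    si <- sym_inv_sqrt(Sres)
    M <- si$inv_sqrt %*% Sfit %*% si$inv_sqrt
    em <- eigen((M + t(M)) / 2, symmetric = TRUE)
    V <- em$vectors[, seq_len(n_coord), drop = FALSE]
    lam_rest <- pmax(em$values[-seq_len(d)], 0)
    loglik <- -(n * p / 2) * (1 + log(2 * pi)) - (n / 2) * si$logdet -
      (n / 2) * sum(log1p(lam_rest))
    W <- si$inv_sqrt %*% V
    Delta_hat <- Sres
    evals <- em$values
  }

  npar <- p + d * (p - d) + d * h +
    switch(structure_, isotropic = 1, diagonal = p, unstructured = p * (p + 1) / 2)
  structure(
    list(mu = mu, W = W, d = d, h = h, structure = structure_,
         Delta_hat = Delta_hat, loglik = loglik, aic = -2 * loglik + 2 * npar,
         npar = npar, evals = evals, n = n, P = p, sufficiency_ok = NA),
    class = "pfc_model"
  )
}

#' @export
print.pfc_model <- function(x, ...) {
  cat(sprintf("<pfc_model> P = %d, d = %d, h = %d, structure = %s, AIC = %.2f\n",
              x$P, x$d, x$h, x$structure, x$aic))
  if (!is.na(x$sufficiency_ok) && !x$sufficiency_ok) {
    cat("  ! AIC prefers d > 2: the 2-D projection may lose information\n")
  }
  invisible(x)
}

#' @export
tidy.pfc_model <- function(x, ...) {
  W <- x$W
  tibble::tibble(
    parameter = rep(names(x$mu) %||% paste0("phi", seq_len(x$P)), ncol(W)),
    component = rep(seq_len(ncol(W)), each = x$P),
    weight = as.numeric(W)
  )
}

#' @export
glance.pfc_model <- function(x, ...) {
  tibble::tibble(P = x$P, d = x$d, h = x$h, structure = x$structure,
                 loglik = x$loglik, aic = x$aic, npar = x$npar,
                 sufficiency_ok = x$sufficiency_ok)
}

#' Select a PFC model by AIC
#'
#' Fits every combination of structural dimension `d`, basis degree `h`
#' (with `d <= min(P, h)`) and error structure, and returns the
#' AIC-minimizing model. The returned model always carries two projection
#' directions (when `P >= 2`): if the selected `d` is 1, the second
#' eigenvector can only add information, so there is no harm in keeping it;
#' if the AIC prefers `d > 2`, `sufficiency_ok` is set to `FALSE` because a
#' 2-D projection may then lose information and the downstream estimate
#' deserves extra model checking.
#'
#' @param phi `n x P` standardized focal draws.
#' @param y response vector.
#' @param d_grid candidate structural dimensions.
#' @param h_grid candidate basis degrees.
#' @param structure_grid candidate error structures.
#' @return The AIC-best [fit_pfc()] model with `sufficiency_ok` filled in.
#' @export
select_pfc <- function(phi, y, d_grid = 1:4, h_grid = 1:4,
                       structure_grid = c("unstructured", "diagonal", "isotropic")) {
  p <- ncol(as.matrix(phi))
  best <- NULL
  fail <- 0
  for (str in structure_grid) for (h in h_grid) {
    for (d in d_grid[d_grid <= min(p, h)]) {
      m <- tryCatch(fit_pfc(phi, y, d = d, h = h, structure = str),
                    error = function(e) NULL)
      if (is.null(m)) { fail <- fail + 1; next }
      if (is.null(best) || m$aic < best$aic) best <- m
    }
  }
  if (is.null(best)) stop("all PFC fits failed over the requested grids")
  best$sufficiency_ok <- best$d <= 2
  best
}

#' Project focal draws onto the fitted 2-D reduction
#'
#' Applies the fitted sufficient reduction and returns the first two
#' coordinates, each standardized to zero mean and unit variance (the
#' rescaling recommended before meshing; it does not change the estimated
#' EVPPI). Deterministic: identical inputs give identical output.
#'
#' @param model a [fit_pfc()] / [select_pfc()] model.
#' @param phi draws with the same columns the model was fitted to.
#' @return An `n x 2` matrix of standardized reduction coordinates.
#' @export
project <- function(model, phi) UseMethod("project")

#' @export
project.pfc_model <- function(model, phi) {
  X <- as.matrix(phi)
  stopifnot(ncol(X) == model$P)
  Xc <- sweep(X, 2, model$mu)
  coords <- Xc %*% model$W
  if (ncol(coords) == 1) {
    warning("only one reduction direction available (P = 1); second coordinate set to 0")
    coords <- cbind(coords, 0)
  }
  coords <- coords[, 1:2, drop = FALSE]
  out <- apply(coords, 2, function(z) {
    s <- stats::sd(z)
    if (s == 0) z - mean(z) else (z - mean(z)) / s
  })
  colnames(out) <- c("z1", "z2")
  out
}
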