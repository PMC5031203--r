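#' Finite-element matrices of a triangular mesh
#'
#' Piecewise-linear ("hat") basis functions on the triangulation give the
#' two matrices discretizing the SPDE operator: the lumped mass matrix `C`
#' (diagonal; `C_ii` is one third of the total area of the triangles
#' incident to vertex `i` — lumping is what keeps the `G C^{-1} G` term of
#' the precision sparse) and the stiffness matrix `G` with
#' `G_ij = integral of grad(psi_i) . grad(psi_j)`. Constants lie in the
#' kernel of the Laplacian, so every row of `G` sums to zero.
#'
#' @param mesh an [build_mesh()] mesh (any conforming triangulation with
#'   counter-clockwise triangles works).
#' @return A list with sparse `C` (diagonal) and `G` (symmetric).
#' @export
fem_matrices <- function(mesh) {
  V <- mesh$vertices; Tm <- mesh$triangles
  x1 <- V[Tm[, 1], 1]; y1 <- V[Tm[, 1], 2]
  x2 <- V[Tm[, 2], 1]; y2 <- V[Tm[, 2], 2]
  x3 <- V[Tm[, 3], 1]; y3 <- V[Tm[, 3], 2]
  area <- 0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
  if (any(area <= 0)) stop("zero-area or clockwise triangle in mesh")
  # gradients of the hat functions: grad psi_r = (b_r, c_r) / (2 area)
  B <- cbind(y2 - y3, y3 - y1, y1 - y2)
  Cc <- cbind(x3 - x2, x1 - x3, x2 - x1)
  ii <- jj <- integer(0); vv <- numeric(0)
  for (r in 1:3) for (s in 1:3) {
    ii <- c(ii, Tm[, r]); jj <- c(jj, Tm[, s])
    vv <- c(vv, (B[, r] * B[, s] + Cc[, r] * Cc[, s]) / (4 * area))
  }
  nv <- nrow(V)
  G <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(nv, nv))
  lump <- Matrix::sparseMatrix(i = c(Tm), j = rep(1L, 3 * nrow(Tm)),
                               x = rep(area / 3, 3), dims = c(nv, 1))
  list(C = Matrix::Diagonal(x = as.numeric(lump)),
       G = Matrix::forceSymmetric((G + Matrix::t(G)) / 2))
}

#' Sparse SPDE precision of the Matern vertex weights
#'
#' The Matern field with smoothness `nu = alpha - 1` (in two dimensions)
#' solves `tau (kappa^2 - Laplacian)^(alpha/2) g = W`; its finite-element
#' discretization makes the vertex weights a Gauss-Markov random field with
#' sparse precision
#' `Q = tau^2 (kappa^4 C + 2 kappa^2 G + G C^{-1} G)` for `alpha = 2`, or
#' `Q = tau^2 (kappa^2 C + G)` for `alpha = 1`. Non-zeros reach only
#' second-order mesh neighbours, which is what buys the fast sparse
#' factorizations downstream.
#'
#' @param kappa inverse range parameter (> 0).
#' @param tau precision scale (> 0).
#' @param fem matrices from [fem_matrices()].
#' @param alpha SPDE order, 1 or 2 (default 2, i.e. `nu = 1`).
#' @return Sparse symmetric positive-definite precision matrix.
#' @export
spde_precision <- function(kappa, tau, fem, alpha = 2) {
  stopifnot(kappa > 0, tau > 0, alpha %in% c(1, 2))
  C <- fem$C; G <- fem$G
  Q <- if (alpha == 2) {
    Cinv <- Matrix::Diagonal(x = 1 / Matrix::diag(C))
    kappa^4 * C + 2 * kappa^2 * G + G %*% Cinv %*% G
  } else {
    kappa^2 * C + G
  }
  Matrix::forceSymmetric(tau^2 * Q)
}

#' Matern covariance function
#'
#' `C(d) = sigma^2 / (Gamma(nu) 2^(nu-1)) * (kappa d)^nu K_nu(kappa d)`,
#' with `K_nu` the modified Bessel function of the second kind; the limit at
#' `d = 0` is `sigma^2`, and `nu = 1/2` reduces to the exponential
#' covariance `sigma^2 exp(-kappa d)`. For the SPDE representation with
#' order `alpha` in two dimensions, `nu = alpha - 1` and the marginal
#' variance identity is
#' `sigma^2 = Gamma(nu) / (Gamma(alpha) (4 pi)) * kappa^(-2 nu) tau^(-2)`.
#'
#' @param d distance(s), >= 0.
#' @param sigma marginal standard deviation.
#' @param kappa inverse range.
#' @param nu smoothness.
#' @return Covariance value(s).
#' @export
matern_covariance <- function(d, sigma, kappa, nu = 1) {
  stopifnot(all(d >= 0), sigma > 0, kappa > 0, nu > 0)
  out <- rep(sigma^2, length(d))
  pos <- d > 0
  kd <- kappa * d[pos]
  out[pos] <- sigma^2 / (gamma(nu) * 2^(nu - 1)) * kd^nu * besselK(kd, nu)
  out
}

# marginal sd implied by (kappa, tau) under the variance identity (2-D)
spde_marginal_sigma <- function(kappa, tau, alpha = 2) {
  nu <- alpha - 1
  if (alpha == 2) sqrt(1 / (4 * pi * kappa^2 * tau^2))
  else sqrt(1 / (4 * pi * tau^2))  # alpha = 1: Gamma(0) form degenerates; surface-level scale
}

# tau giving marginal sd `sigma` at inverse range kappa (alpha = 2)
spde_tau_for_sigma <- function(sigma, kappa) 1 / (sqrt(4 * pi) * sigma * kappa)
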