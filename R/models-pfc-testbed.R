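#' Inverse-regression testbed generator
#'
#' Generates data from the principal-fitted-components model itself,
#' `phi = mu + Upsilon f(y) + eps`, with a known direction matrix, so that
#' subspace recovery and dimension selection can be tested against ground
#' truth. The response is drawn first, the polynomial basis `f(y) = (y, y^2,
#' ..., y^h)` (centred) is built, and the predictors are the structured mean
#' plus Gaussian noise.
#'
#' @param P number of predictors.
#' @param d true structural dimension.
#' @param Upsilon `P x d` direction matrix; defaults to random orthonormal
#'   columns (drawn inside the seeded generator).
#' @param h degree of the polynomial basis used to build the mean.
#' @param sigma error scale: a scalar (isotropic) or length-`P` vector
#'   (diagonal structure).
#' @param response a function `function(S)` drawing the response; defaults
#'   to standard normal.
#' @return An object of class `pfc_testbed_spec`.
#' @export
pfc_testbed_spec <- function(P = 10, d = 1, Upsilon = NULL, h = 1,
                             sigma = 0.5, response = stats::rnorm) {
  stopifnot(P >= 1, d >= 1, d <= P, h >= d, length(sigma) %in% c(1L, P))
  if (!is.null(Upsilon)) {
    Upsilon <- as.matrix(Upsilon)
    stopifnot(nrow(Upsilon) == P, ncol(Upsilon) == d)
    # the all-zero matrix is allowed as the null testbed (no signal);
    # otherwise the directions must be linearly independent
    if (any(Upsilon != 0) && qr(Upsilon)$rank < d) {
      stop("`Upsilon` columns must be linearly independent")
    }
  }
  structure(list(P = P, d = d, Upsilon = Upsilon, h = h, sigma = sigma,
                 response = response),
            class = "pfc_testbed_spec")
}

#' Sample from the inverse-regression testbed
#'
#' @param spec a [pfc_testbed_spec()].
#' @param S sample size.
#' @param seed RNG seed.
#' @return A list with `phi` (tibble `S x P`), `y` (response vector) and
#'   `Upsilon` (the true direction matrix, for recovery tests).
#' @export
sample_pfc_testbed <- function(spec = pfc_testbed_spec(), S = 1000, seed = 1) {
  stopifnot(inherits(spec, "pfc_testbed_spec"))
  set.seed(seed)
  Ups <- spec$Upsilon
  if (is.null(Ups)) {
    Ups <- qr.Q(qr(matrix(stats::rnorm(spec$P * spec$d), spec$P)))
  }
  y <- spec$response(S)
  Fb <- sapply(seq_len(spec$h), function(j) y^j)
  Fb <- scale(Fb, scale = FALSE)
  # coefficients mapping the h basis columns onto the d structured directions
  coefs <- matrix(stats::rnorm(spec$d * spec$h), spec$d, spec$h)
  if (spec$h >= spec$d) coefs[, seq_len(spec$d)] <- diag(spec$d)
  mean_part <- Fb %*% t(coefs) %*% t(Ups)
  sig <- if (length(spec$sigma) == 1) rep(spec$sigma, spec$P) else spec$sigma
  eps <- matrix(stats::rnorm(S * spec$P), S) %*% diag(sig, spec$P)
  phi <- mean_part + eps
  colnames(phi) <- paste0("phi", seq_len(spec$P))
  list(phi = tibble::as_tibble(phi), y = y, Upsilon = Ups)
}

#' Principal angle between two subspaces
#'
#' Largest principal angle (degrees) between the column spans of `A` and
#' `B`, computed from the singular values of the product of their
#' orthonormal bases. 0 means identical spans; 90 means an orthogonal
#' direction exists.
#'
#' @param A,B matrices whose columns span the subspaces.
#' @return Angle in degrees.
#' @export
subspace_angle <- function(A, B) {
  Qa <- qr.Q(qr(as.matrix(A)))
  Qb <- qr.Q(qr(as.matrix(B)))
  sv <- svd(crossprod(Qa, Qb))$d
  acos(max(-1, min(1, min(sv)))) * 180 / pi
}
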