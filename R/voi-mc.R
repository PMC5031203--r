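#' Nested Monte Carlo EVPPI
#'
#' The general-purpose (and expensive) reference estimator. An outer sample
#' `phi_1, ..., phi_{S_phi}` is drawn from the marginal distribution of the
#' focal parameters; for each outer draw, `S_psi` nuisance vectors are drawn
#' from their conditional distribution given the focal values and the inner
#' conditional expectation of each treatment's net benefit is estimated by
#' the inner mean. The usual mean-of-maxima minus max-of-means combiner is
#' then applied to the matrix of inner means.
#'
#' Inner streams are derived deterministically from the outer index
#' (`(seed * 1000003 + s) mod (2^31 - 1)`), so the outer loop is
#' parallelizable without changing the result and repeat runs with the same
#' seed are bit-identical.
#'
#' @param model a simulatable decision model exposing marginal and
#'   conditional sampling (see [voi_model]).
#' @param focal focal parameter names.
#' @param S_phi,S_psi outer and inner sample counts (both >= 2).
#' @param k willingness-to-pay.
#' @param seed RNG seed.
#' @return A [voi_estimate] of kind `"EVPPI"`.
#' @export
evppi_nested_mc <- function(model, focal, S_phi = 1000, S_psi = 1000,
                            k = model$k, seed = 1) {
  stopifnot(S_phi >= 2, S_psi >= 2)
  set.seed(seed)
  phi <- sample_parameters(model, S_phi)[, focal, drop = FALSE]
  Tn <- length(model$treatments)
  ghat <- matrix(NA_real_, S_phi, Tn)
  for (s in seq_len(S_phi)) {
    set.seed((seed * 1000003 + s) %% (2^31 - 1))
    inner <- sample_nuisance_conditional(model, phi[s, , drop = FALSE],
                                         focal, S_psi)
    ghat[s, ] <- colMeans(as.matrix(net_benefit(model, inner, k)))
  }
  colnames(ghat) <- model$treatments
  evppi_from_fitted(ghat, method = "mc-nested", focal_names = focal,
                    k = k, S = S_phi, seed = seed,
                    diagnostics = list(S_psi = S_psi))
}

#' Single-loop EVPPI via analytic conditional expectations
#'
#' When the inner conditional expectation `E[NB_t | phi]` is available in
#' closed form — as it is for independent parameters with sum-product net
#' benefits, or for Gaussian parameters with (bi)linear net benefits — the
#' nested loop collapses: a single marginal sample of the focal parameters
#' is drawn, the closed form is evaluated at each draw, and the combiner is
#' applied. This estimator has no inner Monte Carlo error and serves as the
#' oracle against which the regression estimators are validated.
#'
#' With `focal` equal to all parameter names the conditional expectation is
#' the net benefit itself and the estimate coincides with the Monte Carlo
#' EVPI on the same draws; with an empty `focal` the estimate is exactly 0.
#'
#' @param model a decision model providing [conditional_expectation()].
#' @param focal focal parameter names (may be empty).
#' @param S_phi outer sample count.
#' @param k willingness-to-pay.
#' @param seed RNG seed.
#' @param chunk draws are generated and evaluated in chunks of this size to
#'   bound memory at large `S_phi`.
#' @return A [voi_estimate] of kind `"EVPPI"`.
#' @export
evppi_single_loop <- function(model, focal, S_phi = 1000, k = model$k,
                              seed = 1, chunk = 1e6) {
  stopifnot(S_phi >= 2)
  set.seed(seed)
  if (length(focal) == 0) {
    return(voi_estimate(0, kind = "EVPPI", method = "single-loop",
                        focal_names = character(), k = k, S = as.integer(S_phi),
                        seed = seed,
                        diagnostics = list(note = "empty focal set: conditional expectation is constant")))
  }
  Tn <- length(model$treatments)
  # streaming accumulation of the two combiner terms
  sum_max <- 0
  sum_cols <- numeric(Tn)
  done <- 0
  while (done < S_phi) {
    n <- min(chunk, S_phi - done)
    phi <- sample_parameters(model, n)[, focal, drop = FALSE]
    ghat <- as.matrix(conditional_expectation(model, phi, focal, k))
    sum_max <- sum_max + sum(do.call(pmax, as.data.frame(ghat)))
    sum_cols <- sum_cols + colSums(ghat)
    done <- done + n
  }
  value <- sum_max / S_phi - max(sum_cols / S_phi)
  voi_estimate(value, kind = "EVPPI", method = "single-loop",
               focal_names = focal, k = k, S = as.integer(S_phi), seed = seed)
}
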