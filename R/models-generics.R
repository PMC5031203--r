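#' Simulatable decision-model interface
#'
#' Synthetic decision models implement a small set of generics consumed by
#' the Monte Carlo estimators:
#'
#' * `sample_parameters(model, S)` — `S` draws from the joint parameter
#'   distribution, using the current RNG state.
#' * `sample_nuisance_conditional(model, phi_row, focal, S_psi)` — `S_psi`
#'   draws of the full parameter vector with the focal components held at
#'   `phi_row` and the nuisance components drawn from their conditional
#'   distribution given the focal values.
#' * `net_benefit(model, draws, k)` — per-treatment net benefits for a
#'   table of parameter draws.
#' * `conditional_expectation(model, phi_draws, focal, k)` — closed-form
#'   `E[NB_t | focal]`, where the model admits one (the analytic oracle
#'   behind the single-loop estimator).
#'
#' @param model a model object (e.g. from [influenza_spec()] or
#'   [gaussian_linear_spec()]).
#' @param S,S_psi numbers of draws.
#' @param phi_row single draw (named list / one-row data frame) of the focal
#'   parameters.
#' @param phi_draws data frame of focal parameter draws.
#' @param focal character vector of focal parameter names.
#' @param draws data frame of full parameter draws.
#' @param k willingness-to-pay.
#' @param ... passed to methods.
#' @name voi_model
NULL

#' @rdname voi_model
#' @export
sample_parameters <- function(model, S, ...) UseMethod("sample_parameters")

#' @rdname voi_model
#' @export
sample_nuisance_conditional <- function(model, phi_row, focal, S_psi, ...) {
  UseMethod("sample_nuisance_conditional")
}

#' @export
sample_nuisance_conditional.default <- function(model, phi_row, focal, S_psi, ...) {
  stop("this model does not expose conditional sampling of the nuisance parameters")
}

#' @rdname voi_model
#' @export
net_benefit <- function(model, draws, k, ...) UseMethod("net_benefit")

#' @rdname voi_model
#' @export
conditional_expectation <- function(model, phi_draws, focal, k, ...) {
  UseMethod("conditional_expectation")
}

#' @export
conditional_expectation.default <- function(model, phi_draws, focal, k, ...) {
  stop("this model does not provide a closed-form conditional expectation")
}
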