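#' Value-of-information estimate
#'
#' Light container for an EVPI or EVPPI value together with the metadata
#' needed to reproduce it. Theoretical values are non-negative; Monte Carlo
#' or regression estimates may come out slightly negative, in which case the
#' value is reported as computed and flagged in `diagnostics` rather than
#' silently clipped (truncation would hide estimator failure).
#'
#' @param value the estimate, on the money scale of the net benefits.
#' @param kind `"EVPI"` or `"EVPPI"`.
#' @param method label of the estimator that produced the value.
#' @param focal_names focal parameter names (empty for EVPI).
#' @param k willingness-to-pay.
#' @param S number of PSA draws used.
#' @param seed seed used, if any.
#' @param diagnostics named list of notes (convergence flags, residual
#'   summaries, warnings).
#' @return An object of class `voi_estimate`.
#' @export
voi_estimate <- function(value, kind = c("EVPI", "EVPPI"), method,
                         focal_names = character(), k = NA_real_, S = NA_integer_,
                         seed = NULL, diagnostics = list()) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(value), length(value) == 1, is.finite(value))
  if (value < 0) {
    diagnostics$negative_estimate <- sprintf(
      "estimate %.6g < 0: theoretical value is non-negative; treat as numerically zero only after checking the fit", value)
  }
  structure(
    list(value = value, kind = kind, method = method,
         focal_names = focal_names, k = k, S = S, seed = seed,
         diagnostics = diagnostics),
    class = "voi_estimate"
  )
}

#' @export
print.voi_estimate <- function(x, ...) {
  cat(sprintf("<voi_estimate> %s = %.6g  [method: %s, S = %s]\n",
              x$kind, x$value, x$method, format(x$S)))
  if (length(x$focal_names)) {
    cat("  focal:", paste(x$focal_names, collapse = ", "), "\n")
  }
  notes <- names(x$diagnostics)
  if (length(notes)) cat("  diagnostics:", paste(notes, collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.voi_estimate <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    method = x$method,
    estimate = x$value,
    focal = paste(x$focal_names, collapse = ","),
    n_focal = length(x$focal_names),
    k = x$k,
    S = x$S
  )
}

#' @export
glance.voi_estimate <- function(x, ...) {
  tibble::tibble(
    estimate = x$value,
    kind = x$kind,
    method = x$method,
    S = x$S,
    negative_flag = !is.null(x$diagnostics$negative_estimate)
  )
}

# mean-of-row-maxima minus max-of-column-means: the hat estimator shared by
# every route (MC on raw net benefits, regression on fitted values).
voi_combiner <- function(mat) {
  mean(do.call(pmax, as.data.frame(mat))) - max(colMeans(mat))
}

#' Monte Carlo EVPI from PSA samples
#'
#' The expected value of perfect information is the expected opportunity
#' loss of deciding under current uncertainty:
#' `EVPI = E[max_t NB_t] - max_t E[NB_t]`. Its Monte Carlo estimate replaces
#' both expectations by sample means over the `S` PSA draws — the mean of
#' the row maxima minus the maximum of the column means.
#'
#' @param x a [psa_dataset], or a data frame / matrix of net benefits
#'   (draws by treatments).
#' @param k willingness-to-pay recorded in the result (taken from the
#'   dataset when `x` is a [psa_dataset]).
#' @return A [voi_estimate] of kind `"EVPI"`.
#' @examples
#' evpi_mc(cbind(t0 = c(1, 0), t1 = c(0, 1)))  # 1 - 0.5 = 0.5
#' @export
evpi_mc <- function(x, k = NA_real_) {
  nb <- if (inherits(x, "psa_dataset")) {
    k <- x$k
    as.matrix(x$nb)
  } else {
    as.matrix(x)
  }
  stopifnot(nrow(nb) >= 2, ncol(nb) >= 2, all(is.finite(nb)))
  voi_estimate(voi_combiner(nb), kind = "EVPI", method = "mc",
               k = k, S = nrow(nb))
}

#' EVPPI from fitted conditional expectations
#'
#' Given fitted values `ghat[s, t]` approximating the conditional
#' expectation of each treatment's net benefit given the focal parameters,
#' the EVPPI estimate applies the same combiner as [evpi_mc()] to the fitted
#' table: `mean_s max_t ghat - max_t mean_s ghat`. Every regression route in
#' the package funnels through this function, and the baseline
#' (max-of-means) is always computed on the same fitted values for internal
#' consistency.
#'
#' @param ghat matrix or data frame of fitted conditional expectations,
#'   draws by treatments; all entries finite.
#' @param method estimator label stored in the result.
#' @param focal_names focal parameter names.
#' @param k,S,seed,diagnostics metadata; see [voi_estimate()].
#' @return A [voi_estimate] of kind `"EVPPI"`.
#' @export
evppi_from_fitted <- function(ghat, method = "fitted", focal_names = character(),
                              k = NA_real_, S = nrow(ghat), seed = NULL,
                              diagnostics = list()) {
  ghat <- as.matrix(ghat)
  stopifnot(nrow(ghat) >= 2, ncol(ghat) >= 2, all(is.finite(ghat)))
  voi_estimate(voi_combiner(ghat), kind = "EVPPI", method = method,
               focal_names = focal_names, k = k, S = S, seed = seed,
               diagnostics = diagnostics)
}
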