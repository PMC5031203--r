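#' Residual-structure check for a regression EVPPI fit
#'
#' Highly structured residuals mean the regression surface has not captured
#' every relevant relationship, and the EVPPI estimate should not be
#' trusted. Two statistics are computed per coordinate: the lag-1
#' autocorrelation of the residuals after sorting by that coordinate, and a
#' Wald-Wolfowitz runs test on the signs of the sorted residuals (normal
#' approximation). The check passes if every |autocorrelation| < 0.2 and
#' every runs-test p-value > 0.01 — declared defaults: checking is
#' mandatory, cutoff choice is convention.
#'
#' @param fit a `gp_fit` or `spde_fit` object (anything with `residuals`).
#' @param coordinates matrix of coordinates to order by (for an SPDE fit
#'   typically its projected coordinates; for a GP fit the focal columns).
#' @param max_autocorr,min_runs_p pass thresholds.
#' @return An object of class `residual_report`: a tibble with one row per
#'   coordinate plus an overall `pass` attribute.
#' @export
residual_check <- function(fit, coordinates, max_autocorr = 0.2,
                           min_runs_p = 0.01) {
  r <- fit$residuals
  stopifnot(!is.null(r))
  Z <- as.matrix(coordinates)
  stopifnot(nrow(Z) == length(r))
  rows <- purrr::map_dfr(seq_len(ncol(Z)), function(j) {
    ord <- order(Z[, j])
    rs <- r[ord]
    n <- length(rs)
    ac <- if (stats::sd(rs) == 0) 0 else
      stats::cor(rs[-n], rs[-1])
    s <- sign(rs - stats::median(rs))
    s <- s[s != 0]
    n1 <- sum(s > 0); n2 <- sum(s < 0)
    if (n1 == 0 || n2 == 0) {
      runs_p <- 1
    } else {
      runs <- 1 + sum(s[-1] != s[-length(s)])
      mu <- 1 + 2 * n1 * n2 / (n1 + n2)
      v <- 2 * n1 * n2 * (2 * n1 * n2 - n1 - n2) /
        ((n1 + n2)^2 * (n1 + n2 - 1))
      runs_p <- if (v <= 0) 1 else 2 * stats::pnorm(-abs((runs - mu) / sqrt(v)))
    }
    tibble::tibble(
      coordinate = colnames(Z)[j] %||% paste0("coord", j),
      lag1_autocorr = ac, runs_p = runs_p,
      pass = abs(ac) < max_autocorr & runs_p > min_runs_p
    )
  })
  structure(rows, class = c("residual_report", class(rows)),
            pass = all(rows$pass), residual_mean = mean(r))
}

#' @export
print.residual_report <- function(x, ...) {
  cat(sprintf("<residual_report> overall pass: %s (residual mean %.3g)\n",
              attr(x, "pass"), attr(x, "residual_mean")))
  NextMethod()
}

#' Monotonicity audit over nested focal sets
#'
#' The EVPPI is non-decreasing in the focal set: learning more parameters
#' perfectly can only add value. For a chain of strictly nested focal sets
#' the estimates from a correct method should therefore be non-decreasing
#' (up to estimation noise); a decrease is a necessary-condition failure
#' that points at estimator trouble, though monotone estimates are of
#' course not sufficient evidence of accuracy. Any decrease larger than
#' `tolerance_frac` times the final (largest-set) estimate is reported as a
#' violation.
#'
#' @param psa a [psa_dataset] (used by the regression methods; the MC
#'   methods resample from `model`).
#' @param nested_focal_sets list of character vectors, each a strict subset
#'   of the next.
#' @param method `"gp"`, `"spde"` or `"single-loop"`.
#' @param tolerance_frac allowed decrease as a fraction of the final
#'   estimate.
#' @param model decision model, required for `method = "single-loop"`.
#' @param S_phi single-loop sample size.
#' @param seed seed passed to the estimators.
#' @param .estimates optional precomputed estimates (one per set), bypassing
#'   the estimator calls — for auditing an externally produced sequence.
#' @param ... further arguments passed to the chosen estimator.
#' @return An object of class `monotonicity_report`: a tibble of estimates
#'   with a `violations` attribute.
#' @export
monotonicity_check <- function(psa, nested_focal_sets, method = c("gp", "spde", "single-loop"),
                               tolerance_frac = 0.02, model = NULL,
                               S_phi = 1e5, seed = 1, .estimates = NULL, ...) {
  method <- match.arg(method)
  sets <- nested_focal_sets
  if (length(sets) >= 2) {
    for (i in seq_len(length(sets) - 1)) {
      if (!all(sets[[i]] %in% sets[[i + 1]]) ||
          length(sets[[i]]) >= length(sets[[i + 1]])) {
        stop("focal sets must be strictly nested (set ", i,
             " is not a strict subset of set ", i + 1, ")")
      }
    }
  }
  est <- if (!is.null(.estimates)) .estimates else vapply(sets, function(f) {
    switch(method,
           "gp" = gp_evppi(psa, f, seed = seed, ...)$estimate$value,
           "spde" = spde_evppi(psa, f, ...)$estimate$value,
           "single-loop" = {
             if (is.null(model)) stop("`model` is required for the single-loop method")
             evppi_single_loop(model, f, S_phi = S_phi, k = psa$k,
                               seed = seed, ...)$value
           })
  }, 0)
  tab <- tibble::tibble(
    set = vapply(sets, paste, "", collapse = ","),
    size = lengths(sets),
    estimate = est
  )
  tol <- tolerance_frac * abs(est[length(est)])
  viol <- tibble::tibble(
    from = utils::head(tab$set, -1), to = utils::tail(tab$set, -1),
    decrease = pmax(utils::head(est, -1) - utils::tail(est, -1), 0)
  )
  viol <- viol[viol$decrease > tol, , drop = FALSE]
  structure(tab, class = c("monotonicity_report", class(tab)),
            violations = viol, tolerance = tol, method = method)
}

#' @export
print.monotonicity_report <- function(x, ...) {
  v <- attr(x, "violations")
  cat(sprintf("<monotonicity_report> method %s: %d violation(s) beyond tolerance %.4g\n",
              attr(x, "method"), nrow(v), attr(x, "tolerance")))
  NextMethod()
}
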