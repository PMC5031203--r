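#' Construct a PSA dataset
#'
#' Bundles `S` probabilistic-sensitivity-analysis (PSA) parameter draws with
#' the matching per-treatment net benefits at a given willingness-to-pay.
#' This is the universal input of every estimator in the package: draw `s`
#' of the parameters must have produced row `s` of the net-benefit table
#' (row alignment is positional; no draw identifiers are used).
#'
#' @param draws data frame of parameter draws, one named column per
#'   parameter, one row per PSA simulation. No missing values allowed.
#' @param nb data frame (or matrix) of net benefits, one column per
#'   treatment, same number of rows as `draws`.
#' @param k willingness-to-pay (money per effectiveness unit) at which the
#'   net benefits were computed.
#' @param treatments optional character vector of treatment labels; defaults
#'   to the column names of `nb`, or `t0, t1, ...`.
#' @param provenance free-text note (model name, seed) carried along for
#'   reporting.
#'
#' @return An object of class `psa_dataset`: a list with tibbles `draws`
#'   and `nb`, the scalar `k`, `treatments` and `provenance`.
#' @examples
#' draws <- data.frame(pi = c(0.1, 0.2), lambda = c(6, 9))
#' nb <- data.frame(t0 = c(-1, -2), t1 = c(0, -1))
#' psa_dataset(draws, nb, k = 20000)
#' @export
psa_dataset <- function(draws, nb, k, treatments = NULL, provenance = "") {
  draws <- tibble::as_tibble(as.data.frame(draws))
  nb <- tibble::as_tibble(as.data.frame(nb))
  if (nrow(draws) != nrow(nb)) {
    stop("`draws` and `nb` must have the same number of rows (draw/net-benefit alignment is positional)")
  }
  if (nrow(draws) < 2) stop("a PSA dataset needs at least S = 2 draws")
  if (anyDuplicated(names(draws))) stop("parameter names must be unique")
  if (ncol(nb) < 2) stop("at least two treatments are required")
  if (!all(vapply(draws, is.numeric, TRUE)) || !all(vapply(nb, is.numeric, TRUE))) {
    stop("all parameter and net-benefit columns must be numeric")
  }
  if (anyNA(draws) || any(!vapply(draws, function(x) all(is.finite(x)), TRUE))) {
    stop("parameter draws contain missing or non-finite values")
  }
  if (anyNA(nb) || any(!vapply(nb, function(x) all(is.finite(x)), TRUE))) {
    stop("net benefits contain missing or non-finite values")
  }
  if (!is.numeric(k) || length(k) != 1 || k < 0) stop("`k` must be a single non-negative number")
  if (is.null(treatments)) {
    treatments <- if (!is.null(colnames(nb)) && !any(colnames(nb) == "")) {
      sub("^nb_", "", colnames(nb))
    } else {
      paste0("t", seq_len(ncol(nb)) - 1L)
    }
  }
  if (length(treatments) != ncol(nb)) stop("`treatments` must have one label per net-benefit column")
  names(nb) <- treatments
  structure(
    list(draws = draws, nb = nb, k = k, treatments = treatments,
         provenance = provenance),
    class = "psa_dataset"
  )
}

#' @export
print.psa_dataset <- function(x, ...) {
  cat(sprintf("<psa_dataset> S = %d draws, P = %d parameters, T = %d treatments, k = %g\n",
              nrow(x$draws), ncol(x$draws), ncol(x$nb), x$k))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  cat("  parameters:", paste(names(x$draws), collapse = ", "), "\n")
  cat("  treatments:", paste(x$treatments, collapse = ", "), "\n")
  invisible(x)
}

#' Net benefits from effectiveness and cost
#'
#' The monetary net benefit of treatment `t` at willingness-to-pay `k` is
#' `NB_t = k * e_t - c_t`, placing effectiveness and cost on a common money
#' scale. Applied entrywise to per-draw, per-treatment tables.
#'
#' @param effects data frame or matrix of effectiveness, draws by treatments.
#' @param costs data frame or matrix of costs, same shape as `effects`.
#' @param k willingness-to-pay (money per effectiveness unit), `k >= 0`.
#' @return A tibble of net benefits with the treatment columns of `effects`.
#' @examples
#' compute_net_benefits(data.frame(t0 = 1), data.frame(t0 = 0), k = 20000)
#' @export
compute_net_benefits <- function(effects, costs, k) {
  e <- as.matrix(effects)
  c_ <- as.matrix(costs)
  if (!identical(dim(e), dim(c_))) stop("`effects` and `costs` must have the same shape")
  if (anyNA(e) || anyNA(c_) || !all(is.finite(e)) || !all(is.finite(c_))) {
    stop("`effects`/`costs` contain missing or non-finite values")
  }
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k < 0) {
    stop("`k` must be a single non-negative number")
  }
  nb <- k * e - c_
  colnames(nb) <- colnames(e)
  tibble::as_tibble(nb, .name_repair = "minimal")
}

#' Read a PSA dataset from CSV
#'
#' The CSV dialect is comma-separated, `.` decimal, UTF-8, with a mandatory
#' header. Net-benefit columns are recognised by the prefix `nb_`;
#' alternatively matched `e_<label>` / `c_<label>` pairs may be supplied
#' together with a willingness-to-pay `k`, in which case net benefits are
#' computed as `k * e - c`. All remaining columns are parameter draws.
#'
#' @param path path to a CSV file.
#' @param k willingness-to-pay; required when the file holds `e_*`/`c_*`
#'   columns, optional (metadata only, default 0) when it holds `nb_*`.
#' @return A [psa_dataset].
#' @export
read_psa <- function(path, k = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  nms <- names(df)
  nb_cols <- grep("^nb_", nms, value = TRUE)
  e_cols <- grep("^e_", nms, value = TRUE)
  c_cols <- grep("^c_", nms, value = TRUE)
  if (!all(vapply(df, is.numeric, TRUE))) stop("non-numeric cells in ", path)
  if (anyNA(df)) stop("missing values in ", path)
  if (length(nb_cols) >= 2) {
    nb <- df[nb_cols]
    names(nb) <- sub("^nb_", "", nb_cols)
    par_cols <- setdiff(nms, nb_cols)
    if (is.null(k)) k <- 0
  } else if (length(e_cols) >= 2) {
    labels <- sub("^e_", "", e_cols)
    need_c <- paste0("c_", labels)
    if (!all(need_c %in% c_cols)) {
      stop("effect columns ", paste(e_cols, collapse = ", "),
           " lack matching cost columns")
    }
    if (is.null(k)) stop("`k` is required to combine e_*/c_* columns into net benefits")
    nb <- compute_net_benefits(stats::setNames(df[e_cols], labels),
                               stats::setNames(df[need_c], labels), k)
    par_cols <- setdiff(nms, c(e_cols, need_c))
  } else {
    stop("no nb_* columns and no e_*/c_* pairs found in ", path)
  }
  if (length(par_cols) == 0) stop("no parameter columns found in ", path)
  psa_dataset(df[par_cols], nb, k = k, provenance = paste0("read_psa:", basename(path)))
}

#' Write a PSA dataset to CSV
#'
#' Inverse of [read_psa()]: parameter columns keep their names, net-benefit
#' columns are written as `nb_<treatment>`. Values round-trip bit-exactly at
#' full printed precision.
#'
#' @param x a [psa_dataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_psa <- function(x, path) {
  stopifnot(inherits(x, "psa_dataset"))
  nb <- x$nb
  names(nb) <- paste0("nb_", names(nb))
  readr::write_csv(dplyr::bind_cols(x$draws, nb), path, progress = FALSE)
  invisible(path)
}

#' Select (and standardize) focal parameter columns
#'
#' Returns the focal subset of the parameter draws, in the requested order.
#' With `standardize = TRUE` each column is centred to mean 0 and scaled to
#' unit sample standard deviation (divisor `S - 1`) — the rescaling
#' recommended before any regression or projection step, since mesh and
#' kernel computations behave best when all coordinates share a scale.
#' Constant columns cannot be scaled and are mapped to all zeros with a
#' warning (near-constant nuisance parameters do occur in real PSA output).
#'
#' @param x a [psa_dataset] or a data frame of parameter draws.
#' @param focal character vector of focal parameter names (subset of the
#'   parameter columns).
#' @param standardize center/scale each selected column?
#' @return A tibble with the focal columns.
#' @export
select_parameters <- function(x, focal, standardize = FALSE) {
  draws <- if (inherits(x, "psa_dataset")) x$draws else tibble::as_tibble(x)
  if (length(focal) == 0) stop("empty focal selection")
  unknown <- setdiff(focal, names(draws))
  if (length(unknown)) stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
  out <- draws[focal]
  if (standardize) {
    out <- purrr::map_dfc(out, function(col) {
      s <- stats::sd(col)
      if (!is.finite(s) || s == 0) {
        warning("constant parameter column standardized to all zeros")
        rep(0, length(col))
      } else {
        (col - mean(col)) / s
      }
    })
    names(out) <- focal
  }
  out
}
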