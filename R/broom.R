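#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy the coefficients of a sparse factor fit
#'
#' @param x An `sfa_fit`.
#' @param ... Unused.
#' @return Tibble with one row per (factor, feature): `factor`, `feature`,
#'   `datatype`, `estimate` (the sparse coefficient).
#' @method tidy sfa_fit
#' @export
tidy.sfa_fit <- function(x, ...) {
  B <- x$model$B
  tibble::tibble(
    factor = rep(rownames(B), times = ncol(B)),
    feature = rep(colnames(B), each = nrow(B)),
    datatype = rep(as.character(x$model$datatype_of_feature), each = nrow(B)),
    estimate = as.vector(B)
  )
}

#' One-row summary of a sparse factor fit
#'
#' @param x An `sfa_fit`.
#' @param ... Unused.
#' @return Tibble: `k`, `n_samples`, `n_features`, `nonzero`, `iterations`,
#'   `converged`, `recon_error`, `objective`.
#' @method glance sfa_fit
#' @export
glance.sfa_fit <- function(x, ...) {
  tibble::tibble(
    k = x$model$k,
    n_samples = nrow(x$posterior$mean),
    n_features = ncol(x$model$B),
    nonzero = sum(x$model$B != 0),
    iterations = x$iterations,
    converged = x$converged,
    recon_error = utils::tail(x$trace$recon_error, 1L),
    objective = utils::tail(x$trace$objective, 1L)
  )
}

#' Attach factor scores to a sample table
#'
#' @param x An `sfa_fit`.
#' @param data Optional data frame with a `sample_id` column to join onto;
#'   defaults to just the scores.
#' @param ... Unused.
#' @return Tibble of samples with one `.factor_*` column per factor.
#' @method augment sfa_fit
#' @export
augment.sfa_fit <- function(x, data = NULL, ...) {
  sc <- factor_scores(x)
  names(sc)[-1L] <- paste0(".", names(sc)[-1L])
  if (is.null(data)) return(sc)
  dplyr::left_join(tibble::as_tibble(data), sc, by = "sample_id")
}
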