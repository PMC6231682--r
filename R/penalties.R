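#' Elastic-net penalty configuration
#'
#' The per-feature L1/L2 penalties are reparameterized through a single
#' nonnegative level `l` per data type and a mixing parameter `alpha` shared
#' by all data types:
#' \deqn{\lambda_{1} = \alpha\, l,\qquad \lambda_{2} = 10^{-6} + (1-\alpha)\, l.}
#' All features of one data type share the same penalty pair. `alpha = 0.9`
#' (mostly lasso, a little ridge) is the conventional default.
#'
#' @param alpha Mixing parameter in (0, 1].
#' @param levels Named nonnegative numeric vector, one level per data type.
#' @return A `penalty_config` object.
#' @examples
#' penalty_config(0.9, c(mrna = 1, cn = 0.5))
#' @export
penalty_config <- function(alpha = 0.9, levels) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(names(levels)) || any(!nzchar(names(levels)))) {
    stop("`levels` must be named by data type", call. = FALSE)
  }
  if (any(levels < 0)) stop("penalty levels must be nonnegative", call. = FALSE)
  structure(list(alpha = alpha, levels = levels), class = "penalty_config")
}

#' @export
print.penalty_config <- function(x, ...) {
  cat(sprintf("<penalty_config> alpha = %g; levels: %s\n", x$alpha,
              paste(sprintf("%s = %g", names(x$levels), x$levels), collapse = ", ")))
  invisible(x)
}

#' Per-feature penalty pairs implied by a configuration
#'
#' @param config A [penalty_config()].
#' @param datatype_of_feature Factor (or character) giving each stacked
#'   feature's data type; every level must have a configured level.
#' @return A tibble with columns `feature_index`, `datatype`, `lambda1`,
#'   `lambda2`.
#' @export
expand_penalties <- function(config, datatype_of_feature) {
  stopifnot(inherits(config, "penalty_config"))
  dt <- as.character(datatype_of_feature)
  missing <- setdiff(unique(dt), names(config$levels))
  if (length(missing) > 0L) {
    stop("no penalty level for data type(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  l <- unname(config$levels[dt])
  tibble::tibble(
    feature_index = seq_along(dt),
    datatype = dt,
    lambda1 = config$alpha * l,
    lambda2 = 1e-6 + (1 - config$alpha) * l
  )
}
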