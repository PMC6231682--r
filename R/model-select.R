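#' Effective degrees of freedom of the penalized coefficients
#'
#' Tibshirani-Taylor style estimate for the elastic net, evaluated with the
#' rescaled posterior factor matrix as the design. Once the posterior moments
#' are fixed, the multi-response penalized regression decouples across
#' factors, so factor `i` contributes, for each feature `j` in its active set
#' (nonzero coefficient), the ridge-shrunk hat-trace
#' `t_i / (t_i + 2 lambda2_j)` with `t_i = z_i' z_i`; the L2 penalty is taken
#' per data type. In the `lambda2 -> 0` limit this is the lasso df (the
#' active-set size); for `lambda2 -> Inf` it vanishes.
#'
#' @param fit An `sfa_fit`.
#' @return A single nonnegative df value.
#' @export
effective_df <- function(fit) {
  stopifnot(inherits(fit, "sfa_fit"))
  B <- fit$model$B
  Z <- fit$posterior$mean
  pen <- expand_penalties(fit$model$penalties, fit$model$datatype_of_feature)
  t_i <- colSums(Z^2)
  df <- 0
  for (i in seq_len(nrow(B))) {
    active <- which(B[i, ] != 0)
    if (length(active) > 0L) {
      df <- df + sum(t_i[i] / (t_i[i] + 2 * pen$lambda2[active]))
    }
  }
  df
}

#' Observed-data (marginal) log-likelihood of a fitted model
#'
#' Integrating the factors out of the model gives
#' `x ~ N(0, B'B + Psi)` per sample; this evaluates that Gaussian
#' log-likelihood over all samples via the Woodbury identity and the matrix
#' determinant lemma, so only a `k x k` system is solved.
#'
#' @param dataset The `multiomics_dataset` (or stacked matrix).
#' @param model An `sfa_model`.
#' @return A scalar log-likelihood.
#' @export
marginal_loglik <- function(dataset, model) {
  X <- if (is.matrix(dataset)) dataset else dataset_matrix(dataset)
  psi_vec <- psi_vector(model$psi, model$datatype_of_feature)
  B <- model$B
  N <- nrow(X); n <- ncol(X); k <- model$k
  BtW <- t(B) / psi_vec
  Vinv <- diag(k) + B %*% BtW
  V <- chol2inv(chol(Vinv))
  G <- X %*% BtW
  tr_term <- sum(X^2 %*% (1 / psi_vec)) - sum(G * (G %*% V))
  logdet <- sum(log(psi_vec)) +
    as.numeric(determinant(Vinv, logarithm = TRUE)$modulus)
  -0.5 * (N * n * log(2 * pi) + N * logdet + tr_term)
}

#' Bayesian information criterion of a fitted model
#'
#' `BIC = -2 * loglik + df * log(N)` with [effective_df()] as the parameter
#' count; smaller is better, and [sfa_grid_search()] minimizes it so the
#' selected model is the parsimony/fit optimum.
#'
#' By default the log-likelihood is the observed-data (marginal) likelihood
#' of the factor model ([marginal_loglik()]) — the likelihood BIC is defined
#' on. The complete-data log-likelihood with the posterior factors plugged in
#' is available via `likelihood = "complete"`, but it rewards extra
#' coefficients at a rate that can exceed `log(N)` (every added coefficient
#' also shrinks the block's residual variance), which drives selection toward
#' the densest candidate; see the methods vignette.
#'
#' @param fit An `sfa_fit`.
#' @param dataset The `multiomics_dataset` the model was fitted to.
#' @param likelihood `"marginal"` (default) or `"complete"`.
#' @return A scalar BIC value (smaller is better).
#' @export
bic_score <- function(fit, dataset, likelihood = c("marginal", "complete")) {
  likelihood <- match.arg(likelihood)
  ll <- switch(likelihood,
    marginal = marginal_loglik(dataset, fit$model),
    complete = penalized_loglik(dataset, fit$model, fit$posterior,
                                penalized = FALSE)
  )
  N <- nrow(fit$posterior$mean)
  -2 * ll + effective_df(fit) * log(N)
}

#' BIC-driven grid search over per-data-type penalty levels
#'
#' Fits every point of the Cartesian product of the per-type level lists and
#' returns the BIC-optimal fit plus the full score table. Exact BIC ties are
#' broken toward the larger total penalty (the sparser model). Adjacent grid
#' points are warm-started from the previous fit by default to cut runtime;
#' a grid point whose fit fails (e.g. a penalty so large that a factor
#' vanishes entirely) is scored `NA`, excluded from selection, and reported
#' with a warning.
#'
#' @param dataset A centered, scaled `multiomics_dataset`.
#' @param k Number of factors.
#' @param alpha Elastic-net mixing parameter (default 0.9).
#' @param grid Named list, one nonnegative numeric vector of levels per data
#'   type (defaults to 6 log-spaced levels over `[0.01, 1]` for every type).
#' @param seed Optional seed passed to each fit.
#' @param warm_start Warm-start consecutive grid points (default `TRUE`).
#' @param ... Passed to [fit_sfa()] (`max_iter`, `tol`).
#' @return A list of class `sfa_grid`: `best` (the selected `sfa_fit`),
#'   `scores` (tibble: one row per grid point with levels, `df`, `loglik`,
#'   `bic`, `nonzero`, `optimal`), `grid`.
#' @export
sfa_grid_search <- function(dataset, k, alpha = 0.9, grid = NULL, seed = NULL,
                            warm_start = TRUE, ...) {
  types <- names(dataset$blocks)
  if (is.null(grid)) {
    grid <- stats::setNames(rep(list(exp(seq(log(0.01), log(1), length.out = 6))),
                                length(types)), types)
  }
  stopifnot(all(names(grid) %in% types), length(grid) == length(types))
  grid <- grid[types]
  if (any(lengths(grid) == 0L)) stop("empty penalty grid", call. = FALSE)
  points <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  fits <- vector("list", nrow(points))
  rows <- vector("list", nrow(points))
  prev <- NULL
  for (p in seq_len(nrow(points))) {
    levels_p <- stats::setNames(as.numeric(points[p, ]), types)
    pc <- penalty_config(alpha, levels_p)
    fit <- tryCatch(
      fit_sfa(dataset, k, pc, seed = seed,
              init = if (warm_start) prev else NULL, ...),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      warning(sprintf("grid point (%s) failed: %s",
                      paste(sprintf("%s=%g", types, levels_p), collapse = ", "),
                      conditionMessage(fit)), call. = FALSE)
      rows[[p]] <- tibble::tibble(!!!as.list(levels_p), df = NA_real_,
                                  loglik = NA_real_, bic = NA_real_,
                                  nonzero = NA_integer_)
      next
    }
    fits[[p]] <- fit
    if (warm_start) prev <- fit$model
    rows[[p]] <- tibble::tibble(
      !!!as.list(levels_p),
      df = effective_df(fit),
      loglik = marginal_loglik(dataset, fit$model),
      bic = bic_score(fit, dataset),
      nonzero = sum(fit$model$B != 0)
    )
  }
  scores <- dplyr::bind_rows(rows)
  total_level <- rowSums(as.matrix(scores[, types, drop = FALSE]))
  ok <- which(!is.na(scores$bic))
  if (length(ok) == 0L) stop("all grid points failed", call. = FALSE)
  # minimize BIC; exact ties -> larger total penalty (sparser model)
  best_idx <- ok[order(scores$bic[ok], -total_level[ok])][1L]
  scores$optimal <- seq_len(nrow(scores)) == best_idx
  structure(list(best = fits[[best_idx]], scores = scores, grid = grid),
            class = "sfa_grid")
}

#' @export
print.sfa_grid <- function(x, ...) {
  cat(sprintf("<sfa_grid> %d grid points; selected: row %d (BIC = %.4g)\n",
              nrow(x$scores), which(x$scores$optimal),
              x$scores$bic[x$scores$optimal]))
  invisible(x)
}
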