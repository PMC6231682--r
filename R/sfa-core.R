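#' Sparse factor analysis: model and EM algorithm
#'
#' The model explains each sample vector `x` (all data types stacked, `n`
#' features) by `k` latent factors `z`:
#' \deqn{x = B^T z + e,\quad z \sim N(0, I_k),\quad e \sim N(0, \Psi)}
#' with `Psi` diagonal and equal for all features of one data type. Stacked
#' over `N` samples this factorizes the `N x n` data matrix `X` as `Z B`.
#' Coefficients are made sparse by an elastic-net penalty with one L1/L2 pair
#' per data type (see [penalty_config()]).
#'
#' The fitting algorithm alternates: (1) the exact Gaussian posterior of the
#' factors, rescaled to unit variance per factor (the rescaling stops the
#' penalty from shrinking coefficients while the factors inflate to
#' compensate); (2) one sequential coordinate-descent sweep of the penalized
#' coefficient updates with soft-thresholding; (3) a per-data-type residual
#' variance update. Convergence is declared when the mean absolute change in
#' reconstruction error over the last 10 iterations falls below `tol`.
#'
#' @name sfa_model
NULL

# per-feature residual variance vector from per-type psi
psi_vector <- function(psi, datatype_of_feature) {
  unname(psi[as.character(datatype_of_feature)])
}

#' Initialize coefficients and residual variances from PCA
#'
#' `B` is set from the top-`k` principal axes of the stacked matrix, with each
#' row scaled so the implied factor scores have unit sample variance
#' (`B[j, ] = d_j v_j / sqrt(N - 1)` from the SVD `X = U D V'`). Component
#' signs follow the convention that the largest-magnitude loading is positive.
#' Residual variance per data type is the mean squared entry of the rank-`k`
#' reconstruction residual in that block, floored at 1e-8.
#'
#' @param dataset A `multiomics_dataset` (features centered; see
#'   [scale_by_datatype_sd()]).
#' @param k Number of factors, `1 <= k <= min(N, n)`.
#' @param penalties A [penalty_config()] carried along on the model.
#' @return A list of class `sfa_model` with `B` (k x n), `psi` (named per
#'   data type), `k`, `penalties`, `datatype_of_feature`.
#' @export
init_pca <- function(dataset, k, penalties = NULL) {
  X <- dataset_matrix(dataset)
  N <- nrow(X); n <- ncol(X)
  if (k < 1 || k > min(N, n)) stop("`k` must be in 1..min(N, n)", call. = FALSE)
  if (all(X == 0)) stop("degenerate all-zero data", call. = FALSE)
  sv <- svd(X, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  V <- sv$v
  U <- sv$u
  for (j in seq_len(k)) {
    s <- sign(V[which.max(abs(V[, j])), j])
    if (s < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  B <- t(V) * (d / sqrt(N - 1))
  colnames(B) <- colnames(X)
  rownames(B) <- paste0("factor_", seq_len(k))
  resid <- X - U %*% (d * t(V))
  dt <- dataset$datatype_of_feature
  psi <- vapply(levels(dt), function(lv) {
    max(mean(resid[, dt == lv, drop = FALSE]^2), 1e-8)
  }, numeric(1))
  structure(
    list(B = B, psi = psi, k = k,
         penalties = penalties,
         datatype_of_feature = dt),
    class = "sfa_model"
  )
}

#' @export
print.sfa_model <- function(x, ...) {
  cat(sprintf("<sfa_model> k = %d, %d features; psi: %s\n", x$k, ncol(x$B),
              paste(sprintf("%s = %.4g", names(x$psi), x$psi), collapse = ", ")))
  invisible(x)
}

#' Posterior factor moments, rescaled to unit variance
#'
#' Computes the Gaussian identities
#' `V = (I_k + B Psi^-1 B')^-1`, `E[Z|X] = X Psi^-1 B' V`,
#' `E[Z'Z|X] = N V + E[Z|X]' E[Z|X]`, then divides each factor column of
#' `E[Z|X]` by its sample standard deviation `d_j` and conjugates the second
#' moment by `diag(1/d)` so both moments describe the rescaled factors.
#'
#' @param dataset A `multiomics_dataset` or numeric matrix `X`.
#' @param model An `sfa_model`.
#' @param rescale Apply the unit-variance rescaling (default `TRUE`). The
#'   printed coordinate update is only valid under rescaling.
#' @return A `posterior_factors` list: `mean` (N x k), `second_moment`
#'   (k x k), `scale_applied` (the divisors `d`), plus the raw moments
#'   (`mean_raw`, `second_moment_raw`).
#' @export
e_step <- function(dataset, model, rescale = TRUE) {
  X <- if (is.matrix(dataset)) dataset else dataset_matrix(dataset)
  B <- model$B
  N <- nrow(X); k <- model$k
  psi_vec <- psi_vector(model$psi, model$datatype_of_feature)
  if (any(psi_vec <= 0)) stop("residual variances must be positive", call. = FALSE)
  BtW <- t(B) / psi_vec                       # n x k, Psi^-1 B'
  Vinv <- diag(k) + B %*% BtW
  ch <- tryCatch(chol(Vinv), error = function(e) NULL)
  if (is.null(ch)) stop("singular posterior precision (I + B Psi^-1 B')", call. = FALSE)
  V <- chol2inv(ch)
  EZ <- X %*% BtW %*% V
  M <- N * V + crossprod(EZ)
  out <- list(mean_raw = EZ, second_moment_raw = M)
  if (rescale) {
    d <- apply(EZ, 2L, stats::sd)
    if (any(d <= 0 | !is.finite(d))) {
      stop("zero-variance factor column; cannot rescale to unit variance",
           call. = FALSE)
    }
    out$mean <- sweep(EZ, 2L, d, "/")
    out$second_moment <- M / outer(d, d)
    out$scale_applied <- d
  } else {
    out$mean <- EZ
    out$second_moment <- M
    out$scale_applied <- rep(1, k)
  }
  rownames(out$mean) <- rownames(X)
  colnames(out$mean) <- rownames(B)
  structure(out, class = "posterior_factors")
}

#' @export
print.posterior_factors <- function(x, ...) {
  cat(sprintf("<posterior_factors> %d samples x %d factors\n",
              nrow(x$mean), ncol(x$mean)))
  invisible(x)
}

#' Soft-thresholding operator
#'
#' `S(b, l1) = sign(b) * max(|b| - l1, 0)`, vectorized in `b`.
#'
#' @param b Numeric vector.
#' @param l1 Nonnegative threshold.
#' @return Numeric vector of the same length.
#' @examples
#' soft_threshold(c(2, -0.3), 0.5)
#' @export
soft_threshold <- function(b, l1) {
  stopifnot(all(l1 >= 0))
  sign(b) * pmax(abs(b) - l1, 0)
}

#' Single elastic-net coordinate update
#'
#' The update for coefficient `(i, j)` given fixed posterior moments:
#' \deqn{B[i,j] \leftarrow
#'   S\!\left(B[i,j] + \tfrac1N\left(E[Z|X]_{\cdot i}^T X_{\cdot j}
#'   - B_{\cdot j}^T E[Z^TZ|X]_{\cdot i}\right),\ \lambda_{j,1}\right)
#'   / (1 + \lambda_{j,2}).}
#' The bare `1/(1 + lambda2)` denominator presumes the rescaled second moment
#' satisfies `E[Z'Z|X]/N ~ I`; rescaling in [e_step()] is therefore mandatory.
#'
#' @param B Current coefficient matrix (k x n).
#' @param i,j Factor and feature index.
#' @param C Cross-product `E[Z|X]' X` (k x n).
#' @param M Rescaled second moment `E[Z'Z|X]` (k x k).
#' @param lambda1,lambda2 Penalties for feature `j`.
#' @param N Sample count.
#' @return The updated scalar coefficient.
#' @export
update_coefficient <- function(B, i, j, C, M, lambda1, lambda2, N) {
  u <- B[i, j] + (C[i, j] - sum(B[, j] * M[, i])) / N
  soft_threshold(u, lambda1) / (1 + lambda2)
}

#' One full coordinate-descent sweep over all coefficients
#'
#' Updates every coefficient exactly once in factor-major, then feature order,
#' each update seeing the latest values of the others. Within one factor row
#' the updates are mutually independent (an update touches only its own
#' feature's column of `B`), so the row is computed vectorized with results
#' identical to the sequential order.
#'
#' @inheritParams update_coefficient
#' @param lambda1,lambda2 Per-feature penalty vectors (length n).
#' @return The updated coefficient matrix.
#' @export
coordinate_descent_pass <- function(B, C, M, lambda1, lambda2, N) {
  k <- nrow(B)
  for (i in seq_len(k)) {
    u <- B[i, ] + (C[i, ] - drop(M[, i] %*% B)) / N
    B[i, ] <- soft_threshold(u, lambda1) / (1 + lambda2)
  }
  B
}

#' Per-data-type residual variance update
#'
#' For data type `i`:
#' `psi_i = (trace(X_i X_i') - trace(E[Z|X] B_i X_i')) / (n_i N)`, floored at
#' 1e-8 so degenerate (noiseless) blocks stay positive.
#'
#' @param dataset A `multiomics_dataset` or stacked matrix.
#' @param model An `sfa_model` (its `B` is used).
#' @param posterior A `posterior_factors` (rescaled mean is used).
#' @param datatype_of_feature Required when `dataset` is a bare matrix.
#' @return Named numeric vector of per-type variances.
#' @export
update_residual_variance <- function(dataset, model, posterior,
                                     datatype_of_feature = NULL) {
  X <- if (is.matrix(dataset)) dataset else dataset_matrix(dataset)
  dt <- if (is.matrix(dataset)) datatype_of_feature else dataset$datatype_of_feature
  EZ <- posterior$mean
  N <- nrow(X)
  vapply(levels(dt), function(lv) {
    cols <- which(dt == lv)
    Xi <- X[, cols, drop = FALSE]
    Bi <- model$B[, cols, drop = FALSE]
    est <- (sum(Xi^2) - sum((EZ %*% Bi) * Xi)) / (length(cols) * N)
    max(est, 1e-8)
  }, numeric(1))
}

#' Mean squared reconstruction error
#'
#' `||X - E[Z|X] B||_F^2 / (N n)`; the quantity whose trailing mean absolute
#' change drives the convergence rule. Normalizing by `N n` makes `tol`
#' scale-comparable across datasets.
#'
#' @inheritParams update_residual_variance
#' @return A nonnegative scalar.
#' @export
reconstruction_error <- function(dataset, model, posterior) {
  X <- if (is.matrix(dataset)) dataset else dataset_matrix(dataset)
  mean((X - posterior$mean %*% model$B)^2)
}

#' Complete-data log-likelihood, optionally penalized
#'
#' \deqn{\ell = -\tfrac12\,\mathrm{tr}\!\left((X - ZB)\Psi^{-1}(X - ZB)^T\right)
#'   - \tfrac{N}{2}\log\det\Psi - \tfrac12\,\mathrm{tr}(Z^T Z)}
#' with `Z` the rescaled posterior mean, minus (when `penalized = TRUE`)
#' `sum_j lambda1_j |b_j|_1 + sum_j lambda2_j |b_j|_2^2` over feature columns
#' `b_j` of `B`. The `N/2` normalization of the log-determinant term is the
#' Gaussian likelihood of `N` i.i.d. samples.
#'
#' @inheritParams update_residual_variance
#' @param penalized Subtract the elastic-net penalty (default `TRUE`).
#' @return A scalar log-likelihood.
#' @export
penalized_loglik <- function(dataset, model, posterior, penalized = TRUE) {
  X <- if (is.matrix(dataset)) dataset else dataset_matrix(dataset)
  dt <- model$datatype_of_feature
  psi_vec <- psi_vector(model$psi, dt)
  if (any(psi_vec <= 0)) stop("residual variances must be positive", call. = FALSE)
  Z <- posterior$mean
  R <- X - Z %*% model$B
  N <- nrow(X)
  ll <- -0.5 * sum(sweep(R^2, 2L, psi_vec, "/")) -
    (N / 2) * sum(log(psi_vec)) -
    0.5 * sum(Z^2)
  if (penalized && !is.null(model$penalties)) {
    pen <- expand_penalties(model$penalties, dt)
    ll <- ll - sum(pen$lambda1 * colSums(abs(model$B))) -
      sum(pen$lambda2 * colSums(model$B^2))
  }
  ll
}

#' Fit the sparse factor analysis by penalized EM
#'
#' Runs [init_pca()] (unless a warm start is supplied), then alternates
#' [e_step()], one [coordinate_descent_pass()], and
#' [update_residual_variance()] until the mean absolute change in
#' [reconstruction_error()] over the last 10 iterations drops below `tol`,
#' or `max_iter` iterations.
#'
#' @param dataset A `multiomics_dataset`, centered and scaled
#'   (see [scale_by_datatype_sd()]).
#' @param k Number of factors.
#' @param penalties A [penalty_config()] covering the dataset's data types.
#' @param max_iter Iteration cap (default 5000).
#' @param tol Convergence tolerance on the trailing mean absolute change in
#'   reconstruction error (default 1e-6).
#' @param seed Optional integer seed (the fit itself is deterministic; the
#'   seed is set for any downstream randomness and recorded).
#' @param init Optional `sfa_model` to warm-start from instead of PCA.
#' @return An object of class `sfa_fit`: `model` (`sfa_model`), `posterior`
#'   (`posterior_factors`, consistent with the final model), `trace`
#'   (tibble: iteration, recon_error, objective), `converged`, `iterations`.
#' @examples
#' spec <- synthetic_spec(N = 60, k = 2, n_features = c(mrna = 30, cn = 10),
#'                        seed = 1)
#' sim <- generate_multiomics(spec)
#' fit <- fit_sfa(sim$dataset, k = 2,
#'                penalties = penalty_config(0.9, c(mrna = 0.05, cn = 0.05)))
#' glance(fit)
#' @export
fit_sfa <- function(dataset, k, penalties, max_iter = 5000, tol = 1e-6,
                    seed = NULL, init = NULL) {
  stopifnot(inherits(dataset, "multiomics_dataset"),
            inherits(penalties, "penalty_config"))
  if (!is.null(seed)) set.seed(seed)
  X <- dataset_matrix(dataset)
  dt <- dataset$datatype_of_feature
  N <- nrow(X)
  pen <- expand_penalties(penalties, dt)

  model <- if (is.null(init)) init_pca(dataset, k, penalties) else init
  model$penalties <- penalties
  if (model$k != k) stop("warm start has wrong factor count", call. = FALSE)

  errs <- numeric(0)
  objs <- numeric(0)
  converged <- FALSE
  iter <- 0L
  post <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    post <- e_step(X, model)
    C <- crossprod(post$mean, X)
    model$B <- coordinate_descent_pass(model$B, C, post$second_moment,
                                       pen$lambda1, pen$lambda2, N)
    model$psi <- update_residual_variance(X, model, post,
                                          datatype_of_feature = dt)
    errs[iter] <- reconstruction_error(X, model, post)
    objs[iter] <- penalized_loglik(X, model, post)
    if (iter >= 11L) {
      window <- abs(diff(errs[(iter - 10L):iter]))
      if (mean(window) < tol) { converged <- TRUE; break }
    }
  }
  # posterior consistent with the final coefficients and variances
  post <- e_step(X, model)
  structure(
    list(
      model = model,
      posterior = post,
      trace = tibble::tibble(iteration = seq_len(iter),
                             recon_error = errs, objective = objs),
      converged = converged,
      iterations = iter,
      seed = seed
    ),
    class = "sfa_fit"
  )
}

#' @export
print.sfa_fit <- function(x, ...) {
  cat(sprintf(
    "<sfa_fit> k = %d, %d samples x %d features; %d iteration%s (%s)\n",
    x$model$k, nrow(x$posterior$mean), ncol(x$model$B), x$iterations,
    if (x$iterations == 1L) "" else "s",
    if (x$converged) "converged" else "iteration cap reached"
  ))
  cat(sprintf("  reconstruction error %.6g; psi: %s\n",
              utils::tail(x$trace$recon_error, 1L),
              paste(sprintf("%s = %.4g", names(x$model$psi), x$model$psi),
                    collapse = ", ")))
  invisible(x)
}

#' Factor scores of a fit as a tibble
#' @param fit An `sfa_fit`.
#' @return Tibble with `sample_id` and one column per factor.
#' @export
factor_scores <- function(fit) {
  stopifnot(inherits(fit, "sfa_fit"))
  tibble::as_tibble(fit$posterior$mean, rownames = "sample_id")
}
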