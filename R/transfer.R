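#' Build a transferable single-platform model from a fit
#'
#' Extracts the mRNA (or any one data type's) coefficient block together with
#' the reference cohort's per-gene means and variances, ready for
#' [adapt_coefficients()], [harmonize_expression()] and [project_samples()].
#'
#' @param fit An `sfa_fit`.
#' @param dataset The reference `multiomics_dataset` the model was fitted to
#'   (its block values define the reference per-gene means/variances; pass
#'   the same preprocessed data the fit saw).
#' @param datatype Which block to transfer (default `"mrna"`).
#' @return A `transfer_model`: list with `B` (k x n_genes), `gene_ids`,
#'   `ref_mean`, `ref_var`, `datatype`.
#' @export
transfer_model <- function(fit, dataset, datatype = "mrna") {
  stopifnot(inherits(fit, "sfa_fit"))
  if (!datatype %in% names(dataset$blocks)) {
    stop("data type '", datatype, "' not in dataset", call. = FALSE)
  }
  cols <- which(as.character(fit$model$datatype_of_feature) == datatype)
  B <- fit$model$B[, cols, drop = FALSE]
  vals <- dataset$blocks[[datatype]]$values
  stopifnot(identical(colnames(vals), colnames(B)))
  structure(
    list(B = B, gene_ids = colnames(B),
         ref_mean = colMeans(vals),
         ref_var = apply(vals, 2L, stats::var),
         datatype = datatype),
    class = "transfer_model"
  )
}

#' @export
print.transfer_model <- function(x, ...) {
  cat(sprintf("<transfer_model> '%s': %d factors x %d genes\n",
              x$datatype, nrow(x$B), length(x$gene_ids)))
  invisible(x)
}

#' Undo precision weighting in transferred coefficients
#'
#' When the reference model was fitted on weight-multiplied expression, its
#' coefficients absorb the per-gene precision weights; to apply them to an
#' unweighted platform each gene's coefficients are divided by that gene's
#' average weight over the reference samples (the `avg_weights` attribute
#' recorded by [apply_precision_weights()]).
#'
#' @param tm A `transfer_model`.
#' @param avg_weights Named positive numeric vector of per-gene mean weights;
#'   must cover every modeled gene.
#' @return The adjusted `transfer_model`.
#' @export
adapt_coefficients <- function(tm, avg_weights) {
  stopifnot(inherits(tm, "transfer_model"))
  missing <- setdiff(tm$gene_ids, names(avg_weights))
  if (length(missing) > 0L) {
    stop("missing average weight for gene(s): ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  w <- avg_weights[tm$gene_ids]
  if (any(w <= 0)) stop("average weights must be positive", call. = FALSE)
  tm$B <- sweep(tm$B, 2L, w, "/")
  tm
}

#' Map probes to genes and harmonize a new cohort's expression
#'
#' For each modeled gene the most variable probe on the new platform is
#' chosen (variance computed on the new cohort), the probe's values are
#' mean-centered on the new cohort, and scaled by
#' `sqrt(reference variance / new variance)` so each gene has the reference
#' cohort's variance. Genes without any probe are dropped from both the
#' expression and the transfer model; the drop count is reported as a
#' message (no renormalization of the remaining coefficients is applied).
#'
#' @param new_expr [omics_matrix()] or samples-by-probes matrix of the new
#'   cohort.
#' @param tm A `transfer_model` (after [adapt_coefficients()] if the
#'   reference used precision weights).
#' @param probe_map Two-column data frame `probe`, `gene` (probe ids matching
#'   `new_expr` columns). If `NULL`, `new_expr` columns are taken as gene ids
#'   directly.
#' @return List: `expr` (harmonized [omics_matrix()], genes in model order),
#'   `tm` (the possibly gene-restricted transfer model), `dropped`
#'   (character vector of genes without probes).
#' @export
harmonize_expression <- function(new_expr, tm, probe_map = NULL) {
  X <- if (inherits(new_expr, "omics_matrix")) new_expr$values else as.matrix(new_expr)
  if (is.null(probe_map)) {
    probe_map <- data.frame(probe = colnames(X), gene = colnames(X))
  }
  probe_map <- probe_map[probe_map$probe %in% colnames(X), , drop = FALSE]
  keep <- intersect(tm$gene_ids, unique(probe_map$gene))
  dropped <- setdiff(tm$gene_ids, keep)
  if (length(dropped) > 0L) {
    message(sprintf("harmonize_expression: %d modeled gene(s) have no probe and are dropped",
                    length(dropped)))
    tm$B <- tm$B[, keep, drop = FALSE]
    tm$gene_ids <- keep
    tm$ref_mean <- tm$ref_mean[keep]
    tm$ref_var <- tm$ref_var[keep]
  }
  probe_var <- apply(X, 2L, stats::var)
  cols <- vapply(keep, function(g) {
    cand <- probe_map$probe[probe_map$gene == g]
    cand[which.max(probe_var[cand])]
  }, character(1))
  H <- X[, cols, drop = FALSE]
  colnames(H) <- keep
  new_var <- apply(H, 2L, stats::var)
  zero <- keep[new_var <= 0]
  if (length(zero) > 0L) {
    stop("zero variance on the new cohort for gene(s): ",
         paste(utils::head(zero, 5L), collapse = ", "), call. = FALSE)
  }
  H <- sweep(H, 2L, colMeans(H), "-")
  H <- sweep(H, 2L, sqrt(tm$ref_var / new_var), "*")
  list(expr = omics_matrix(H, tm$datatype), tm = tm, dropped = dropped)
}

#' Project expression profiles onto fitted factors
#'
#' Closed-form factor scores with the sparse coefficients held fixed:
#' \deqn{Z = X_{mRNA}\, B_{mRNA}^T (B_{mRNA} B_{mRNA}^T + I)^{-1}.}
#' Works for a whole cohort or a single sample (one-row matrix). Gene columns
#' must be aligned to the transfer model's gene order; a factor with all-zero
#' coefficients receives score 0 everywhere.
#'
#' @param expr Harmonized expression ([omics_matrix()] or matrix), genes
#'   matching `tm$gene_ids` in order.
#' @param tm A `transfer_model`.
#' @return Tibble with `sample_id` and one column per factor.
#' @export
project_samples <- function(expr, tm) {
  X <- if (inherits(expr, "omics_matrix")) expr$values else as.matrix(expr)
  if (ncol(X) != length(tm$gene_ids) ||
      (!is.null(colnames(X)) && !identical(colnames(X), tm$gene_ids))) {
    stop("expression columns are not aligned to the transfer model's genes",
         call. = FALSE)
  }
  B <- tm$B
  k <- nrow(B)
  Z <- X %*% t(B) %*% solve(B %*% t(B) + diag(k))
  colnames(Z) <- rownames(B)
  if (is.null(rownames(X))) rownames(X) <- paste0("S", seq_len(nrow(X)))
  tibble::as_tibble(Z) |>
    dplyr::mutate(sample_id = rownames(X), .before = 1L)
}
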