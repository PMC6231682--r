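#' Convergence trace of a fit
#'
#' Reconstruction error (log scale) and penalized objective per iteration.
#'
#' @param object An `sfa_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sfa_fit
#' @export
autoplot.sfa_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, -"iteration",
                            names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "EM iteration", y = NULL,
                  title = "Sparse factor analysis convergence") +
    ggplot2::theme_minimal()
}

#' Heatmap of explained variance per factor and data type
#'
#' @param ev Tibble from [explained_variance()].
#' @param include_total Show the per-block `"all"` row (default `FALSE`).
#' @return A ggplot object.
#' @export
plot_explained_variance <- function(ev, include_total = FALSE) {
  df <- if (include_total) ev else dplyr::filter(ev, .data$factor != "all")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$datatype,
                                   fill = .data$explained_variance)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$explained_variance)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 name = "explained\nvariance") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of normalized enrichment scores
#'
#' @param object An `sfa_gsea` tibble from [run_factor_gsea()].
#' @param filtered Show only pairs passing the report filter (default
#'   `FALSE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sfa_gsea
#' @export
autoplot.sfa_gsea <- function(object, filtered = FALSE, ...) {
  df <- if (filtered) dplyr::filter(object, .data$passes_filter) else object
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$set_name,
                                   fill = .data$nes)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                                  midpoint = 0, name = "NES") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Gene-set enrichment per factor") +
    ggplot2::theme_minimal()
}

#' Effect-size matrix of factor-label associations
#'
#' @param assoc Tibble from [factor_mutation_association()], optionally with
#'   a `label` column distinguishing several binary labels.
#' @param alpha Show only associations with `p_value` below this (default
#'   0.05, mirroring the usual reporting cut).
#' @return A ggplot object.
#' @export
plot_association <- function(assoc, alpha = 0.05) {
  df <- dplyr::filter(assoc, .data$p_value < alpha)
  if (!"label" %in% names(df)) df$label <- "label"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$label,
                                   fill = .data$effect_size)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0.5,
                                  limits = c(0, 1), name = "U / (n1 n2)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
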