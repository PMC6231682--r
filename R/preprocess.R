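#' Keep the most variable genes by median absolute deviation
#'
#' Ranks features by the raw median absolute deviation of their values across
#' samples (no consistency constant) and keeps the `count` largest, preserving
#' the original column order among the selected. Ties at the cutoff are broken
#' by original column order.
#'
#' @param expr An [omics_matrix()].
#' @param count Number of features to keep (>= 1). If `count` exceeds the
#'   number of features, all are kept.
#' @return An `omics_matrix` restricted to the selected features (weights
#'   subset accordingly).
#' @export
select_top_mad_genes <- function(expr, count) {
  stopifnot(inherits(expr, "omics_matrix"))
  if (!is.numeric(count) || length(count) != 1L || count < 1) {
    stop("`count` must be a single integer >= 1", call. = FALSE)
  }
  count <- as.integer(count)
  mads <- apply(expr$values, 2L, function(v) stats::median(abs(v - stats::median(v))))
  keep_n <- min(count, length(mads))
  # stable: order() breaks MAD ties by original position
  top <- sort(order(-mads)[seq_len(keep_n)])
  omics_matrix(
    expr$values[, top, drop = FALSE], expr$datatype,
    if (is.null(expr$weights)) NULL else expr$weights[, top, drop = FALSE]
  )
}

#' Fold precision weights into expression values
#'
#' Multiplies each expression value by its precision weight (e.g. the voom
#' weight encoding the mean-variance trend of log-count data), so downstream
#' least-squares steps are implicitly weighted. The per-gene mean weight is
#' recorded in the result's `avg_weights` attribute for later coefficient
#' adjustment when a model is transferred to unweighted platforms
#' (see [adapt_coefficients()]).
#'
#' @param expr An [omics_matrix()] with `weights` present.
#' @return An `omics_matrix` of weighted values; weights slot cleared, with
#'   attribute `avg_weights` (named per-gene mean weight).
#' @export
apply_precision_weights <- function(expr) {
  stopifnot(inherits(expr, "omics_matrix"))
  if (is.null(expr$weights)) stop("`expr` has no precision weights", call. = FALSE)
  out <- omics_matrix(expr$values * expr$weights, expr$datatype)
  attr(out, "avg_weights") <- colMeans(expr$weights)
  out
}

#' Summarize segmented copy number over recurrent regions
#'
#' For each sample and region, takes the unweighted median of the values of
#' all of that sample's segments that overlap the region by at least one base
#' pair (coordinates 1-based inclusive). Every sample must have at least one
#' overlapping segment per region.
#'
#' @param segments Segment tibble as from [read_seg()].
#' @param regions Region tibble as from [read_regions()].
#' @param sample_ids Samples to summarize; defaults to the samples present in
#'   `segments`, in order of first appearance.
#' @param datatype Data type label for the resulting matrix.
#' @return An [omics_matrix()], samples x regions.
#' @export
summarize_cn_regions <- function(segments, regions, sample_ids = NULL,
                                 datatype = "cn") {
  if (is.null(sample_ids)) sample_ids <- unique(segments$sample_id)
  vals <- matrix(NA_real_, length(sample_ids), nrow(regions),
                 dimnames = list(sample_ids, regions$region_id))
  missing_pairs <- character(0)
  for (s in sample_ids) {
    seg_s <- segments[segments$sample_id == s, , drop = FALSE]
    for (r in seq_len(nrow(regions))) {
      hit <- seg_s$chrom == regions$chrom[r] &
        seg_s$start <= regions$end[r] &
        seg_s$end >= regions$start[r]
      if (!any(hit)) {
        missing_pairs <- c(missing_pairs,
                           sprintf("(%s, %s)", s, regions$region_id[r]))
      } else {
        vals[s, r] <- stats::median(seg_s$value[hit])
      }
    }
  }
  if (length(missing_pairs) > 0L) {
    stop("no overlapping segment for: ",
         paste(missing_pairs, collapse = ", "), call. = FALSE)
  }
  omics_matrix(vals, datatype)
}

#' Center features and scale each data type to unit pooled spread
#'
#' Each feature is mean-centered (the factor model has no intercept), then
#' every block is divided by a single scalar: the pooled standard deviation of
#' all its centered entries. This removes gross scale differences between data
#' types without erasing the within-type variance structure that the shared
#' per-type penalty acts on. Centering means and scale factors are stored in
#' the returned dataset (`$centers`, `$scales`) for use when projecting new
#' samples.
#'
#' @param dataset A `multiomics_dataset`.
#' @param center Mean-center each feature first (default `TRUE`).
#' @return The dataset with scaled blocks plus `centers` (list of per-feature
#'   means per block) and `scales` (named per-block scalar).
#' @export
scale_by_datatype_sd <- function(dataset, center = TRUE) {
  stopifnot(inherits(dataset, "multiomics_dataset"))
  centers <- list()
  scales <- numeric(0)
  blocks <- lapply(dataset$blocks, function(b) {
    v <- b$values
    mu <- if (center) colMeans(v) else rep(0, ncol(v))
    v <- sweep(v, 2L, mu, "-")
    s <- stats::sd(as.vector(v))
    if (!is.finite(s) || s <= 0) {
      stop("zero pooled SD in data type '", b$datatype, "'", call. = FALSE)
    }
    centers[[b$datatype]] <<- mu
    scales[[b$datatype]] <<- s
    omics_matrix(v / s, b$datatype, b$weights)
  })
  dataset$blocks <- blocks
  dataset$centers <- centers
  dataset$scales <- scales
  dataset
}
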