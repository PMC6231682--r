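#' Construct a single-data-type omics matrix
#'
#' An `omics_matrix` holds one data type's measurements as a numeric
#' samples-by-features matrix, optionally accompanied by a shape-matched
#' matrix of strictly positive precision weights (e.g. voom weights for
#' log-count expression data).
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#'   Row and column names are taken as sample and feature ids; unnamed axes
#'   get `S1..SN` / `F1..Fn`.
#' @param datatype Single string labelling the data type (e.g. `"mrna"`,
#'   `"cn"`, `"rppa"`).
#' @param weights Optional numeric matrix of strictly positive precision
#'   weights with the same shape as `values`.
#' @return An object of class `omics_matrix`: a list with elements `values`,
#'   `datatype` and `weights`.
#' @examples
#' m <- omics_matrix(matrix(rnorm(20), 4, 5), "mrna")
#' dim(m)
#' @export
omics_matrix <- function(values, datatype, weights = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`values` contains missing or non-finite entries; the factor model ",
         "has no missing-data mechanism", call. = FALSE)
  }
  if (is.null(rownames(values))) rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("F", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    stop("duplicate feature id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  stopifnot(is.character(datatype), length(datatype) == 1L)
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    if (!identical(dim(weights), dim(values))) {
      stop("`weights` must have the same shape as `values`", call. = FALSE)
    }
    if (anyNA(weights) || any(weights <= 0)) {
      stop("`weights` must be strictly positive", call. = FALSE)
    }
    dimnames(weights) <- dimnames(values)
  }
  structure(
    list(values = values, datatype = datatype, weights = weights),
    class = "omics_matrix"
  )
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf(
    "<omics_matrix '%s'> %d samples x %d features%s\n",
    x$datatype, nrow(x$values), ncol(x$values),
    if (is.null(x$weights)) "" else " (with precision weights)"
  ))
  invisible(x)
}

#' Sample and feature ids of an omics matrix
#' @param x An `omics_matrix`.
#' @return Character vector of ids in matrix order.
#' @export
sample_ids <- function(x) UseMethod("sample_ids")

#' @export
sample_ids.omics_matrix <- function(x) rownames(x$values)

#' @rdname sample_ids
#' @export
feature_ids <- function(x) UseMethod("feature_ids")

#' @export
feature_ids.omics_matrix <- function(x) colnames(x$values)

#' @importFrom tibble as_tibble
#' @method as_tibble omics_matrix
#' @export
as_tibble.omics_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "feature_id",
                        values_to = "value") |>
    dplyr::mutate(datatype = x$datatype, .before = 1L)
}

#' Stack sample-aligned omics matrices into a multi-omics dataset
#'
#' Blocks are restricted to the intersection of their sample ids and reordered
#' to a common order (the sample order of the first block, restricted to the
#' intersection). Samples present in only some blocks are dropped with a
#' message. The stacked matrix is the per-sample concatenation
#' `X = [X_1, ..., X_t]` on which the factor model operates.
#'
#' @param blocks A list of [omics_matrix()] objects (at least one); data type
#'   labels must be unique.
#' @return A `multiomics_dataset`: list with `blocks` (sample-aligned
#'   `omics_matrix` list, named by data type), `sample_ids`, and
#'   `datatype_of_feature` (factor over stacked columns).
#' @examples
#' a <- omics_matrix(matrix(rnorm(6), 2, 3,
#'   dimnames = list(c("s1", "s2"), c("g1", "g2", "g3"))), "mrna")
#' b <- omics_matrix(matrix(rnorm(4), 2, 2,
#'   dimnames = list(c("s2", "s1"), c("r1", "r2"))), "cn")
#' ds <- assemble_dataset(list(a, b))
#' dim(dataset_matrix(ds))
#' @export
assemble_dataset <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  blocks <- lapply(blocks, function(b) {
    if (!inherits(b, "omics_matrix")) stop("all blocks must be omics_matrix objects", call. = FALSE)
    b
  })
  labels <- vapply(blocks, function(b) b$datatype, character(1))
  if (anyDuplicated(labels)) stop("duplicate data type labels", call. = FALSE)
  names(blocks) <- labels

  common <- Reduce(intersect, lapply(blocks, sample_ids))
  if (length(common) == 0L) stop("sample id intersection is empty", call. = FALSE)
  # keep the first block's ordering for determinism
  common <- sample_ids(blocks[[1]])[sample_ids(blocks[[1]]) %in% common]
  n_drop <- sum(vapply(blocks, function(b) length(setdiff(sample_ids(b), common)),
                       integer(1)))
  if (n_drop > 0L) {
    message(sprintf("assemble_dataset: dropped %d sample entr%s outside the common id set",
                    n_drop, if (n_drop == 1L) "y" else "ies"))
  }
  blocks <- lapply(blocks, function(b) {
    v <- b$values[common, , drop = FALSE]
    w <- if (is.null(b$weights)) NULL else b$weights[common, , drop = FALSE]
    omics_matrix(v, b$datatype, w)
  })
  n_i <- vapply(blocks, function(b) ncol(b$values), integer(1))
  structure(
    list(
      blocks = blocks,
      sample_ids = common,
      datatype_of_feature = factor(rep(labels, n_i), levels = labels)
    ),
    class = "multiomics_dataset"
  )
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  cat(sprintf("<multiomics_dataset> %d samples, %d data types (%s), %d stacked features\n",
              length(x$sample_ids), length(x$blocks),
              paste(names(x$blocks), collapse = ", "),
              length(x$datatype_of_feature)))
  invisible(x)
}

#' Stacked data matrix of a multi-omics dataset
#'
#' @param dataset A `multiomics_dataset`.
#' @return Numeric matrix `N x n` with blocks concatenated column-wise in
#'   block order.
#' @export
dataset_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "multiomics_dataset"))
  do.call(cbind, lapply(dataset$blocks, function(b) b$values))
}

#' Per-data-type feature counts
#' @param dataset A `multiomics_dataset`.
#' @return Named integer vector `n_i`.
#' @export
block_sizes <- function(dataset) {
  vapply(dataset$blocks, function(b) ncol(b$values), integer(1))
}

# column index ranges per block of the stacked matrix
block_columns <- function(dataset) {
  n_i <- block_sizes(dataset)
  ends <- cumsum(n_i)
  starts <- ends - n_i + 1L
  Map(function(s, e) seq.int(s, e), starts, ends)
}
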