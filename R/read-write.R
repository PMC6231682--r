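#' Read a sample-by-feature matrix from TSV
#'
#' Expects a header row of feature ids and a first column of sample ids; the
#' body must be fully numeric with no missing cells. Set `transpose = TRUE`
#' for files stored features-by-samples.
#'
#' @param path Path to a tab-separated file.
#' @param datatype Data type label for the resulting matrix.
#' @param transpose If `TRUE`, the file is features-by-samples and is
#'   transposed after reading.
#' @return An [omics_matrix()].
#' @export
read_omics_matrix <- function(path, datatype, transpose = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix file needs an id column plus >= 1 feature column", call. = FALSE)
  ids <- as.character(df[[1L]])
  feature_names <- colnames(df)[-1L]   # subsetting would de-duplicate names
  body <- df[, -1L, drop = FALSE]
  # an all-NA column is read as logical; it is a missing-data problem, not a type one
  body[] <- lapply(body, function(col) {
    if (is.logical(col) && all(is.na(col))) as.numeric(col) else col
  })
  bad <- !vapply(body, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric column(s) in ", path, ": ",
         paste(feature_names[bad], collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(body)
  if (anyNA(m)) stop("missing cells in ", path, call. = FALSE)
  rownames(m) <- ids
  colnames(m) <- feature_names
  if (transpose) m <- t(m)
  omics_matrix(m, datatype)
}

#' Write a sample-by-feature matrix to TSV
#'
#' Inverse of [read_omics_matrix()]: first column `sample_id`, one column per
#' feature.
#'
#' @param x An [omics_matrix()] or numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(x, path) {
  m <- if (inherits(x, "omics_matrix")) x$values else as.matrix(x)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read segmented copy-number calls (SEG dialect)
#'
#' Tab-separated with at least five columns: sample, chromosome, start, end,
#' value. Coordinates are treated as 1-based inclusive base pairs (the common
#' SEG convention). A header line is detected by non-numeric start/end fields.
#'
#' @param path Path to a SEG file.
#' @return A tibble with columns `sample_id`, `chrom`, `start`, `end`,
#'   `value`, in file order.
#' @export
read_seg <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(sample_id = character(), chrom = character(),
                          start = integer(), end = integer(), value = double()))
  }
  first <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  has_header <- length(first) >= 5L &&
    (is.na(suppressWarnings(as.integer(first[3L]))) ||
       is.na(suppressWarnings(as.integer(first[4L]))))
  if (has_header) lines <- lines[-1L]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 5L)
  if (length(short) > 0L) {
    stop("SEG record with fewer than 5 fields at line ", short[1L], call. = FALSE)
  }
  seg <- tibble::tibble(
    sample_id = vapply(fields, `[[`, character(1), 1L),
    chrom     = vapply(fields, `[[`, character(1), 2L),
    start     = suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L))),
    end       = suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 4L))),
    value     = suppressWarnings(as.double(vapply(fields, `[[`, character(1), 5L)))
  )
  if (anyNA(seg$start) || anyNA(seg$end)) stop("non-integer SEG coordinates", call. = FALSE)
  if (anyNA(seg$value)) stop("non-numeric SEG value", call. = FALSE)
  bad <- which(seg$end < seg$start)
  if (length(bad) > 0L) {
    stop("SEG record with end < start (record ", bad[1L], ")", call. = FALSE)
  }
  seg
}

#' Write a segment table in SEG format
#' @param seg Tibble as returned by [read_seg()].
#' @param path Output path.
#' @param header Write a header line.
#' @return `path`, invisibly.
#' @export
write_seg <- function(seg, path, header = TRUE) {
  utils::write.table(seg, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Read recurrently aberrated copy-number regions (BED-like)
#'
#' Tab-separated columns: chrom, start, end, region id, aberration label
#' (`gain` or `loss`). No header.
#'
#' @param path Path to the region file.
#' @return Tibble with columns `region_id`, `chrom`, `start`, `end`, `label`.
#' @export
read_regions <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "region_id", "label"))
  reg <- tibble::tibble(
    region_id = as.character(df$region_id),
    chrom = as.character(df$chrom),
    start = as.integer(df$start),
    end = as.integer(df$end),
    label = as.character(df$label)
  )
  if (anyDuplicated(reg$region_id)) {
    stop("duplicate region id(s): ",
         paste(unique(reg$region_id[duplicated(reg$region_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(reg$end < reg$start)) stop("region with end < start", call. = FALSE)
  reg
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then one or more gene ids, all
#' tab-separated. Duplicate genes within a set are collapsed; duplicate set
#' names and empty sets are errors.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set_name`, `description` and a list-column
#'   `genes` (character vectors). Use [gene_set_list()] for the named-list
#'   view used by enrichment routines.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    stop("GMT line ", bad[1L], " has no genes", call. = FALSE)
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  genes <- lapply(fields, function(f) unique(f[-(1:2)]))
  if (any(lengths(genes) == 0L)) stop("empty gene set", call. = FALSE)
  tibble::tibble(
    set_name = nm,
    description = vapply(fields, `[[`, character(1), 2L),
    genes = genes
  )
}

#' Named-list view of a gene-set collection
#' @param gmt Tibble from [read_gmt()] (or a named list, returned unchanged).
#' @return Named list of character vectors.
#' @export
gene_set_list <- function(gmt) {
  if (is.list(gmt) && !is.data.frame(gmt)) {
    stopifnot(length(gmt) == 0L || !is.null(names(gmt)))
    return(gmt)
  }
  stats::setNames(gmt$genes, gmt$set_name)
}

#' Serialize / restore a fitted sparse-factor model
#'
#' The archive is a single JSON document: metadata (factor count, data type
#' labels, penalty settings, convergence info) plus the numeric arrays
#' (coefficients, residual variances, factor scores) at full precision.
#'
#' @param fit An `sfa_fit` object from [fit_sfa()].
#' @param path Output path (conventionally `.json`).
#' @return `path` invisibly, or the restored `sfa_fit`.
#' @export
write_sfa_model <- function(fit, path) {
  stopifnot(inherits(fit, "sfa_fit"))
  obj <- list(
    format = "omicsfa-model-1",
    k = fit$model$k,
    datatypes = names(fit$model$psi),
    feature_ids = colnames(fit$model$B),
    datatype_of_feature = as.character(fit$model$datatype_of_feature),
    sample_ids = rownames(fit$posterior$mean),
    B = fit$model$B,
    psi = fit$model$psi,
    penalties = list(alpha = fit$model$penalties$alpha,
                     levels = fit$model$penalties$levels),
    factors = fit$posterior$mean,
    second_moment = fit$posterior$second_moment,
    scale_applied = fit$posterior$scale_applied,
    converged = fit$converged,
    iterations = fit$iterations,
    trace = as.list(fit$trace)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_sfa_model
#' @export
read_sfa_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "omicsfa-model-1")) stop("unrecognized model archive", call. = FALSE)
  B <- matrix(obj$B, nrow = obj$k, byrow = FALSE)
  # jsonlite simplifies row-major matrices back to R matrices already
  if (is.matrix(obj$B)) B <- obj$B
  colnames(B) <- obj$feature_ids
  rownames(B) <- paste0("factor_", seq_len(obj$k))
  EZ <- obj$factors
  rownames(EZ) <- obj$sample_ids
  colnames(EZ) <- rownames(B)
  psi <- stats::setNames(as.numeric(obj$psi), obj$datatypes)
  structure(
    list(
      model = list(
        B = B, psi = psi, k = obj$k,
        penalties = penalty_config(obj$penalties$alpha,
                                   stats::setNames(as.numeric(obj$penalties$levels),
                                                   obj$datatypes)),
        datatype_of_feature = factor(obj$datatype_of_feature, levels = obj$datatypes)
      ),
      posterior = structure(
        list(mean = EZ, second_moment = obj$second_moment,
             scale_applied = as.numeric(obj$scale_applied)),
        class = "posterior_factors"
      ),
      trace = tibble::as_tibble(obj$trace),
      converged = obj$converged,
      iterations = obj$iterations
    ),
    class = "sfa_fit"
  )
}
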