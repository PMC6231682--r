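#' Regress expression on factors to get correlation-like gene profiles
#'
#' Each gene is regressed jointly on all `k` factors:
#' `C = (Z'Z)^-1 Z' X_m` (k x n_m), then each gene's coefficients are divided
#' by that gene's sample standard deviation. For a single unit-variance factor
#' the normalized entry is exactly the Pearson correlation between factor and
#' gene; with several factors it is a correlation-like quantity adjusted for
#' the other factors. The full expression matrix (all genes, not only the
#' modeled subset) is intended here.
#'
#' @param expr_full An [omics_matrix()] or numeric samples-by-genes matrix.
#' @param factors A `posterior_factors`, `sfa_fit`, or numeric N x k matrix;
#'   samples must align with `expr_full`.
#' @return A `factor_expression_profile`: list with `coefficients` (k x n_m),
#'   `normalized` (k x n_m), `gene_ids`, `gene_sd`.
#' @export
factor_expression_coefficients <- function(expr_full, factors) {
  X <- if (inherits(expr_full, "omics_matrix")) expr_full$values else as.matrix(expr_full)
  Z <- factor_matrix(factors)
  if (nrow(X) != nrow(Z)) stop("samples of expression and factors differ", call. = FALSE)
  G <- crossprod(Z)
  C <- tryCatch(solve(G, crossprod(Z, X)),
                error = function(e) stop("rank-deficient factor matrix", call. = FALSE))
  gene_sd <- apply(X, 2L, stats::sd)
  normalized <- sweep(C, 2L, gene_sd, "/")
  rownames(C) <- rownames(normalized) <- colnames(Z)
  structure(
    list(coefficients = C, normalized = normalized,
         gene_ids = colnames(X), gene_sd = gene_sd),
    class = "factor_expression_profile"
  )
}

# accept several factor containers
factor_matrix <- function(factors) {
  if (inherits(factors, "sfa_fit")) return(factors$posterior$mean)
  if (inherits(factors, "posterior_factors")) return(factors$mean)
  Z <- as.matrix(factors)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("factor_", seq_len(ncol(Z)))
  Z
}

#' @export
print.factor_expression_profile <- function(x, ...) {
  cat(sprintf("<factor_expression_profile> %d factors x %d genes\n",
              nrow(x$coefficients), length(x$gene_ids)))
  invisible(x)
}

#' Rank genes for one factor by normalized coefficient
#'
#' @param profile A `factor_expression_profile`.
#' @param factor Factor index or name.
#' @return Tibble `gene`, `score` sorted by decreasing score; ties broken by
#'   gene id for determinism.
#' @export
rank_genes <- function(profile, factor = 1L) {
  stopifnot(inherits(profile, "factor_expression_profile"))
  s <- profile$normalized[factor, ]
  ord <- order(-s, profile$gene_ids, method = "radix")
  tibble::tibble(gene = profile$gene_ids[ord], score = unname(s[ord]))
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating `|score|^p / N_R` at gene-set hits
#' (`N_R` = total hit weight) and `-1/(n - |S|)` at misses; the enrichment
#' score is the running-sum value of largest magnitude. The leading edge is
#' the fraction of set members at or before the extremum for positive ES
#' (strictly after, for negative ES).
#'
#' @param ranked Tibble from [rank_genes()] (columns `gene`, `score`), or a
#'   named score vector already in rank order.
#' @param gene_set Character vector of gene ids; must intersect the ranking.
#' @param p Weight exponent (default 1, the classic GSEA weighting).
#' @return List: `es`, `at_rank` (position of the extremum),
#'   `leading_edge` (proportion), `n_hits`.
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  if (is.data.frame(ranked)) {
    genes <- ranked$gene; scores <- ranked$score
  } else {
    genes <- names(ranked); scores <- unname(ranked)
  }
  hit <- genes %in% gene_set
  m <- sum(hit)
  if (m == 0L) stop("gene set does not intersect the ranked list", call. = FALSE)
  n <- length(genes)
  if (m == n) stop("gene set covers the whole ranked list", call. = FALSE)
  w <- abs(scores)^p
  NR <- sum(w[hit])
  inc <- ifelse(hit, if (NR > 0) w / NR else 1 / m, 0)
  inc[!hit] <- -1 / (n - m)
  run <- cumsum(inc)
  at <- which.max(abs(run))
  es <- run[at]
  pos <- which(hit)
  le <- if (es >= 0) sum(pos <= at) / m else sum(pos > at) / m
  list(es = es, at_rank = at, leading_edge = le, n_hits = m)
}

# ES for many sets at once given sorted scores; positions precomputed per set.
# Same running-sum definition as enrichment_score, evaluated only at hit
# boundaries (the only candidate extrema).
.es_batch <- function(scores_sorted, set_positions, p = 1) {
  n <- length(scores_sorted)
  w_all <- abs(scores_sorted)^p
  vapply(set_positions, function(pos) {
    m <- length(pos)
    if (m == 0L || m == n) return(NA_real_)
    w <- w_all[pos]
    NR <- sum(w)
    hits <- if (NR > 0) cumsum(w) / NR else seq_len(m) / m
    miss_unit <- 1 / (n - m)
    at_hit <- hits - (pos - seq_len(m)) * miss_unit        # value at each hit
    before_hit <- c(0, hits[-m]) - (pos - seq_len(m)) * miss_unit # just before
    # running sum is piecewise: max at a hit, min just before one (or 0 at ends)
    hi <- max(at_hit)
    lo <- min(before_hit, 0)
    if (abs(hi) >= abs(lo)) hi else lo
  }, numeric(1))
}

#' Factor-tailored gene-set enrichment analysis
#'
#' The full pipeline: regress expression on factors
#' ([factor_expression_coefficients()]), rank genes per factor
#' ([rank_genes()]), score every (gene set, factor) pair
#' ([enrichment_score()]), and assess significance by a sample permutation
#' test — each permutation shuffles the factor rows across samples and
#' recomputes the entire regression-normalization-ranking-scoring chain, so
#' the null reflects the whole procedure, not just the scoring step.
#' NES divides each ES by the mean same-sign null ES of its pair; p-values
#' use the add-one convention; FDR follows the GSEA pooled-NES tail-ratio
#' convention (Benjamini-Hochberg on the permutation p-values available via
#' `fdr_method = "BH"`).
#'
#' @param expr_full Expression over all genes ([omics_matrix()] or matrix).
#' @param factors Factors aligned to the expression samples (`sfa_fit`,
#'   `posterior_factors`, or matrix).
#' @param gene_sets Tibble from [read_gmt()] or a named list of gene id
#'   vectors.
#' @param n_perm Number of sample permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @param p Weight exponent for the running sum (default 1).
#' @param fdr_method `"pool"` (GSEA NES pooling, default) or `"BH"`.
#' @param min_size Sets with fewer overlapping genes are dropped (default 2).
#' @return A tibble of class `sfa_gsea` with one row per (set, factor):
#'   `set_name`, `factor`, `es`, `nes`, `at_rank`, `leading_edge`,
#'   `p_value`, `fdr`, `passes_filter` (the S3-style report filter
#'   FDR < 0.25 and leading edge < 0.5).
#' @export
run_factor_gsea <- function(expr_full, factors, gene_sets, n_perm = 1000,
                            seed = NULL, p = 1, fdr_method = c("pool", "BH"),
                            min_size = 2L) {
  fdr_method <- match.arg(fdr_method)
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  X <- if (inherits(expr_full, "omics_matrix")) expr_full$values else as.matrix(expr_full)
  Z <- factor_matrix(factors)
  sets <- gene_set_list(gene_sets)
  sets <- lapply(sets, intersect, y = colnames(X))
  sets <- sets[lengths(sets) >= min_size & lengths(sets) < ncol(X)]
  if (length(sets) == 0L) {
    warning("no usable gene sets after intersection with the expression matrix")
    out <- tibble::tibble(set_name = character(), factor = character(),
                          es = double(), nes = double(), at_rank = integer(),
                          leading_edge = double(), p_value = double(),
                          fdr = double(), passes_filter = logical())
    class(out) <- c("sfa_gsea", class(out))
    return(out)
  }
  k <- ncol(Z)
  factor_names <- colnames(Z)

  observed <- .gsea_pass(X, Z, sets, p, details = TRUE)
  es_obs <- observed$es                                    # sets x k

  null_es <- array(NA_real_, c(length(sets), k, n_perm))
  N <- nrow(Z)
  for (b in seq_len(n_perm)) {
    Zp <- Z[sample.int(N), , drop = FALSE]
    null_es[, , b] <- .gsea_pass(X, Zp, sets, p)$es
  }

  stat <- nes_and_fdr(es_obs, null_es, fdr_method = fdr_method)

  out <- tibble::tibble(
    set_name = rep(names(sets), times = k),
    factor = rep(factor_names, each = length(sets)),
    es = as.vector(es_obs),
    nes = as.vector(stat$nes),
    at_rank = as.vector(observed$at_rank),
    leading_edge = as.vector(observed$leading_edge),
    p_value = as.vector(stat$p_value),
    fdr = as.vector(stat$fdr)
  )
  out$passes_filter <- !is.na(out$fdr) & out$fdr < 0.25 & out$leading_edge < 0.5
  class(out) <- c("sfa_gsea", class(out))
  out
}

#' Normalize enrichment scores and assess significance against a null
#'
#' Given observed enrichment scores and their permutation nulls:
#' NES divides each ES by the mean same-sign null ES of its own
#' (set, factor) pair (`NA` and flagged when no same-sign nulls exist);
#' p-values count same-sign nulls at least as extreme among the same-sign
#' nulls, with the add-one convention
#' `p = (1 + #extreme) / (1 + #same-sign)` so null p-values are
#' approximately uniform; FDR q-values follow the
#' GSEA pooled-NES convention — the tail fraction of all null NES beyond the
#' observed NES divided by the tail fraction of observed NES beyond it,
#' same sign, capped at 1 — or Benjamini-Hochberg on the p-values.
#'
#' @param es_obs Numeric matrix of observed ES (sets x factors; a vector is
#'   treated as one factor).
#' @param null_es Numeric array `sets x factors x n_perm` of null ES (a
#'   matrix `sets x n_perm` when `es_obs` is a vector).
#' @param fdr_method `"pool"` (default) or `"BH"`.
#' @return List of matrices shaped like `es_obs`: `nes`, `p_value`, `fdr`,
#'   and logical `undefined` (no same-sign nulls for that pair).
#' @export
nes_and_fdr <- function(es_obs, null_es, fdr_method = c("pool", "BH")) {
  fdr_method <- match.arg(fdr_method)
  if (is.null(dim(es_obs))) es_obs <- matrix(es_obs, ncol = 1)
  if (length(dim(null_es)) == 2L) {
    null_es <- array(null_es, c(nrow(null_es), 1L, ncol(null_es)))
  }
  stopifnot(dim(null_es)[1] == nrow(es_obs), dim(null_es)[2] == ncol(es_obs))
  n_set <- nrow(es_obs); k <- ncol(es_obs); n_perm <- dim(null_es)[3]

  nes_obs <- matrix(NA_real_, n_set, k)
  p_val <- matrix(NA_real_, n_set, k)
  undefined <- matrix(FALSE, n_set, k)
  nes_null <- array(NA_real_, dim(null_es))
  for (s in seq_len(n_set)) for (f in seq_len(k)) {
    nulls <- null_es[s, f, ]
    obs <- es_obs[s, f]
    pos_nulls <- nulls[nulls >= 0]
    neg_nulls <- nulls[nulls < 0]
    mpos <- if (length(pos_nulls) > 0) mean(pos_nulls) else NA_real_
    mneg <- if (length(neg_nulls) > 0) mean(neg_nulls) else NA_real_
    if (obs >= 0) {
      nes_obs[s, f] <- if (is.na(mpos)) NA_real_ else obs / mpos
      undefined[s, f] <- is.na(mpos)
      p_val[s, f] <- (1 + sum(pos_nulls >= obs)) / (1 + length(pos_nulls))
    } else {
      nes_obs[s, f] <- if (is.na(mneg)) NA_real_ else -obs / mneg
      undefined[s, f] <- is.na(mneg)
      p_val[s, f] <- (1 + sum(neg_nulls <= obs)) / (1 + length(neg_nulls))
    }
    nes_null[s, f, ] <- ifelse(nulls >= 0,
                               if (is.na(mpos)) NA_real_ else nulls / mpos,
                               if (is.na(mneg)) NA_real_ else -nulls / mneg)
  }

  fdr <- matrix(NA_real_, n_set, k)
  if (fdr_method == "pool") {
    pool <- as.vector(nes_null)
    obs_vec <- as.vector(nes_obs)
    pool_pos <- pool[!is.na(pool) & pool >= 0]
    pool_neg <- pool[!is.na(pool) & pool < 0]
    obs_pos <- obs_vec[!is.na(obs_vec) & obs_vec >= 0]
    obs_neg <- obs_vec[!is.na(obs_vec) & obs_vec < 0]
    for (s in seq_len(n_set)) for (f in seq_len(k)) {
      nes <- nes_obs[s, f]
      if (is.na(nes)) next
      if (nes >= 0) {
        num <- if (length(pool_pos)) mean(pool_pos >= nes) else NA_real_
        den <- mean(obs_pos >= nes)
      } else {
        num <- if (length(pool_neg)) mean(pool_neg <= nes) else NA_real_
        den <- mean(obs_neg <= nes)
      }
      fdr[s, f] <- if (is.na(num) || den == 0) NA_real_ else min(1, num / den)
    }
  } else {
    fdr[] <- stats::p.adjust(as.vector(p_val), method = "BH")
  }
  list(nes = nes_obs, p_value = p_val, fdr = fdr, undefined = undefined)
}

# one regression -> normalization -> ranking -> ES pass over all factors
.gsea_pass <- function(X, Z, sets, p, details = FALSE) {
  prof <- factor_expression_coefficients(X, Z)
  k <- nrow(prof$normalized)
  es <- matrix(NA_real_, length(sets), k)
  at_rank <- matrix(NA_integer_, length(sets), k)
  le <- matrix(NA_real_, length(sets), k)
  for (f in seq_len(k)) {
    s <- prof$normalized[f, ]
    ord <- order(-s, prof$gene_ids, method = "radix")
    genes_sorted <- prof$gene_ids[ord]
    scores_sorted <- unname(s[ord])
    idx <- stats::setNames(seq_along(genes_sorted), genes_sorted)
    positions <- lapply(sets, function(g) sort(unname(idx[g])))
    if (details) {
      ranked <- tibble::tibble(gene = genes_sorted, score = scores_sorted)
      for (si in seq_along(sets)) {
        r <- enrichment_score(ranked, sets[[si]], p = p)
        es[si, f] <- r$es; at_rank[si, f] <- r$at_rank; le[si, f] <- r$leading_edge
      }
    } else {
      es[, f] <- .es_batch(scores_sorted, positions, p = p)
    }
  }
  list(es = es, at_rank = at_rank, leading_edge = le)
}
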