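#' Explained variance per factor and data type
#'
#' For block `i` and factor `j`, the drop in residual sum of squares when the
#' factor is included, relative to the block's total sum of squares:
#' \deqn{(\|X_i - Z_{[-j]} B_{i[-j]}\|_F^2 - \|X_i - Z B_i\|_F^2) / \|X_i\|_F^2}
#' where the `[-j]` quantities drop factor `j` without refitting the others.
#' Because sparse factors are not orthogonal, individual entries can be
#' slightly negative; they are reported as-is (rows with negative entries are
#' flagged, never clipped). The per-block total over all factors is appended
#' as factor `"all"`.
#'
#' @param dataset The fitted `multiomics_dataset`.
#' @param fit An `sfa_fit` (or pass `model` and `posterior` explicitly).
#' @return Tibble of class `sfa_explained_variance`: `datatype`, `factor`,
#'   `explained_variance`, `negative` flag.
#' @export
explained_variance <- function(dataset, fit) {
  model <- fit$model
  post <- fit$posterior
  X <- dataset_matrix(dataset)
  dt <- dataset$datatype_of_feature
  Z <- post$mean
  k <- model$k
  rows <- list()
  for (lv in levels(dt)) {
    cols <- which(dt == lv)
    Xi <- X[, cols, drop = FALSE]
    tot <- sum(Xi^2)
    if (tot == 0) stop("zero-norm block '", lv, "'", call. = FALSE)
    Bi <- model$B[, cols, drop = FALSE]
    full_rss <- sum((Xi - Z %*% Bi)^2)
    ev_j <- vapply(seq_len(k), function(j) {
      drop_rss <- sum((Xi - Z[, -j, drop = FALSE] %*% Bi[-j, , drop = FALSE])^2)
      (drop_rss - full_rss) / tot
    }, numeric(1))
    rows[[lv]] <- tibble::tibble(
      datatype = lv,
      factor = c(rownames(model$B), "all"),
      explained_variance = c(ev_j, (tot - full_rss) / tot)
    )
  }
  out <- dplyr::bind_rows(rows)
  out$negative <- out$explained_variance < 0
  class(out) <- c("sfa_explained_variance", class(out))
  out
}

#' Rank-based association between factor values and a binary label
#'
#' Effect size is the Mann-Whitney U statistic of the factor values in the
#' labelled (e.g. mutated) group versus the rest, divided by the product of
#' the group sizes — the probability that a random labelled sample scores
#' above a random unlabelled one (ties counted one half); identical to the
#' AUC of the factor as a classifier of the label. Two-sided p-values come
#' from the Wilcoxon rank-sum test.
#'
#' @param values Numeric factor values, or an `sfa_fit` (then all factors are
#'   tested).
#' @param label Logical/0-1 vector: `TRUE` for the labelled group.
#' @param adjust Optionally adjust p-values across factors
#'   (`"none"` default, or `"BH"`).
#' @return Tibble: `factor`, `effect_size`, `p_value`, `n_pos`, `n_neg`
#'   (and `p_adjusted` when requested).
#' @export
factor_mutation_association <- function(values, label, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  label <- as.logical(label)
  if (inherits(values, "sfa_fit")) {
    M <- values$posterior$mean
  } else {
    M <- matrix(as.numeric(values), ncol = 1,
                dimnames = list(NULL, "factor_1"))
  }
  if (length(label) != nrow(M)) stop("label length must match samples", call. = FALSE)
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0L || n0 == 0L) stop("both groups must be non-empty", call. = FALSE)
  res <- lapply(colnames(M), function(f) {
    x <- M[label, f]; y <- M[!label, f]
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    u <- unname(wt$statistic)   # = #(x > y) + 0.5 #(x == y)
    tibble::tibble(factor = f, effect_size = u / (n1 * n0),
                   p_value = wt$p.value, n_pos = n1, n_neg = n0)
  })
  out <- dplyr::bind_rows(res)
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Match two factorizations up to permutation and sign
#'
#' Finds the one-to-one assignment between the columns of two factor score
#' matrices (same samples) that maximizes the total absolute Pearson
#' correlation. The assignment is exact: exhaustive for `k <= 7`, otherwise
#' branch-and-bound over permutations with a greedy upper bound; a plain
#' greedy matching is available via `method = "greedy"`.
#'
#' @param factors_a,factors_b N x k matrices (or `sfa_fit` /
#'   `posterior_factors`) over the same samples.
#' @param method `"optimal"` (default) or `"greedy"`.
#' @return Tibble: `factor_a`, `factor_b`, `sign` (+1/-1), `abs_correlation`.
#' @export
match_factors <- function(factors_a, factors_b, method = c("optimal", "greedy")) {
  method <- match.arg(method)
  A <- factor_matrix(factors_a)
  B <- factor_matrix(factors_b)
  if (nrow(A) != nrow(B)) stop("factor matrices have different sample counts", call. = FALSE)
  R <- stats::cor(A, B)
  W <- abs(R)
  ka <- ncol(A); kb <- ncol(B)
  if (ka > kb) stop("factors_a has more columns than factors_b", call. = FALSE)
  assign <- switch(method,
                   greedy = .greedy_assign(W),
                   optimal = .optimal_assign(W))
  tibble::tibble(
    factor_a = colnames(A),
    factor_b = colnames(B)[assign],
    sign = ifelse(R[cbind(seq_len(ka), assign)] >= 0, 1, -1),
    abs_correlation = W[cbind(seq_len(ka), assign)]
  )
}

.greedy_assign <- function(W) {
  ka <- nrow(W)
  assign <- integer(ka)
  used <- logical(ncol(W))
  for (step in seq_len(ka)) {
    W_mask <- W
    W_mask[assign > 0, ] <- -Inf
    W_mask[, used] <- -Inf
    idx <- arrayInd(which.max(W_mask), dim(W))
    assign[idx[1]] <- idx[2]
    used[idx[2]] <- TRUE
  }
  assign
}

.optimal_assign <- function(W) {
  ka <- nrow(W); kb <- ncol(W)
  if (ka <= 7L) {
    perms <- .all_injections(ka, kb)
    scores <- vapply(perms, function(p) sum(W[cbind(seq_len(ka), p)]), numeric(1))
    return(perms[[which.max(scores)]])
  }
  # branch and bound: order rows, bound remaining by column maxima
  best <- list(score = sum(W[cbind(seq_len(ka), .greedy_assign(W))]),
               assign = .greedy_assign(W))
  colmax <- apply(W, 2L, max)
  recurse <- function(row, used, cur, score) {
    if (row > ka) {
      if (score > best$score) best <<- list(score = score, assign = cur)
      return(invisible())
    }
    bound <- score + sum(sort(pmax(apply(W[row:ka, !used, drop = FALSE], 1L, max), 0),
                              decreasing = TRUE)[seq_len(ka - row + 1L)])
    if (bound <= best$score) return(invisible())
    ord <- order(-W[row, ])
    for (j in ord) {
      if (used[j]) next
      used[j] <- TRUE
      cur[row] <- j
      recurse(row + 1L, used, cur, score + W[row, j])
      used[j] <- FALSE
    }
  }
  recurse(1L, logical(kb), integer(ka), 0)
  best$assign
}

.all_injections <- function(ka, kb) {
  if (ka == 0L) return(list(integer(0)))
  out <- list()
  for (cols in utils::combn(kb, ka, simplify = FALSE)) {
    perms <- .permutations(cols)
    out <- c(out, perms)
  }
  out
}

.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}
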