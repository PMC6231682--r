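test_that("factor-expression coefficients equal least squares and correlations", {
  set.seed(71)
  # exact regression: gene = 2 * factor
  z <- stats::rnorm(30)
  X1 <- matrix(2 * z, ncol = 1, dimnames = list(NULL, "g1"))
  prof1 <- factor_expression_coefficients(X1, matrix(z, ncol = 1))
  expect_equal(unname(prof1$coefficients[1, 1]), 2)

  # unit-variance single factor: normalized entry is the Pearson correlation
  zu <- as.vector(scale(stats::rnorm(40)))  # sample sd exactly 1
  Xg <- matrix(stats::rnorm(40 * 6), 40, 6,
               dimnames = list(NULL, paste0("g", 1:6)))
  Xg[, 1] <- 1.5 * zu + 0.3 * stats::rnorm(40)
  prof <- factor_expression_coefficients(Xg, matrix(zu, ncol = 1))
  expect_equal(unname(prof$normalized[1, ]),
               unname(apply(Xg, 2, function(g) stats::cor(zu, g))),
               tolerance = 1e-10)
  expect_true(all(abs(prof$normalized) <= 1 + 1e-10))

  # random 3-factor instance vs normal-equations oracle by explicit inverse
  Z3 <- matrix(stats::rnorm(25 * 3), 25, 3)
  X3 <- matrix(stats::rnorm(25 * 8), 25, 8,
               dimnames = list(NULL, paste0("g", 1:8)))
  prof3 <- factor_expression_coefficients(X3, Z3)
  C_oracle <- solve(t(Z3) %*% Z3) %*% t(Z3) %*% X3
  expect_equal(unname(prof3$coefficients), unname(C_oracle))
  expect_equal(unname(prof3$normalized),
               unname(sweep(C_oracle, 2, apply(X3, 2, stats::sd), "/")))

  # rank-deficient factor matrix is refused
  Zdef <- cbind(Z3[, 1], Z3[, 1])
  expect_error(factor_expression_coefficients(X3, Zdef), "rank")
})

test_that("gene ranking is a stable descending sort with id tie-breaks", {
  prof <- structure(list(
    normalized = matrix(c(0.5, -0.2, 0.9), 1, 3),
    gene_ids = c("A", "B", "C")
  ), class = "factor_expression_profile")
  expect_equal(rank_genes(prof, 1)$gene, c("C", "A", "B"))

  tie <- structure(list(normalized = matrix(c(0.5, 0.5), 1, 2),
                        gene_ids = c("B", "A")),
                   class = "factor_expression_profile")
  expect_equal(rank_genes(tie, 1)$gene, c("A", "B"))

  set.seed(72)
  sc <- stats::rnorm(100)
  prof100 <- structure(list(normalized = matrix(sc, 1, 100),
                            gene_ids = sprintf("g%03d", 1:100)),
                       class = "factor_expression_profile")
  r <- rank_genes(prof100, 1)
  expect_equal(r$score, sort(sc, decreasing = TRUE))
  expect_equal(r$gene, prof100$gene_ids[order(-sc)])
})

test_that("enrichment score follows the weighted running sum exactly", {
  ranked <- tibble::tibble(gene = paste0("g", 1:5),
                           score = c(0.9, 0.5, 0.3, -0.2, -0.8))
  # hand-computed running sum for the set {g2, g5}, p = 1:
  # -1/3, -1/3 + 0.5/1.3, ..., extremum -8/13 just before the last hit
  r <- enrichment_score(ranked, c("g2", "g5"))
  expect_equal(r$es, -8 / 13)
  expect_equal(r$at_rank, 4L)
  expect_equal(r$leading_edge, 0.5)

  # the top-ranked singleton attains ES = 1 at rank 1
  top <- enrichment_score(ranked, "g1")
  expect_equal(top$es, 1)
  expect_equal(top$at_rank, 1L)
  expect_equal(top$leading_edge, 1)

  # the bottom-ranked singleton attains ES = -1 just before the hit
  bottom <- enrichment_score(ranked, "g5")
  expect_equal(bottom$es, -1)
  expect_equal(bottom$at_rank, 4L)
  expect_equal(bottom$leading_edge, 1)

  expect_error(enrichment_score(ranked, "absent"), "intersect")
})

test_that("enrichment score agrees with the fgsea reference on random rankings", {
  skip_if_not_installed("fgsea")
  set.seed(73)
  for (r in 1:20) {
    n <- sample(30:80, 1)
    stats_vec <- sort(stats::rnorm(n), decreasing = TRUE)
    names(stats_vec) <- sprintf("g%03d", seq_len(n))
    m <- sample(3:10, 1)
    set_genes <- sample(names(stats_vec), m)
    got <- enrichment_score(stats_vec, set_genes)
    want <- fgsea::calcGseaStat(stats_vec,
                                selectedStats = sort(match(set_genes, names(stats_vec))),
                                gseaParam = 1)
    expect_equal(got$es, want, tolerance = 1e-10)
    # reversing the ranking negates the score
    rev_stats <- rev(-stats_vec)
    got_rev <- enrichment_score(rev_stats, set_genes)
    expect_equal(got_rev$es, -got$es, tolerance = 1e-10)
  }
})

test_that("batch scorer matches the single-set scorer on shared rankings", {
  set.seed(74)
  n <- 200
  scores <- sort(stats::rnorm(n), decreasing = TRUE)
  names(scores) <- sprintf("g%03d", seq_len(n))
  sets <- lapply(1:15, function(i) sample(names(scores), sample(5:30, 1)))
  positions <- lapply(sets, function(g) sort(match(g, names(scores))))
  batch <- omicsfa:::.es_batch(unname(scores), positions, p = 1)
  single <- vapply(sets, function(g) enrichment_score(scores, g)$es, numeric(1))
  expect_equal(batch, single, tolerance = 1e-12)
})

test_that("tail genes outside every set shift ES only via the miss denominator", {
  set.seed(75)
  scores <- sort(stats::runif(40, 0.1, 1), decreasing = TRUE)
  names(scores) <- sprintf("g%02d", 1:40)
  set_genes <- names(scores)[c(3, 7, 12)]
  base <- enrichment_score(scores, set_genes)
  padded <- c(scores, stats::setNames(rep(0.01, 20), sprintf("x%02d", 1:20)))
  got <- enrichment_score(padded, set_genes)
  # brute-force recomputation with the enlarged list
  w <- abs(padded); hit <- names(padded) %in% set_genes
  inc <- ifelse(hit, w / sum(w[hit]), -1 / (length(padded) - 3))
  run <- cumsum(inc)
  expect_equal(got$es, run[which.max(abs(run))])
  expect_false(isTRUE(all.equal(got$es, base$es)))  # denominator did change
})

test_that("NES, permutation p and FDR follow the tail-ratio conventions", {
  # positive observed equal to the mean positive null has NES 1
  null1 <- array(c(0.2, 0.4, -0.1, -0.3), c(1, 1, 4))
  r1 <- nes_and_fdr(matrix(0.3, 1, 1), null1)
  expect_equal(r1$nes[1, 1], 1)

  # observed exceeding all (same-sign) nulls: add-one extreme p
  nulls <- array(seq(0.05, 0.50, length.out = 10), c(1, 1, 10))
  r2 <- nes_and_fdr(matrix(0.9, 1, 1), nulls)
  expect_equal(r2$p_value[1, 1], 1 / 11)

  # no same-sign nulls: flagged undefined
  r3 <- nes_and_fdr(matrix(-0.5, 1, 1), nulls)
  expect_true(r3$undefined[1, 1])

  # hand-computed pooled tail-ratio FDR on a 2-set table
  es <- matrix(c(0.6, 0.3), 2, 1)
  null2 <- array(c(0.2, 0.4, 0.1, 0.3), c(2, 1, 2))  # set1: {0.2, 0.1}; set2: {0.4, 0.3}
  r4 <- nes_and_fdr(es, null2)
  # NES: 0.6/0.15 = 4; 0.3/0.35 = 6/7
  expect_equal(as.vector(r4$nes), c(4, 6 / 7))
  # null NES pool: {4/3, 2/3, 8/7, 6/7}
  # q(4)   = mean(pool >= 4)  /mean(obs >= 4)   = 0 / 0.5  = 0
  # q(6/7) = mean(pool >= 6/7)/mean(obs >= 6/7) = 0.75 / 1 = 0.75
  expect_equal(as.vector(r4$fdr), c(0, 0.75))
})

test_that("the full enrichment pipeline finds planted signal and is reproducible", {
  set.seed(76)
  N <- 60; n_genes <- 300; k <- 2
  Z <- matrix(stats::rnorm(N * k), N, k)
  B <- matrix(0, k, n_genes)
  B[1, 1:20] <- stats::runif(20, 0.8, 1.2)     # factor 1 drives genes 1..20
  X <- Z %*% B + 0.5 * matrix(stats::rnorm(N * n_genes), N, n_genes)
  colnames(X) <- sprintf("g%04d", seq_len(n_genes))
  sets <- c(list(planted = colnames(X)[1:20]),
            lapply(stats::setNames(1:8, paste0("rand", 1:8)),
                   function(i) sample(colnames(X), 20)))
  res <- run_factor_gsea(X, Z, sets, n_perm = 100, seed = 5)
  top <- res[which.max(res$nes), ]
  expect_equal(top$set_name, "planted")
  expect_equal(top$factor, "factor_1")
  expect_lte(top$p_value, 1 / 51)  # at most 1 extreme same-sign null
  # a sharply enriched set concentrates all members in the leading edge,
  # so the report filter (leading edge < 0.5) excludes it by design
  expect_gt(top$leading_edge, 0.5)

  res2 <- run_factor_gsea(X, Z, sets, n_perm = 100, seed = 5)
  expect_identical(res, res2)
  expect_error(run_factor_gsea(X, Z, sets, n_perm = 0), "n_perm")
  expect_warning(empty <- run_factor_gsea(X, Z, list(), n_perm = 10),
                 "no usable gene sets")
  expect_equal(nrow(empty), 0L)
})
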