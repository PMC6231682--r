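# Fixture builders and independent oracles used across the suite.
# Oracles deliberately use a different computational route than the package
# (dense joint-Gaussian conditionals, naive loops, exhaustive scans).

rand_omics <- function(N, n, label = "a", weights = FALSE) {
  m <- matrix(stats::rnorm(N * n), N, n,
              dimnames = list(sprintf("s%03d", seq_len(N)),
                              sprintf("%s_f%03d", label, seq_len(n))))
  w <- if (weights) matrix(stats::runif(N * n, 0.5, 2), N, n) else NULL
  omics_matrix(m, label, w)
}

rand_dataset <- function(N, sizes) {
  blocks <- Map(function(lab, n) rand_omics(N, n, lab), names(sizes), sizes)
  assemble_dataset(unname(blocks))
}

# joint-Gaussian conditional for the factor model, by explicit dense inversion
e_step_oracle <- function(X, B, psi_vec) {
  N <- nrow(X); k <- nrow(B)
  Sigma <- t(B) %*% B + diag(psi_vec, ncol(X))
  EZ <- X %*% solve(Sigma) %*% t(B)
  Vc <- diag(k) - B %*% solve(Sigma) %*% t(B)
  list(mean = EZ, second_moment = N * Vc + crossprod(EZ))
}

# naive per-entry residual variance per data type
psi_oracle <- function(X, B, EZ, dt) {
  vapply(levels(dt), function(lv) {
    cols <- which(dt == lv)
    t1 <- 0; t2 <- 0
    for (j in cols) for (s in seq_len(nrow(X))) {
      t1 <- t1 + X[s, j]^2
      t2 <- t2 + sum(EZ[s, ] * B[, j]) * X[s, j]
    }
    max((t1 - t2) / (length(cols) * nrow(X)), 1e-8)
  }, numeric(1))
}

# Tibshirani-Taylor df by explicit dense hat-matrix traces, one active
# feature at a time with the single factor column as design
df_oracle <- function(B, Z, lambda2) {
  df <- 0
  for (i in seq_len(nrow(B))) {
    z <- Z[, i, drop = FALSE]
    for (j in which(B[i, ] != 0)) {
      hat <- z %*% solve(crossprod(z) + 2 * lambda2[j], t(z))
      df <- df + sum(diag(hat))
    }
  }
  df
}

# per-sample dense solve of the projection identity
projection_oracle <- function(X, B) {
  k <- nrow(B)
  out <- matrix(0, nrow(X), k)
  for (s in seq_len(nrow(X))) {
    out[s, ] <- solve(B %*% t(B) + diag(k), B %*% X[s, ])
  }
  out
}

# explained variance by naive recomputation of both residual norms
ev_oracle <- function(Xi, Bi, Z, j) {
  full <- sum((Xi - Z %*% Bi)^2)
  drop <- sum((Xi - Z[, -j, drop = FALSE] %*% Bi[-j, , drop = FALSE])^2)
  (drop - full) / sum(Xi^2)
}

# Mann-Whitney effect size by enumerating all pairs
mwu_oracle <- function(x, y) {
  wins <- 0
  for (a in x) for (b in y) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  wins / (length(x) * length(y))
}

# brute-force per-(sample, region) overlap scan over a segment table
cn_oracle <- function(seg, regions, samples) {
  out <- matrix(NA_real_, length(samples), nrow(regions))
  for (si in seq_along(samples)) for (ri in seq_len(nrow(regions))) {
    vals <- c()
    for (r in seq_len(nrow(seg))) {
      if (seg$sample_id[r] == samples[si] &&
          seg$chrom[r] == regions$chrom[ri] &&
          seg$start[r] <= regions$end[ri] &&
          seg$end[r] >= regions$start[ri]) {
        vals <- c(vals, seg$value[r])
      }
    }
    out[si, ri] <- stats::median(vals)
  }
  out
}

# centered + per-type pooled-SD-scaled dataset from a generated simulation
scaled_sim <- function(spec) {
  sim <- generate_multiomics(spec)
  sim$dataset <- scale_by_datatype_sd(sim$dataset)
  sim
}

# permutation aligning fitted factor rows to the truth, via match_factors
aligned_support <- function(fit, truth_Z, truth_B) {
  m <- match_factors(truth_Z, fit)
  perm <- match(m$factor_b, rownames(fit$model$B))
  list(B = fit$model$B[perm, , drop = FALSE], match = m)
}
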