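test_that("PCA initialization recovers rank structure and unit-variance scaling", {
  set.seed(41)
  # exact rank-1 data: the single coefficient row spans the true direction
  z <- stats::rnorm(30)
  b <- stats::rnorm(10)
  ds1 <- assemble_dataset(list(omics_matrix(outer(z, b), "a")))
  m1 <- init_pca(ds1, 1)
  cosang <- abs(sum(m1$B[1, ] * b)) / sqrt(sum(m1$B[1, ]^2) * sum(b^2))
  expect_gt(cosang, 1 - 1e-10)

  # k = 2 on random data: rows orthogonal, implied scores unit variance
  ds2 <- rand_dataset(40, c(a = 15))
  X <- dataset_matrix(ds2)
  X <- sweep(X, 2, colMeans(X))
  ds2 <- assemble_dataset(list(omics_matrix(X, "a")))
  m2 <- init_pca(ds2, 2)
  expect_lt(abs(sum(m2$B[1, ] * m2$B[2, ])), 1e-10)
  sv <- svd(X)
  # row j = d_j v_j / sqrt(N-1), up to sign
  for (j in 1:2) {
    expected <- sv$d[j] * sv$v[, j] / sqrt(nrow(X) - 1)
    expect_equal(abs(m2$B[j, ]), abs(expected), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }

  expect_error(init_pca(ds2, 100), "min")
  zero <- assemble_dataset(list(omics_matrix(matrix(0, 4, 3), "a")))
  expect_error(init_pca(zero, 1), "zero")
})

test_that("posterior moments match the dense joint-Gaussian oracle", {
  # closed form: B = I, psi = 1 gives raw E[Z|X] = X/2
  Xsq <- matrix(stats::rnorm(20), 5, 4)
  model <- structure(list(B = diag(4), psi = c(a = 1), k = 4,
                          penalties = NULL,
                          datatype_of_feature = factor(rep("a", 4))),
                     class = "sfa_model")
  post <- e_step(Xsq, model, rescale = FALSE)
  expect_equal(post$mean, Xsq / 2, ignore_attr = TRUE)

  # null model: raw moments collapse, rescaling is impossible
  model0 <- model
  model0$B <- matrix(0, 4, 4)
  post0 <- e_step(Xsq, model0, rescale = FALSE)
  expect_equal(post0$mean, matrix(0, 5, 4), ignore_attr = TRUE)
  expect_equal(post0$second_moment, 5 * diag(4))
  expect_error(e_step(Xsq, model0, rescale = TRUE), "zero-variance")

  # >= 20 random small instances vs explicit dense inversion
  set.seed(42)
  for (r in 1:25) {
    N <- sample(4:10, 1); n <- sample(2:10, 1); k <- sample(1:3, 1)
    X <- matrix(stats::rnorm(N * n), N, n)
    B <- matrix(stats::rnorm(k * n), k, n)
    psi <- stats::runif(1, 0.2, 2)
    m <- structure(list(B = B, psi = c(a = psi), k = k, penalties = NULL,
                        datatype_of_feature = factor(rep("a", n))),
                   class = "sfa_model")
    got <- e_step(X, m, rescale = FALSE)
    want <- e_step_oracle(X, B, rep(psi, n))
    expect_equal(got$mean, want$mean, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(got$second_moment, want$second_moment, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("rescaled factors have unit sample variance and conjugated moments", {
  set.seed(43)
  sim <- scaled_sim(synthetic_spec(50, 3, c(a = 20, b = 8), seed = 9))
  model <- init_pca(sim$dataset, 3)
  post <- e_step(sim$dataset, model)
  expect_equal(apply(post$mean, 2, stats::sd), rep(1, 3),
               tolerance = 1e-10, ignore_attr = TRUE)
  raw <- e_step(sim$dataset, model, rescale = FALSE)
  d <- post$scale_applied
  expect_equal(post$second_moment, raw$second_moment / outer(d, d))
  # second moment symmetric PSD
  expect_equal(post$second_moment, t(post$second_moment))
  expect_gte(min(eigen(post$second_moment, symmetric = TRUE)$values), -1e-8)
})

test_that("soft thresholding shrinks toward zero exactly", {
  expect_equal(soft_threshold(2, 0.5), 1.5)
  expect_equal(soft_threshold(-0.3, 0.5), 0)
  b <- stats::rnorm(20)
  expect_equal(soft_threshold(b, 0), b)
  expect_error(soft_threshold(1, -1))
})

test_that("coordinate update has the elastic-net fixed point", {
  set.seed(44)
  # orthonormal limit: lambda = 0 and M = N I makes the OLS value a fixed point
  N <- 20
  z <- stats::rnorm(N); x <- stats::rnorm(N)
  C <- matrix(sum(z * x), 1, 1)
  M <- matrix(N, 1, 1)
  b_ols <- sum(z * x) / N
  expect_equal(update_coefficient(matrix(b_ols, 1, 1), 1, 1, C, M, 0, 0, N),
               b_ols)
  # total shrinkage
  expect_equal(update_coefficient(matrix(0, 1, 1), 1, 1, C, M,
                                  abs(sum(z * x)) / N + 1, 0, N), 0)

  # iterated 1-d update converges to the fine-grid minimizer of its objective
  for (r in 1:20) {
    Cr <- matrix(stats::rnorm(1, sd = 2), 1, 1)
    Mr <- matrix(stats::runif(1, 0.7, 1.4) * N, 1, 1)
    l1 <- stats::runif(1, 0, 0.8); l2 <- stats::runif(1, 0, 0.5)
    b <- 0
    for (it in 1:500) b <- update_coefficient(matrix(b, 1, 1), 1, 1, Cr, Mr, l1, l2, N)
    grid <- seq(-4, 4, by = 1e-4)
    obj <- (Mr[1, 1] / (2 * N)) * grid^2 - (Cr[1, 1] / N) * grid +
      l1 * abs(grid) + (l2 / 2) * grid^2
    expect_lt(abs(b - grid[which.min(obj)]), 2e-4)
  }
})

test_that("a coordinate-descent sweep is exact when the factor design is orthonormal", {
  set.seed(45)
  k <- 3; n <- 7; N <- 25
  # with M = N I the sweep decouples: one pass lands on the global optimum
  C <- matrix(stats::rnorm(k * n), k, n)
  M <- N * diag(k)
  B0 <- matrix(stats::rnorm(k * n), k, n)
  l1 <- rep(0.2, n); l2 <- rep(0.1, n)
  B1 <- coordinate_descent_pass(B0, C, M, l1, l2, N)
  expect_equal(dim(B1), c(k, n))
  expect_true(all(is.finite(B1)))
  # closed-form separable optimum
  expect_equal(B1, soft_threshold(C / N, rep(l1, each = k)) /
                 (1 + rep(l2, each = k)))
  # a second pass does not move (fixed point), zero penalty from OLS likewise
  expect_equal(coordinate_descent_pass(B1, C, M, l1, l2, N), B1)
  B_ols <- C / N
  expect_equal(coordinate_descent_pass(B_ols, C, M, rep(0, n), rep(0, n), N),
               B_ols)
})

test_that("coordinate sweeps do not decrease the penalized surrogate they minimize", {
  # objective consistent with the update: quadratic in M and C, elastic net
  surrogate <- function(B, C, M, l1, l2, N) {
    -(sum(colSums(B * (M %*% B))) / (2 * N) - sum(B * C) / N +
        sum(l1 * colSums(abs(B))) + sum((l2 / 2) * colSums(B^2)))
  }
  set.seed(46)
  worst <- Inf
  for (r in 1:20) {
    N <- sample(30:60, 1); n <- sample(5:10, 1); k <- sample(1:3, 1)
    ds <- rand_dataset(N, stats::setNames(n, "a"))
    pc <- penalty_config(0.9, c(a = stats::runif(1, 0, 0.3)))
    model <- init_pca(ds, k, pc)
    model$B <- model$B + matrix(stats::rnorm(k * n, sd = 0.3), k, n)
    post <- e_step(ds, model)
    X <- dataset_matrix(ds)
    pen <- expand_penalties(pc, ds$datatype_of_feature)
    C <- crossprod(post$mean, X)
    g0 <- surrogate(model$B, C, post$second_moment, pen$lambda1, pen$lambda2, N)
    B1 <- coordinate_descent_pass(model$B, C, post$second_moment,
                                  pen$lambda1, pen$lambda2, N)
    g1 <- surrogate(B1, C, post$second_moment, pen$lambda1, pen$lambda2, N)
    worst <- min(worst, g1 - g0)
  }
  # at realistic N the rescaled second moment is near N I and sweeps ascend
  expect_gt(worst, -1e-8)
})

test_that("residual variance update matches the naive trace oracle", {
  set.seed(47)
  sim <- scaled_sim(synthetic_spec(20, 2, c(a = 6, b = 4), seed = 13))
  X <- dataset_matrix(sim$dataset)
  dt <- sim$dataset$datatype_of_feature
  model <- init_pca(sim$dataset, 2)
  post <- e_step(sim$dataset, model)
  got <- update_residual_variance(X, model, post, datatype_of_feature = dt)
  expect_equal(got, psi_oracle(X, model$B, post$mean, dt))

  # B = 0: psi is the mean squared entry per block
  model0 <- model; model0$B <- matrix(0, 2, ncol(X))
  got0 <- update_residual_variance(X, model0, post, datatype_of_feature = dt)
  expect_equal(unname(got0), c(mean(X[, dt == "a"]^2), mean(X[, dt == "b"]^2)))

  # noiseless exact fit floors at 1e-8
  Zt <- matrix(stats::rnorm(40), 20, 2)
  Bt <- matrix(stats::rnorm(2 * 10), 2, 10)
  modelx <- structure(list(B = Bt, psi = c(a = 1), k = 2, penalties = NULL,
                           datatype_of_feature = factor(rep("a", 10))),
                      class = "sfa_model")
  postx <- list(mean = Zt)
  expect_equal(unname(update_residual_variance(Zt %*% Bt, modelx, postx,
                                               factor(rep("a", 10)))), 1e-8)
})

test_that("reconstruction error and likelihood match naive evaluation", {
  set.seed(48)
  N <- 8; n <- 5; k <- 2
  X <- matrix(stats::rnorm(N * n), N, n)
  B <- matrix(stats::rnorm(k * n), k, n)
  EZ <- matrix(stats::rnorm(N * k), N, k)
  dt <- factor(rep("a", n))
  model <- structure(list(B = B, psi = c(a = 0.7), k = k,
                          penalties = penalty_config(0.9, c(a = 0.3)),
                          datatype_of_feature = dt),
                     class = "sfa_model")
  post <- list(mean = EZ)

  # loop oracle for the reconstruction error
  acc <- 0
  for (s in seq_len(N)) for (j in seq_len(n)) {
    acc <- acc + (X[s, j] - sum(EZ[s, ] * B[, j]))^2
  }
  expect_equal(reconstruction_error(X, model, post), acc / (N * n))
  expect_equal(reconstruction_error(EZ %*% B, model, list(mean = EZ)), 0)
  model0 <- model; model0$B <- matrix(0, k, n)
  expect_equal(reconstruction_error(X, model0, post), mean(X^2))

  # term-by-term likelihood oracle
  pen <- expand_penalties(model$penalties, dt)
  ll_oracle <- -0.5 * acc / 0.7 - (N / 2) * n * log(0.7) - 0.5 * sum(EZ^2) -
    sum(pen$lambda1 * colSums(abs(B))) - sum(pen$lambda2 * colSums(B^2))
  expect_equal(penalized_loglik(X, model, post), ll_oracle)

  # all terms but the residual vanish for B = 0, psi = 1, Z = 0
  model1 <- model0; model1$psi <- c(a = 1); model1$penalties <- NULL
  expect_equal(penalized_loglik(X, model1, list(mean = matrix(0, N, k))),
               -0.5 * sum(X^2))
  # zero penalties: penalized equals unpenalized
  model2 <- model; model2$penalties <- penalty_config(0.9, c(a = 0))
  # level 0 leaves only the 1e-6 ridge floor; penalty is O(1e-6 * ||B||^2)
  expect_equal(penalized_loglik(X, model2, post),
               penalized_loglik(X, model2, post, penalized = FALSE),
               tolerance = 1e-6)
})

test_that("EM fit recovers noiseless low-rank data and obeys the stopping rule", {
  set.seed(49)
  Zt <- matrix(stats::rnorm(80), 40, 2)
  Bt <- matrix(stats::rnorm(2 * 12), 2, 12)
  ds <- scale_by_datatype_sd(
    assemble_dataset(list(omics_matrix(Zt %*% Bt, "a"))))
  fit <- fit_sfa(ds, 2, penalty_config(0.9, c(a = 0)), max_iter = 200)
  ev <- explained_variance(ds, fit)
  expect_gte(ev$explained_variance[ev$factor == "all"], 0.99)

  # tol = Inf: stops as soon as the 10-change window exists
  fit_inf <- fit_sfa(ds, 2, penalty_config(0.9, c(a = 0)), tol = Inf)
  expect_equal(fit_inf$iterations, 11L)
  expect_true(fit_inf$converged)

  # determinism: identical runs produce identical results
  spec <- synthetic_spec(30, 2, c(a = 10, b = 6), seed = 17)
  s1 <- scaled_sim(spec); s2 <- scaled_sim(spec)
  f1 <- fit_sfa(s1$dataset, 2, penalty_config(0.9, c(a = 0.05, b = 0.05)), seed = 1)
  f2 <- fit_sfa(s2$dataset, 2, penalty_config(0.9, c(a = 0.05, b = 0.05)), seed = 1)
  expect_identical(f1$model$B, f2$model$B)
  expect_identical(f1$trace, f2$trace)
  expect_lte(nrow(f1$trace), 5000L)
})

test_that("broom and plotting surfaces describe a fit faithfully", {
  set.seed(50)
  sim <- scaled_sim(synthetic_spec(30, 2, c(a = 10, b = 4), seed = 23))
  fit <- fit_sfa(sim$dataset, 2, penalty_config(0.9, c(a = 0.05, b = 0.05)),
                 max_iter = 100)
  td <- tidy(fit)
  expect_equal(nrow(td), 2 * 14)
  expect_equal(sum(td$estimate != 0), glance(fit)$nonzero)
  gl <- glance(fit)
  expect_equal(gl$k, 2)
  expect_equal(gl$recon_error, fit$trace$recon_error[fit$iterations])
  ag <- augment(fit)
  expect_equal(nrow(ag), 30)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_explained_variance(explained_variance(sim$dataset, fit)),
                  "ggplot")
})
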