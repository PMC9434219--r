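# The seven models: closed-form agreement, objective conventions,
# reductions, sampler behavior, and the common predict contract.

test_that("ridge matches its closed form", {
  fit <- fit_ridge(diag(2), c(1, 2), lambda = 1,
                   intercept = FALSE, standardize = FALSE)
  expect_equal(unname(fit$B[, 1]), c(0.5, 1.0), tolerance = 1e-12)
  for (s in 1:10) {
    X <- withr::with_seed(s, matrix(rnorm(200), 20, 10))
    y <- withr::with_seed(100 + s, rnorm(20))
    lam <- withr::with_seed(200 + s, runif(1, 0.1, 10))
    b_hat <- fit_ridge(X, y, lam, intercept = FALSE,
                       standardize = FALSE)$B[, 1]
    b_ref <- solve(crossprod(X) + diag(lam, 10), crossprod(X, y))[, 1]
    expect_lt(max(abs(b_hat - b_ref)), 1e-8)
  }
})

test_that("ridge limits: no penalty gives OLS, huge penalty kills the fit", {
  X <- withr::with_seed(1, matrix(rnorm(300), 30, 10))
  y <- withr::with_seed(2, rnorm(30))
  b0 <- fit_ridge(X, y, 0, intercept = FALSE, standardize = FALSE)$B
  expect_equal(unname(b0[, 1]), unname(qr.solve(X, y)), tolerance = 1e-8)
  binf <- fit_ridge(X, y, 1e8, intercept = FALSE, standardize = FALSE)$B
  expect_lt(sqrt(sum(binf^2)), 1e-4)
})

test_that("mLASSO equals soft-thresholding on orthonormal designs and dies at lambda_max", {
  for (s in 1:5) {
    Q <- withr::with_seed(s, qr.Q(qr(matrix(rnorm(200), 20, 10))))
    y <- withr::with_seed(50 + s, rnorm(20))
    lam <- withr::with_seed(60 + s, runif(1, 0.2, 1.5))
    b <- fit_mlasso(Q, y, lam, intercept = FALSE, standardize = FALSE)$B[, 1]
    bols <- crossprod(Q, y)[, 1]
    expect_lt(max(abs(b - sign(bols) * pmax(abs(bols) - lam / 2, 0))), 1e-6)
  }
  # above the data-dependent maximum 2*max|X'y| the fit is exactly zero
  X <- withr::with_seed(3, matrix(rnorm(150), 15, 10))
  y <- withr::with_seed(4, rnorm(15))
  lmax <- 2 * max(abs(crossprod(X, y)))
  expect_true(all(fit_mlasso(X, y, lmax * 1.0001, intercept = FALSE,
                             standardize = FALSE)$B == 0))
  expect_false(all(fit_mlasso(X, y, lmax * 0.9, intercept = FALSE,
                              standardize = FALSE)$B == 0))
})

test_that("elastic net reduces to ridge, LASSO and OLS", {
  X <- withr::with_seed(5, matrix(rnorm(300), 30, 10))
  Y <- withr::with_seed(6, matrix(rnorm(60), 30, 2))
  en_r <- fit_elastic_net(X, Y, 2.5, 0, intercept = FALSE,
                          standardize = FALSE)$B
  ri <- fit_ridge(X, Y, 2.5, intercept = FALSE, standardize = FALSE)$B
  expect_lt(max(abs(en_r - ri)), 1e-8)
  en_l <- fit_elastic_net(X, Y, 0, 1.2, intercept = FALSE,
                          standardize = FALSE)$B
  la <- fit_mlasso(X, Y, 1.2, intercept = FALSE, standardize = FALSE)$B
  expect_lt(max(abs(en_l - la)), 1e-10)
  en_0 <- fit_elastic_net(X, Y, 0, 0, intercept = FALSE,
                          standardize = FALSE)$B
  ols <- qr.solve(X, Y)
  expect_lt(max(abs(en_0 - ols)), 1e-6)
})

test_that("elastic net agrees with glmnet under the convention mapping", {
  skip_if_not_installed("glmnet")
  X <- withr::with_seed(7, matrix(rnorm(50 * 30), 50, 30))
  y <- withr::with_seed(8, X[, 1] - 2 * X[, 5] + rnorm(50))
  n <- nrow(X)
  l1 <- 1.5; l2 <- 3 # unscaled objective penalties
  # glmnet scales the ridge part of its penalty by the population sd of
  # y (the L1 part is invariant to that internal rescaling), so the
  # unscaled-objective mapping is lambda*alpha = l2/(2n) and
  # lambda*(1-alpha) = l1*sd_pop(y)/n
  s_y <- sd(y) * sqrt((n - 1) / n)
  lam_g <- l2 / (2 * n) + l1 * s_y / n
  alpha_g <- (l2 / (2 * n)) / lam_g
  gfit <- glmnet::glmnet(X, y, alpha = alpha_g,
                         lambda = lam_g * c(16, 8, 4, 2, 1),
                         standardize = FALSE, intercept = TRUE,
                         thresh = 1e-14)
  b_ref <- as.numeric(coef(gfit, s = lam_g, exact = TRUE, x = X, y = y))[-1]
  b_hat <- fit_elastic_net(X, y, l1, l2, intercept = TRUE,
                           standardize = FALSE)$B[, 1]
  expect_lt(max(abs(b_hat - b_ref)), 1e-5)
})

test_that("GBLUP predictions equal marker ridge at lambda = sigma_e^2/sigma_u^2", {
  for (s in 1:10) {
    g <- rand_geno(20, 10, seed = 300 + s)
    y <- withr::with_seed(400 + s,
                          drop(scale(g[, 1:3]) %*% rep(1, 3)) + rnorm(20))
    fit <- fit_gblup(g, y)
    lam <- fit$sigma2_e / fit$sigma2_u
    Z <- sweep(g, 2, colMeans(g))
    b <- solve(crossprod(Z) + diag(lam, ncol(Z)),
               crossprod(Z, y - fit$mu))
    g_new <- rand_geno(8, 10, seed = 500 + s)
    pred_ridge <- fit$mu + sweep(g_new, 2, colMeans(g)) %*% b
    expect_lt(max(abs(predict(fit, g_new) - pred_ridge)), 1e-6)
  }
})

test_that("GBLUP degenerates gracefully", {
  g <- rand_geno(15, 8, seed = 9)
  fit <- fit_gblup(g, rep(3.3, 15))
  expect_equal(fit$sigma2_u, 0)
  expect_equal(unname(predict(fit, g)[, 1]), rep(3.3, 15))
  # a sample at the training centroid carries no relationship signal:
  # its prediction is the intercept
  fit2 <- fit_gblup(g, withr::with_seed(10, rnorm(15)))
  centroid <- matrix(colMeans(g), 1, dimnames = list("new", colnames(g)))
  expect_equal(unname(predict(fit2, centroid)[, 1]), fit2$mu,
               tolerance = 1e-8)
})

test_that("Bayesian LASSO is seeded, honest about null signal, and validates its chain", {
  X <- withr::with_seed(11, matrix(rnorm(100 * 20), 100, 20))
  X[, 7] <- 0
  y <- withr::with_seed(12, X[, 1] * 2 + rnorm(100, 0, 0.5))
  f1 <- fit_bayesian_lasso(X, y, n_iter = 800, burnin = 200, seed = 5)
  f2 <- fit_bayesian_lasso(X, y, n_iter = 800, burnin = 200, seed = 5)
  expect_identical(f1$B, f2$B)
  expect_lt(abs(f1$B[7, 1]), 0.05) # zero predictor column
  expect_gt(f1$B[1, 1], 1.5)
  expect_error(fit_bayesian_lasso(X, y, n_iter = 100, burnin = 200),
               "burn-in")
})

test_that("mBayesB recovers trait-specific sparsity and reduces to t=1", {
  n <- 120; p <- 40
  X <- withr::with_seed(13, matrix(rnorm(n * p), n, p))
  B <- matrix(0, p, 2)
  B[1:5, 1] <- withr::with_seed(14, rnorm(5, 0, 1.5))
  B[36:40, 2] <- withr::with_seed(15, rnorm(5, 0, 1.5))
  Y <- X %*% B + withr::with_seed(16, matrix(rnorm(n * 2, 0, 0.5), n, 2))
  fit <- fit_mbayesb(X, Y, mbayesb_config(n_iter = 1000, burnin = 250,
                                          seed = 3))
  inc <- fit$inclusion
  expect_gt(mean(inc[1:5, 1]), 2 * mean(inc[6:35, 1]))
  expect_gt(mean(inc[36:40, 2]), 2 * mean(inc[6:35, 2]))
  expect_gt(mean(inc[1:5, 1]), mean(inc[1:5, 2]))
  # single-trait reduction runs with scalar indicators
  f1 <- fit_mbayesb(X, Y[, 1], mbayesb_config(n_iter = 300, burnin = 100,
                                              seed = 4))
  expect_equal(dim(f1$B), c(p, 1L))
  expect_error(fit_mbayesb(X, Y, mbayesb_config(df = 0.5)), "df")
})

test_that("predict enforces the training column roster and the linear contract", {
  X <- withr::with_seed(17, matrix(rnorm(60), 20, 3,
                                   dimnames = list(NULL, c("a", "b", "c"))))
  y <- withr::with_seed(18, rnorm(20))
  fit <- fit_ridge(X, y, 1)
  expect_equal(predict(fit, X),
               X %*% fit$B + fit$intercept, ignore_attr = TRUE)
  Xbad <- X[, c(1, 3, 2)]
  expect_error(predict(fit, Xbad), "do not match")
  # a fully shrunk fit predicts its intercepts everywhere
  dead <- fit_mlasso(X, y, 1e9)
  expect_true(all(dead$B == 0))
  expect_equal(unname(predict(dead, X)[, 1]), rep(mean(y), 20))
})
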