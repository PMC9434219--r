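# The seven prediction models behind one common fit/predict contract.
# All penalized objectives use the unscaled convention
#   ||y - X b||^2 + lambda1 ||b||^2 + lambda2 ||b||_1,
# i.e. penalties are not divided by the sample size. Coefficients are
# always returned on the original predictor scale, with an explicit
# intercept, so predict() is simply intercept + X_new %*% B.

new_gs_fit <- function(method, B, intercept, hyper = list(),
                       extra = list(), subclass = character()) {
  structure(c(list(method = method, B = B, intercept = intercept,
                   hyper = hyper), extra),
            class = c(subclass, "gs_fit"))
}

#' @exportS3Method base::print
print.gs_fit <- function(x, ...) {
  cat(sprintf("<%s fit> %d predictors, %d response(s)\n", x$method,
              nrow(x$B), ncol(x$B)))
  if (length(x$hyper))
    cat("  hyper:", paste(names(x$hyper), unlist(x$hyper), sep = "=",
                          collapse = ", "), "\n")
  invisible(x)
}

# Shared preprocessing for the penalized fits: optional centering
# (intercept) and column standardization; fitting happens on the working
# scale and coefficients are mapped back.
prep_xy <- function(X, Y, intercept, standardize) {
  X <- as_design_matrix(X); Y <- as_response_matrix(Y)
  assert_that(nrow(X) == nrow(Y), "X and Y row counts differ")
  assert_that(all(is.finite(Y)), "response contains non-finite values")
  std <- standardize_columns(X, center = intercept || standardize,
                             scale = standardize)
  ymean <- if (intercept) colMeans(Y) else rep(0, ncol(Y))
  Yc <- sweep(Y, 2, ymean, "-")
  list(X = std$X, Y = Yc, center = std$center, scale = std$scale,
       ymean = ymean)
}

finish_fit <- function(method, pp, B_std, hyper, extra = list(),
                       subclass = character()) {
  B <- B_std / pp$scale
  intercept <- pp$ymean - drop(crossprod(pp$center, B))
  dimnames(B) <- list(names(pp$scale), names(pp$ymean))
  new_gs_fit(method, B, intercept, hyper, extra, subclass)
}

#' Ridge regression (closed form)
#'
#' Solves, per response column, `argmin ||y - Xb||^2 + lambda ||b||^2`
#' via the singular value decomposition (so a whole `lambda` path costs
#' one factorization).
#'
#' @param X samples x predictors design matrix.
#' @param Y response vector or samples x t matrix.
#' @param lambda ridge penalty (scalar, on the unscaled objective).
#' @param intercept fit an unpenalized intercept (default `TRUE`).
#' @param standardize center and unit-scale predictor columns before
#'   penalization (default `TRUE`); coefficients are returned on the
#'   original scale either way.
#' @return a `gs_fit` with coefficient matrix `B` (p x t), `intercept`,
#'   and the chosen `lambda`.
#' @export
#' @examples
#' fit <- fit_ridge(diag(2), c(1, 2), lambda = 1,
#'                  intercept = FALSE, standardize = FALSE)
#' fit$B # 0.5, 1.0
fit_ridge <- function(X, Y, lambda, intercept = TRUE, standardize = TRUE) {
  assert_that(length(lambda) == 1 && lambda >= 0, "lambda must be >= 0")
  pp <- prep_xy(X, Y, intercept, standardize)
  sv <- svd(pp$X)
  B_std <- ridge_from_svd(sv, pp$Y, lambda)
  finish_fit("RR", pp, B_std, list(lambda = lambda), subclass = "ridge_fit")
}

ridge_from_svd <- function(sv, Yc, lambda) {
  d <- sv$d
  keep <- d > max(d[1], 0) * 1e-12
  if (!any(keep)) return(matrix(0, nrow(sv$v), ncol(Yc)))
  f <- d[keep] / (d[keep]^2 + lambda)
  if (lambda == 0) f <- 1 / d[keep] # pseudo-inverse limit
  sv$v[, keep, drop = FALSE] %*% (f * crossprod(sv$u[, keep, drop = FALSE], Yc))
}

#' Multi-response LASSO
#'
#' Solves `argmin ||Y - XB||^2 + lambda ||B||_1` (elementwise L1; the
#' problem separates over response columns) by coordinate descent.
#' Under this unscaled convention the soft-threshold level is
#' `lambda / 2`, and `B` is exactly zero for
#' `lambda >= 2 * max|X'Y|`.
#'
#' @inheritParams fit_ridge
#' @param lambda L1 penalty.
#' @param max_iter,tol coordinate-descent controls.
#' @return a `gs_fit`.
#' @export
fit_mlasso <- function(X, Y, lambda, intercept = TRUE, standardize = TRUE,
                       max_iter = 1000, tol = 1e-10) {
  fit <- fit_elastic_net(X, Y, lambda1 = 0, lambda2 = lambda,
                         intercept = intercept, standardize = standardize,
                         max_iter = max_iter, tol = tol)
  fit$method <- "mLASSO"
  fit$hyper <- list(lambda = lambda)
  fit
}

#' Elastic net
#'
#' Solves `argmin ||y - Xb||^2 + lambda1 ||b||^2 + lambda2 ||b||_1`
#' (`lambda1` on the ridge term, `lambda2` on the lasso term) by
#' coordinate descent, per response column. `lambda2 = 0` reduces to
#' [fit_ridge()] and `lambda1 = 0` to [fit_mlasso()].
#'
#' @inheritParams fit_ridge
#' @param lambda1 ridge penalty.
#' @param lambda2 lasso penalty.
#' @param max_iter,tol coordinate-descent controls.
#' @param warm optional p x t warm-start coefficient matrix (working
#'   scale).
#' @return a `gs_fit`.
#' @export
fit_elastic_net <- function(X, Y, lambda1, lambda2,
                            intercept = TRUE, standardize = TRUE,
                            max_iter = 1000, tol = 1e-10, warm = NULL) {
  assert_that(lambda1 >= 0 && lambda2 >= 0, "penalties must be >= 0")
  pp <- prep_xy(X, Y, intercept, standardize)
  p <- ncol(pp$X); t <- ncol(pp$Y)
  B_std <- matrix(0, p, t)
  for (k in seq_len(t)) {
    b0 <- if (is.null(warm)) rep(0, p) else warm[, k]
    B_std[, k] <- enet_cd(pp$X, pp$Y[, k], lambda1, lambda2, b0,
                          max_iter, tol)
  }
  finish_fit("EN", pp, B_std, list(lambda1 = lambda1, lambda2 = lambda2),
             extra = list(B_working = B_std), subclass = "enet_fit")
}

# Path versions used by the inner cross-validation loop: one data
# preparation (and one SVD, or warm-started coordinate descent) serves
# the whole hyperparameter grid.
fit_ridge_path <- function(X, Y, lambdas, standardize = TRUE) {
  pp <- prep_xy(X, Y, intercept = TRUE, standardize = standardize)
  sv <- svd(pp$X)
  lapply(lambdas, function(l)
    finish_fit("RR", pp, ridge_from_svd(sv, pp$Y, l), list(lambda = l),
               subclass = "ridge_fit"))
}

fit_enet_path <- function(X, Y, grid, standardize = TRUE,
                          max_iter = 250, tol = 1e-7, method_id = "EN") {
  pp <- prep_xy(X, Y, intercept = TRUE, standardize = standardize)
  p <- ncol(pp$X); t <- ncol(pp$Y)
  # process large penalties first so each solution warm-starts the next
  ord <- order(vapply(grid, function(h)
    (h$lambda1 %||% 0) + (h$lambda2 %||% h$lambda), numeric(1)),
    decreasing = TRUE)
  warm <- matrix(0, p, t)
  fits <- vector("list", length(grid))
  for (i in ord) {
    h <- grid[[i]]
    l1 <- h$lambda1 %||% 0
    l2 <- h$lambda2 %||% h$lambda
    B_std <- matrix(0, p, t)
    for (k in seq_len(t))
      B_std[, k] <- enet_cd(pp$X, pp$Y[, k], l1, l2, warm[, k],
                            max_iter, tol)
    warm <- B_std
    fits[[i]] <- finish_fit(method_id, pp, B_std, h,
                            extra = list(B_working = B_std),
                            subclass = "enet_fit")
  }
  fits
}

#' Genomic BLUP via REML on the realized relationship matrix
#'
#' Fits the mixed model `y = 1 mu + Z u + e` with `var(Zu) = K sigma_u^2`,
#' `K = Z Z'` the realized genomic relationship matrix built from the
#' column-centered marker matrix `Z`, and `var(e) = I sigma_e^2`.
#' Variance components are estimated by restricted maximum likelihood on
#' the eigendecomposition of `K`; unseen samples are predicted through
#' the cross-relationship block `K(test, train)`.
#'
#' @param g_train training samples x markers matrix (QC'd, imputed).
#' @param y single response vector.
#' @param scale_k divide `K` by the marker count (default `FALSE`,
#'   matching the plain `K = ZZ'` definition; the variance-component
#'   ratio, and hence all predictions, are invariant to this scaling).
#' @param ridge_eps diagonal ridge added to `K` for numerical stability
#'   (default 1e-8).
#' @return object of class `gblup_fit` with variance components
#'   `sigma2_u`, `sigma2_e`, BLUPs `u` for the training samples, the
#'   intercept `mu`, and what [predict()] needs for new samples.
#' @export
fit_gblup <- function(g_train, y, scale_k = FALSE, ridge_eps = 1e-8) {
  Z0 <- as_design_matrix(g_train)
  y <- as.numeric(y)
  n <- nrow(Z0)
  assert_that(length(y) == n, "y length must match rows of g_train")
  assert_that(all(is.finite(y)), "response contains non-finite values")
  ctr <- colMeans(Z0)
  Z <- sweep(Z0, 2, ctr, "-")
  K <- tcrossprod(Z)
  if (scale_k) K <- K / ncol(Z)
  K <- K + diag(ridge_eps, n)

  if (var(y) == 0) {
    fit <- structure(list(method = "GBLUP", mu = y[1], c = rep(0, n),
                          u = rep(0, n), sigma2_u = 0, sigma2_e = 0,
                          Z_train = Z, center = ctr, scale_k = scale_k,
                          K = K),
                     class = c("gblup_fit"))
    return(fit)
  }

  # REML for the variance ratio delta = sigma2_e / sigma2_u on the
  # spectrum of the intercept-projected relationship matrix.
  one <- rep(1, n)
  Pm <- diag(n) - tcrossprod(one) / n
  es <- eigen(Pm %*% K %*% Pm, symmetric = TRUE)
  xi <- es$values[seq_len(n - 1)]
  xi[xi < 1e-10] <- 1e-10
  eta <- crossprod(es$vectors[, seq_len(n - 1), drop = FALSE], y)
  negloglik <- function(log_delta) {
    delta <- exp(log_delta)
    ss <- sum(eta^2 / (xi + delta))
    0.5 * ((n - 1) * log(ss) + sum(log(xi + delta)))
  }
  opt <- optimize(negloglik, c(log(1e-8), log(1e8)))
  delta <- exp(opt$minimum)
  sigma2_u <- sum(eta^2 / (xi + delta)) / (n - 1)
  sigma2_e <- delta * sigma2_u

  ev <- eigen(K, symmetric = TRUE)
  dvals <- pmax(ev$values, 0)
  vinv_apply <- function(v) # (K + delta I)^{-1} v
    ev$vectors %*% (crossprod(ev$vectors, v) / (dvals + delta))
  mu <- drop(crossprod(one, vinv_apply(y)) / crossprod(one, vinv_apply(one)))
  cvec <- drop(vinv_apply(y - mu * one))
  u <- drop(K %*% cvec)

  structure(list(method = "GBLUP", mu = mu, c = cvec, u = u,
                 sigma2_u = sigma2_u, sigma2_e = sigma2_e,
                 Z_train = Z, center = ctr, scale_k = scale_k, K = K),
            class = "gblup_fit")
}

#' @exportS3Method base::print
print.gblup_fit <- function(x, ...) {
  cat(sprintf("<GBLUP fit> n=%d, sigma2_u=%.4g, sigma2_e=%.4g\n",
              length(x$u), x$sigma2_u, x$sigma2_e))
  invisible(x)
}

#' Bayesian LASSO via Gibbs sampling
#'
#' Whole-genome regression with independent double-exponential (Laplace)
#' priors on the marker effects, fitted by the normal-exponential
#' scale-mixture Gibbs sampler: conjugate updates for the coefficients,
#' per-coefficient mixing variances (inverse-Gaussian), the residual
#' variance (scaled inverse chi-squared), and the squared regularization
#' parameter (gamma hyperprior). Returns posterior-mean coefficients.
#'
#' @inheritParams fit_ridge
#' @param y single response vector.
#' @param n_iter chain length (default 20000).
#' @param burnin burn-in iterations discarded (default 5000; the chain
#'   must be longer than the burn-in).
#' @param r_hyper,delta_hyper gamma hyperprior (shape, rate) on the
#'   squared regularization parameter (defaults 1, 1).
#' @param seed optional seed applied just for the chain.
#' @return a `gs_fit` carrying posterior means (`B`, `intercept`,
#'   `sigma2`, `lambda2`) and the chain settings.
#' @export
fit_bayesian_lasso <- function(X, y, n_iter = 20000, burnin = 5000,
                               r_hyper = 1, delta_hyper = 1,
                               intercept = TRUE, standardize = TRUE,
                               seed = NULL) {
  assert_that(n_iter > burnin, "chain length must exceed burn-in")
  pp <- prep_xy(X, y, intercept, standardize)
  res <- with_seed(seed, bl_gibbs(pp$X, pp$Y[, 1], n_iter, burnin,
                                  r_hyper, delta_hyper))
  B_std <- matrix(res$b, ncol = 1)
  fit <- finish_fit("BL", pp, B_std, list(n_iter = n_iter, burnin = burnin),
                    extra = list(sigma2 = res$sigma2, lambda2 = res$lambda2),
                    subclass = "bl_fit")
  # the sampled intercept absorbs the centering used during fitting
  fit$intercept <- fit$intercept + res$mu
  fit
}

#' Configuration for the multi-trait BayesB sampler
#'
#' @param pi_incl prior inclusion probability per (locus, trait)
#'   indicator, in (0, 1\] (default 0.05).
#' @param df inverse-Wishart degrees of freedom for the locus-specific
#'   effect covariance; must exceed `t - 1` (default `t + 4`).
#' @param scale inverse-Wishart scale, as a scalar multiplying the
#'   identity (default 0.1).
#' @param n_iter,burnin chain settings (defaults 2000 / 500).
#' @param df_r,scale_r inverse-Wishart prior on the residual covariance
#'   (defaults `t + 4` and 1).
#' @param seed optional chain seed.
#' @return list of class `mbayesb_config`.
#' @export
mbayesb_config <- function(pi_incl = 0.05, df = NULL, scale = 0.1,
                           n_iter = 2000, burnin = 500,
                           df_r = NULL, scale_r = 1, seed = NULL) {
  assert_that(pi_incl > 0 && pi_incl <= 1, "pi_incl must be in (0, 1]")
  assert_that(n_iter > burnin, "chain length must exceed burn-in")
  structure(list(pi_incl = pi_incl, df = df, scale = scale,
                 n_iter = n_iter, burnin = burnin, df_r = df_r,
                 scale_r = scale_r, seed = seed),
            class = "mbayesb_config")
}

#' Multi-trait BayesB via Gibbs sampling
#'
#' Variable-selection regression in which each locus carries one
#' inclusion indicator per trait (so any of the `2^t` sparsity patterns
#' is admissible), effect vectors are multivariate normal with a
#' locus-specific covariance under an inverse-Wishart prior, and the
#' residual covariance is sampled from its inverse-Wishart full
#' conditional. Indicators and effects are updated jointly per (locus,
#' trait) with the effect integrated out of the inclusion odds.
#'
#' @inheritParams fit_ridge
#' @param config an [mbayesb_config()].
#' @return a `gs_fit` with posterior-mean `B`, `intercept`, per-locus
#'   per-trait `inclusion` frequencies, and posterior-mean residual
#'   covariance `R`.
#' @export
fit_mbayesb <- function(X, Y, config = mbayesb_config(),
                        intercept = TRUE, standardize = TRUE) {
  stopifnot(inherits(config, "mbayesb_config"))
  pp <- prep_xy(X, Y, intercept, standardize)
  t <- ncol(pp$Y)
  df <- config$df %||% (t + 4)
  df_r <- config$df_r %||% (t + 4)
  assert_that(df > t - 1, "inverse-Wishart df must exceed t - 1")
  res <- with_seed(config$seed,
    mbayesb_gibbs(pp$X, pp$Y, config$n_iter, config$burnin,
                  config$pi_incl, df, diag(config$scale, t),
                  df_r, diag(config$scale_r, t)))
  fit <- finish_fit("mBayesB", pp, res$B,
                    list(n_iter = config$n_iter, burnin = config$burnin,
                         pi_incl = config$pi_incl, df = df),
                    extra = list(inclusion = res$inclusion, R = res$R),
                    subclass = "mbayesb_fit")
  fit$intercept <- fit$intercept + drop(res$mu)
  fit
}

#' Predict from a fitted prediction model
#'
#' Deterministic linear prediction `intercept + X_new %*% B`. The column
#' roster of `X_new` must match the training design; a mismatch is
#' rejected with a name diff.
#'
#' @param object a `gs_fit`.
#' @param newdata samples x predictors matrix.
#' @param ... unused.
#' @return n_new x t matrix of predictions.
#' @export
predict.gs_fit <- function(object, newdata, ...) {
  X <- as_design_matrix(newdata)
  check_roster(colnames(X), rownames(object$B))
  out <- sweep(X %*% object$B, 2, object$intercept, "+")
  rownames(out) <- rownames(newdata)
  out
}

check_roster <- function(have, want) {
  if (is.null(want) || is.null(have)) return(invisible(TRUE))
  if (!identical(have, want)) {
    missing <- setdiff(want, have)
    extra <- setdiff(have, want)
    stop("predictor columns do not match the training design",
         if (length(missing)) paste0("; missing: ",
                                     paste(head(missing, 5), collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ",
                                   paste(head(extra, 5), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname predict.gs_fit
#' @param g_new new samples x markers matrix (GBLUP prediction goes
#'   through the cross-relationship block `K(new, train)`).
#' @export
predict.gblup_fit <- function(object, g_new, ...) {
  Znew <- sweep(as_design_matrix(g_new), 2, object$center, "-")
  check_roster(colnames(Znew), colnames(object$Z_train))
  Kc <- tcrossprod(Znew, object$Z_train)
  if (object$scale_k) Kc <- Kc / ncol(Znew)
  out <- matrix(object$mu + drop(Kc %*% object$c), ncol = 1)
  rownames(out) <- rownames(g_new)
  out
}
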