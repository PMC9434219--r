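# L2,1-regularized multivariate regression with joint sparse
# precision-matrix estimation, fitted by alternating minimization:
#   (i) B-step: proximal-gradient (FISTA with monotone backtracking) on
#       the row-sparse weighted least-squares problem;
#   (ii) Omega-step: proximal gradient (G-ISTA) on the L1-penalized
#       log-determinant problem over the residual scatter.
# The objective is
#   J(B, Omega) = (1/s) tr[(Y - XB) Omega (Y - XB)'] - log|Omega|
#                 + lambda1 ||Omega||_1 + lambda2 sum_j ||B_j.||_2
# with s the training sample count.

# log|Omega| via Cholesky; -Inf (i.e. infeasible) when Omega is not PD.
logdet_pd <- function(Omega) {
  ch <- tryCatch(chol(Omega), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  2 * sum(log(diag(ch)))
}

l21_objective <- function(X, Y, B, Omega, s, lambda1, lambda2) {
  ld <- logdet_pd(Omega)
  if (!is.finite(ld)) return(Inf)
  E <- Y - X %*% B
  sum((E %*% Omega) * E) / s - ld +
    lambda1 * sum(abs(Omega)) +
    lambda2 * sum(sqrt(rowSums(B^2)))
}

row_group_prox <- function(B, level) {
  nr <- sqrt(rowSums(B^2))
  shrink <- pmax(0, 1 - level / pmax(nr, 1e-300))
  B * shrink
}

# FISTA on the B subproblem with a monotone safeguard. The gradient is
# formed as X'((XB - Y) Omega), linear in p, so wide marker matrices
# never require the p x p Gram matrix.
l21_b_step <- function(X, Y, B, Omega, s, lambda2, lip_x,
                       inner_iter, inner_tol) {
  if (lambda2 == 0) { # exact minimizer; Omega drops out of the argmin
    sv <- svd(X)
    keep <- sv$d > max(sv$d[1], 0) * 1e-12
    B <- sv$v[, keep, drop = FALSE] %*%
      (crossprod(sv$u[, keep, drop = FALSE], Y) / sv$d[keep])
    return(B)
  }
  lip_o <- max(abs(eigen(Omega, symmetric = TRUE, only.values = TRUE)$values))
  step <- 1 / ((2 / s) * lip_x * lip_o + 1e-12)
  smooth <- function(B) {
    E <- Y - X %*% B
    sum((E %*% Omega) * E) / s
  }
  fobj <- function(B) smooth(B) + lambda2 * sum(sqrt(rowSums(B^2)))
  f_cur <- fobj(B)
  Bm <- B; tk <- 1
  for (i in seq_len(inner_iter)) {
    G <- (2 / s) * crossprod(X, (X %*% Bm - Y) %*% Omega)
    repeat {
      B_new <- row_group_prox(Bm - step * G, step * lambda2)
      f_new <- fobj(B_new)
      if (f_new <= f_cur + 1e-12 || step < 1e-14) break
      step <- step / 2
    }
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Bm <- B_new + ((tk - 1) / t_new) * (B_new - B)
    tk <- t_new
    conv <- abs(f_cur - f_new) <= inner_tol * (abs(f_cur) + 1)
    B <- B_new; f_cur <- f_new
    if (conv) break
  }
  B
}

# Largest eigenvalue of X'X, computed on whichever Gram matrix is
# smaller (X'X or XX' share their nonzero spectrum).
design_spectral_norm <- function(X) {
  G <- if (nrow(X) <= ncol(X)) tcrossprod(X) else crossprod(X)
  max(eigen(G, symmetric = TRUE, only.values = TRUE)$values, 0)
}

# G-ISTA for min_Omega tr(S Omega) - log|Omega| + lambda1 ||Omega||_1.
penalized_precision <- function(S, lambda1, Omega = NULL,
                                max_iter = 200, tol = 1e-10) {
  t <- ncol(S)
  # ridge a non-PD scatter before the precision step (documented epsilon)
  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-8) S <- S + diag(1e-8 - ev_min + 1e-10, t)
  if (is.null(Omega)) Omega <- diag(1 / diag(S))
  fobj <- function(O) {
    ld <- logdet_pd(O)
    if (!is.finite(ld)) return(Inf)
    sum(S * O) - ld + lambda1 * sum(abs(O))
  }
  f_cur <- fobj(Omega)
  step <- min(eigen(Omega, symmetric = TRUE, only.values = TRUE)$values)^2
  for (i in seq_len(max_iter)) {
    G <- S - chol2inv(chol(Omega))
    repeat {
      O_new <- Omega - step * G
      O_new <- sign(O_new) * pmax(abs(O_new) - step * lambda1, 0)
      O_new <- (O_new + t(O_new)) / 2
      f_new <- fobj(O_new)
      if (is.finite(f_new) && f_new <= f_cur + 1e-12) break
      step <- step / 2
      if (step < 1e-16) { O_new <- Omega; f_new <- f_cur; break }
    }
    conv <- abs(f_cur - f_new) <= tol * (abs(f_cur) + 1)
    Omega <- O_new; f_cur <- f_new
    if (conv) break
    step <- step * 2
  }
  Omega
}

#' L2,1-joint multivariate regression with sparse precision estimation
#'
#' Jointly estimates a row-sparse coefficient matrix `B` (the L2,1
#' penalty selects predictors shared across all responses) and a sparse
#' residual precision matrix `Omega` by alternating minimization; at
#' each round the current `Omega` re-weights the residuals used to
#' refine `B`, until the joint objective converges. See the package
#' vignette for the objective and conventions (`s` is the training
#' sample count; `lambda1` penalizes all entries of `Omega`).
#'
#' @inheritParams fit_ridge
#' @param Y samples x t response matrix, t >= 2.
#' @param lambda1 L1 penalty on the precision matrix (>= 0).
#' @param lambda2 L2,1 (row) penalty on the coefficients (>= 0).
#' @param tol relative objective-decrease tolerance for the outer loop
#'   (default 1e-6).
#' @param max_iter maximum outer iterations (default 500).
#' @param inner_iter,inner_tol controls for the B and Omega subproblem
#'   solvers.
#' @param fix_omega optional fixed precision matrix; if supplied the
#'   Omega-step is skipped (with `fix_omega = diag(t)` and zero
#'   penalties the fit reduces to per-response least squares).
#' @return a `gs_fit` with `B`, `intercept`, the estimated precision
#'   matrix `Omega`, the per-iteration `objective` trace, and
#'   convergence diagnostics.
#' @export
fit_l21_joint <- function(X, Y, lambda1, lambda2, tol = 1e-6,
                          max_iter = 500, inner_iter = 100,
                          inner_tol = 1e-9,
                          intercept = TRUE, standardize = TRUE,
                          fix_omega = NULL) {
  assert_that(lambda1 >= 0 && lambda2 >= 0, "penalties must be >= 0")
  Y0 <- as_response_matrix(Y)
  assert_that(ncol(Y0) >= 2, "L21-joint requires at least two responses")
  pp <- prep_xy(X, Y0, intercept, standardize)
  Xs <- pp$X; Yc <- pp$Y
  s <- nrow(Xs)
  t <- ncol(Yc)
  lip_x <- design_spectral_norm(Xs)

  B <- matrix(0, ncol(Xs), t)
  Omega <- fix_omega %||% diag(t)
  obj <- l21_objective(Xs, Yc, B, Omega, s, lambda1, lambda2)
  trace <- obj
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    B <- l21_b_step(Xs, Yc, B, Omega, s, lambda2, lip_x,
                    inner_iter, inner_tol)
    if (is.null(fix_omega)) {
      E <- Yc - Xs %*% B
      S_res <- crossprod(E) / s
      Omega <- penalized_precision(S_res, lambda1, Omega)
    }
    obj_new <- l21_objective(Xs, Yc, B, Omega, s, lambda1, lambda2)
    trace <- c(trace, obj_new)
    if (abs(obj - obj_new) <= tol * (abs(obj) + 1)) {
      converged <- TRUE
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  finish_fit("L21-joint", pp, B,
             list(lambda1 = lambda1, lambda2 = lambda2),
             extra = list(Omega = Omega, objective = trace,
                          iterations = length(trace) - 1,
                          converged = converged),
             subclass = "l21_fit")
}
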