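# Cross-validation machinery, the method roster, predictability scoring,
# and the evaluation drivers for the four settings.

#' Cross-validation scheme
#'
#' @param K number of folds (default 3).
#' @param repetitions number of repeated random partitions (default 20).
#' @param nested use an inner 3-fold loop on the training data to select
#'   hyperparameters (default `TRUE`; methods without hyperparameters
#'   skip the inner loop either way).
#' @param inner_K folds of the inner loop (default 3).
#' @param seed base seed; every partition and every stochastic fit is
#'   derived deterministically from it.
#' @return object of class `cv_scheme`.
#' @export
cv_scheme <- function(K = 3, repetitions = 20, nested = TRUE,
                      inner_K = 3, seed = 1L) {
  assert_that(K >= 2, "K must be at least 2")
  assert_that(repetitions >= 1, "repetitions must be at least 1")
  structure(list(K = as.integer(K), repetitions = as.integer(repetitions),
                 nested = isTRUE(nested), inner_K = as.integer(inner_K),
                 seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Partition sample ids into K folds
#'
#' Random folds of approximately equal size (sizes differ by at most
#' one; e.g. 74 samples in 3 folds gives sizes 25, 25, 24). The
#' partition is deterministic given `(scheme$seed, repetition)`.
#'
#' @param ids character vector of sample ids.
#' @param scheme a [cv_scheme()].
#' @param repetition repetition index (default 1).
#' @return list of K disjoint id vectors covering `ids`.
#' @export
kfold_partition <- function(ids, scheme, repetition = 1) {
  n <- length(ids)
  K <- scheme$K
  assert_that(n >= K, "need at least K samples")
  perm <- with_seed(derive_seed(scheme$seed, repetition), sample(ids))
  sizes <- rep(n %/% K, K)
  extra <- n %% K
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  split(perm, rep(seq_len(K), times = sizes))
}

#' Predictability: Pearson correlation with the zero-variance NA rule
#'
#' The model-performance metric: Pearson correlation between observed
#' and predicted trait values in a validation set. Returns `NA` when
#' either vector has zero standard deviation (e.g. an all-zero
#' coefficient LASSO fit predicting a constant), mirroring the NA
#' reporting convention for such fits.
#'
#' @param observed,predicted numeric vectors of equal length (>= 3).
#' @return correlation in \[-1,1\], or `NA`.
#' @export
predictability <- function(observed, predicted) {
  assert_that(length(observed) == length(predicted),
              "observed and predicted lengths differ")
  assert_that(length(observed) >= 3, "need at least 3 pairs")
  if (sd(observed) == 0 || sd(predicted) == 0) return(NA_real_)
  cor(observed, predicted)
}

# ---------------------------------------------------------------------
# Method roster

#' The seven-method roster
#'
#' @return character vector of method ids.
#' @export
method_roster <- function() {
  c("RR", "mLASSO", "EN", "GBLUP", "BL", "mBayesB", "L21-joint")
}

log_grid <- function(lmax, n, span = 1e-4) {
  lmax <- max(lmax, 1e-8)
  exp(seq(log(span * lmax), log(lmax), length.out = n))
}

#' Construct a prediction method for the evaluation drivers
#'
#' Wraps one of the seven models behind a uniform interface: a
#' hyperparameter grid builder (empty for the Bayesian methods and
#' GBLUP, whose settings are fixed by `opts`) and a fit function
#' returning an object with a [predict()] method. Hyperparameter grids
#' default to 20 logarithmically spaced penalties spanning
#' `[1e-4 lmax, lmax]` with `lmax` the data-derived level at which the
#' L1 solution is exactly zero (used as a scale reference for the ridge
#' grid too); the elastic net crosses that grid with 5 mixing levels.
#'
#' @param id one of [method_roster()].
#' @param opts named list of options: `standardize` (default `TRUE`),
#'   `n_lambda` (20), `en_mix` (5 mixing levels), `bl_iter`/`bl_burnin`
#'   (20000/5000), `mbayesb` (an [mbayesb_config()]),
#'   `l21_lambda1` (grid for the precision penalty, default
#'   `c(0.01, 0.1)`), `l21_n_lambda2` (5), `l21_max_iter` (30),
#'   `l21_inner_iter` (50).
#' @return object of class `gs_method`.
#' @export
gs_method <- function(id, opts = list()) {
  id <- match.arg(id, method_roster())
  o <- modifyList(list(standardize = TRUE, n_lambda = 20,
                       en_mix = c(0.1, 0.3, 0.5, 0.7, 0.9),
                       bl_iter = 20000, bl_burnin = 5000,
                       mbayesb = NULL,
                       l21_lambda1 = c(0.01, 0.1), l21_n_lambda2 = 5,
                       l21_max_iter = 30, l21_inner_iter = 50,
                       l21_tol = 1e-5),
                  opts)
  lmax_l1 <- function(X, Y) {
    pp <- prep_xy(X, Y, intercept = TRUE, standardize = o$standardize)
    2 * max(abs(crossprod(pp$X, pp$Y)))
  }
  spec <- switch(id,
    "RR" = list(
      grid = function(X, Y) lapply(log_grid(lmax_l1(X, Y), o$n_lambda),
                                   function(l) list(lambda = l)),
      fit = function(X, Y, hyper)
        fit_ridge(X, Y, hyper$lambda, standardize = o$standardize),
      fit_path = function(X, Y, grid)
        fit_ridge_path(X, Y, vapply(grid, `[[`, numeric(1), "lambda"),
                       standardize = o$standardize)),
    "mLASSO" = list(
      grid = function(X, Y) lapply(log_grid(lmax_l1(X, Y), o$n_lambda),
                                   function(l) list(lambda = l)),
      fit = function(X, Y, hyper)
        fit_mlasso(X, Y, hyper$lambda, standardize = o$standardize),
      fit_path = function(X, Y, grid)
        fit_enet_path(X, Y, grid, standardize = o$standardize,
                      method_id = "mLASSO")),
    "EN" = list(
      grid = function(X, Y) {
        lams <- log_grid(lmax_l1(X, Y), o$n_lambda)
        out <- list()
        for (a in o$en_mix) for (l in lams)
          out[[length(out) + 1]] <- list(lambda1 = (1 - a) * l,
                                         lambda2 = a * l)
        out
      },
      fit = function(X, Y, hyper)
        fit_elastic_net(X, Y, hyper$lambda1, hyper$lambda2,
                        standardize = o$standardize),
      fit_path = function(X, Y, grid)
        fit_enet_path(X, Y, grid, standardize = o$standardize)),
    "GBLUP" = list(
      grid = function(X, Y) list(),
      fit = function(X, Y, hyper) fit_percolumn(X, Y, fit_gblup)),
    "BL" = list(
      grid = function(X, Y) list(),
      fit = function(X, Y, hyper)
        fit_percolumn(X, Y, function(X, y)
          fit_bayesian_lasso(X, y, n_iter = o$bl_iter,
                             burnin = o$bl_burnin,
                             standardize = o$standardize))),
    "mBayesB" = list(
      grid = function(X, Y) list(),
      fit = function(X, Y, hyper)
        fit_mbayesb(X, Y, config = o$mbayesb %||% mbayesb_config(),
                    standardize = o$standardize)),
    "L21-joint" = list(
      grid = function(X, Y) {
        pp <- prep_xy(X, Y, intercept = TRUE, standardize = o$standardize)
        lmax <- 2 * max(sqrt(rowSums(crossprod(pp$X, pp$Y)^2))) / nrow(pp$X)
        out <- list()
        for (l1 in o$l21_lambda1)
          for (l2 in log_grid(lmax, o$l21_n_lambda2, span = 1e-2))
            out[[length(out) + 1]] <- list(lambda1 = l1, lambda2 = l2)
        out
      },
      fit = function(X, Y, hyper)
        fit_l21_joint(X, Y, hyper$lambda1, hyper$lambda2,
                      tol = o$l21_tol, max_iter = o$l21_max_iter,
                      inner_iter = o$l21_inner_iter,
                      standardize = o$standardize))
  )
  structure(list(id = id, opts = o, grid = spec$grid, fit = spec$fit,
                 fit_path = spec$fit_path,
                 sources = if (id == "GBLUP") "snp" else c("snp", "chlf")),
            class = "gs_method")
}

# Fit a single-response model to each response column; predictions are
# column-bound.
fit_percolumn <- function(X, Y, fitter) {
  Y <- as_response_matrix(Y)
  fits <- lapply(seq_len(ncol(Y)), function(k) fitter(X, Y[, k]))
  structure(list(fits = fits, responses = colnames(Y)),
            class = "percolumn_fit")
}

#' @export
predict.percolumn_fit <- function(object, newdata, ...) {
  out <- do.call(cbind, lapply(object$fits, function(f)
    predict(f, newdata)))
  colnames(out) <- object$responses
  out
}

check_method_source <- function(method, source) {
  if (!source %in% method$sources)
    stop(sprintf("method %s is not applicable to %s predictors",
                 method$id, source), call. = FALSE)
}

# Mean validation predictability across response columns for one
# train/validation split; NA columns are dropped, all-NA gives NA.
split_score <- function(fit, X_val, Y_val) {
  pred <- predict(fit, X_val)
  vals <- vapply(seq_len(ncol(Y_val)), function(k)
    predictability(Y_val[, k], pred[, k]), numeric(1))
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

select_hyper <- function(method, X, Y, scheme, stream) {
  grid <- method$grid(X, Y)
  if (length(grid) <= 1) return(if (length(grid)) grid[[1]] else list())
  inner <- cv_scheme(K = scheme$inner_K, repetitions = 1,
                     seed = derive_seed(scheme$seed, stream))
  folds <- kfold_partition(rownames(X), inner, 1)
  score_fold <- function(val_ids) {
    tr <- !(rownames(X) %in% val_ids)
    X_tr <- X[tr, , drop = FALSE]; Y_tr <- Y[tr, , drop = FALSE]
    X_va <- X[!tr, , drop = FALSE]; Y_va <- Y[!tr, , drop = FALSE]
    fits <- if (!is.null(method$fit_path))
      method$fit_path(X_tr, Y_tr, grid)
    else lapply(grid, function(h) method$fit(X_tr, Y_tr, h))
    vapply(fits, split_score, numeric(1), X_val = X_va, Y_val = Y_va)
  }
  per_fold <- vapply(folds, score_fold, numeric(length(grid)))
  scores <- rowMeans(per_fold, na.rm = TRUE)
  scores[is.nan(scores)] <- NA_real_
  if (all(is.na(scores))) return(grid[[1]])
  grid[[which.max(scores)]]
}

new_evaluation_record <- function(setting, source, method_id, traits,
                                  per_rep, per_rep_trait, family = NA,
                                  info = list()) {
  ok <- !is.na(per_rep)
  structure(list(setting = setting, source = source, method = method_id,
                 family = family, traits = traits,
                 per_rep = per_rep, per_rep_trait = per_rep_trait,
                 mean = if (any(ok)) mean(per_rep[ok]) else NA_real_,
                 se = if (sum(ok) > 1) sd(per_rep[ok]) / sqrt(sum(ok))
                      else NA_real_,
                 n_na = sum(!ok), info = info),
            class = "evaluation_record")
}

#' @exportS3Method base::print
print.evaluation_record <- function(x, ...) {
  cat(sprintf("<evaluation %s | %s | %s> mean predictability %.3f (se %.3f, %d reps, %d NA)\n",
              x$setting, x$source, x$method,
              x$mean, x$se %||% NA, length(x$per_rep), x$n_na))
  invisible(x)
}

#' Repeated nested cross-validation of one method on one setting block
#'
#' Outer loop over K test folds; when the method has hyperparameters an
#' inner 3-fold loop on the remaining data selects them by mean
#' validation predictability; the model is refit on the outer-training
#' data and scored on the test fold. Per-trait predictabilities are
#' averaged over traits within a fold, then over folds (one value per
#' repetition), then over repetitions. Folds and every stochastic fit
#' are derived from the scheme seed, so the record is reproducible
#' bit-for-bit.
#'
#' @param block a `setting_block` without a test side (S1/S2/S2aug).
#' @param method a [gs_method()] (or a method id).
#' @param scheme a [cv_scheme()].
#' @return an `evaluation_record`; `per_rep` holds the repetition-level
#'   predictabilities and `per_rep_trait` the repetition x trait detail.
#' @export
nested_cv_evaluate <- function(block, method, scheme = cv_scheme()) {
  stopifnot(inherits(block, "setting_block"))
  if (is.character(method)) method <- gs_method(method)
  check_method_source(method, block$source)
  X <- block$X; Y <- block$Y
  ids <- rownames(X)
  t <- ncol(Y)
  per_rep <- numeric(scheme$repetitions)
  per_rep_trait <- matrix(NA_real_, scheme$repetitions, t,
                          dimnames = list(NULL, colnames(Y)))
  for (rep_i in seq_len(scheme$repetitions)) {
    res <- with_seed(derive_seed(scheme$seed, 500000L + rep_i), {
      folds <- kfold_partition(ids, scheme, rep_i)
      fold_mean <- numeric(length(folds))
      fold_trait <- matrix(NA_real_, length(folds), t)
      for (f in seq_along(folds)) {
        test_ids <- folds[[f]]
        tr <- !(ids %in% test_ids)
        stopifnot(length(intersect(ids[tr], test_ids)) == 0)
        X_tr <- X[tr, , drop = FALSE]; Y_tr <- Y[tr, , drop = FALSE]
        hyper <- if (scheme$nested)
          select_hyper(method, X_tr, Y_tr, scheme, rep_i * 100L + f)
        else list()
        if (!scheme$nested && length(method$grid(X_tr, Y_tr)))
          hyper <- method$grid(X_tr, Y_tr)[[1]]
        fit <- method$fit(X_tr, Y_tr, hyper)
        pred <- predict(fit, X[!tr, , drop = FALSE])
        vals <- vapply(seq_len(t), function(k)
          predictability(Y[!tr, k], pred[, k]), numeric(1))
        fold_trait[f, ] <- vals
        fold_mean[f] <- if (all(is.na(vals))) NA_real_
                        else mean(vals, na.rm = TRUE)
      }
      list(
        rep_value = if (all(is.na(fold_mean))) NA_real_
                    else mean(fold_mean, na.rm = TRUE),
        rep_trait = colMeans(fold_trait, na.rm = TRUE)
      )
    })
    per_rep[rep_i] <- res$rep_value
    per_rep_trait[rep_i, ] <- ifelse(is.nan(res$rep_trait), NA,
                                     res$rep_trait)
  }
  new_evaluation_record(block$setting, block$source, method$id,
                        colnames(Y), per_rep, per_rep_trait)
}

#' Condition-ahead evaluation (setting S3)
#'
#' For each (train condition -> test condition) block, fits each method
#' on the training-condition data (hyperparameters selected by inner
#' 3-fold cross-validation on the training data only, so no test
#' leakage) and predicts the traits of the held-out samples in the test
#' condition. Predictability is the Pearson correlation over those
#' held-out samples; the evaluation is a single deterministic pass.
#'
#' @param blocks list of S3 `setting_block`s from [assemble_setting()].
#' @param methods character ids or list of [gs_method()]s.
#' @param scheme a [cv_scheme()] (used for the inner loop and seeding).
#' @return list of `evaluation_record`s, one per (block, method), each
#'   with one "repetition" holding the per-trait detail.
#' @export
condition_ahead_evaluate <- function(blocks, methods,
                                     scheme = cv_scheme()) {
  methods <- normalize_methods(methods)
  out <- list()
  for (b_i in seq_along(blocks)) {
    block <- blocks[[b_i]]
    assert_that(!is.null(block$X_test) && nrow(block$X_test) >= 3,
                "S3 block lacks held-out test samples")
    for (method in methods) {
      check_method_source(method, block$source)
      rec <- with_seed(derive_seed(scheme$seed, 700000L + b_i), {
        hyper <- select_hyper(method, block$X, block$Y, scheme, b_i)
        fit <- method$fit(block$X, block$Y, hyper)
        pred <- predict(fit, block$X_test)
        vals <- vapply(seq_len(ncol(block$Y_test)), function(k)
          predictability(block$Y_test[, k], pred[, k]), numeric(1))
        names(vals) <- colnames(block$Y_test)
        vals
      })
      out[[paste(names(blocks)[b_i] %||% b_i, method$id, sep = ".")]] <-
        new_evaluation_record("S3", block$source, method$id,
                              colnames(block$Y_test),
                              per_rep = mean(rec, na.rm = TRUE),
                              per_rep_trait = matrix(rec, 1,
                                dimnames = list(NULL, names(rec))),
                              info = block$info)
    }
  }
  out
}

#' Cross-family evaluation (setting S4)
#'
#' Fits each method on one family's concatenated block and scores it per
#' trait-condition response column on the other family.
#'
#' @param block an S4 `setting_block` (train family on the train side,
#'   test family on the test side).
#' @param methods character ids or list of [gs_method()]s.
#' @param scheme a [cv_scheme()].
#' @return list of `evaluation_record`s, one per method.
#' @export
cross_family_evaluate <- function(block, methods, scheme = cv_scheme()) {
  methods <- normalize_methods(methods)
  out <- list()
  for (method in methods) {
    check_method_source(method, block$source)
    vals <- with_seed(derive_seed(scheme$seed, 800000L), {
      hyper <- select_hyper(method, block$X, block$Y, scheme, 1L)
      fit <- method$fit(block$X, block$Y, hyper)
      pred <- predict(fit, block$X_test)
      v <- vapply(seq_len(ncol(block$Y_test)), function(k)
        predictability(block$Y_test[, k], pred[, k]), numeric(1))
      names(v) <- colnames(block$Y_test)
      v
    })
    out[[method$id]] <-
      new_evaluation_record("S4", block$source, method$id,
                            colnames(block$Y_test),
                            per_rep = mean(vals, na.rm = TRUE),
                            per_rep_trait = matrix(vals, 1,
                              dimnames = list(NULL, names(vals))))
  }
  out
}

normalize_methods <- function(methods) {
  if (inherits(methods, "gs_method")) return(list(methods))
  lapply(methods, function(m) if (is.character(m)) gs_method(m) else m)
}

#' Selection ability of the top (or bottom) ranked lines
#'
#' Ranks lines by observed and by predicted value, retains the
#' `n_selected` best (or worst) of each, and reports the percentage of
#' truly best (worst) lines correctly identified. Ties are broken by
#' stable sample order.
#'
#' @param observed,predicted numeric vectors over the same lines.
#' @param n_selected lines retained on each side (default 20).
#' @param direction `"best"` (largest values) or `"worst"`.
#' @return object of class `selection_ability`: a list with the
#'   percentage `proportion`, the direction, and `n_selected`.
#' @export
selection_ability <- function(observed, predicted, n_selected = 20,
                              direction = c("best", "worst")) {
  direction <- match.arg(direction)
  n <- length(observed)
  assert_that(length(predicted) == n, "lengths differ")
  assert_that(n_selected <= n, "n_selected exceeds the number of lines")
  decreasing <- direction == "best"
  top_obs <- order(observed, decreasing = decreasing)[seq_len(n_selected)]
  top_pred <- order(predicted, decreasing = decreasing)[seq_len(n_selected)]
  structure(list(proportion = 100 * length(intersect(top_obs, top_pred)) /
                   n_selected,
                 direction = direction, n_selected = n_selected),
            class = "selection_ability")
}
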