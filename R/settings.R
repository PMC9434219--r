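# Assembly of predictor/response blocks for the four evaluation settings.

#' Cast a tidy panel to a wide samples x (variable_condition) matrix
#'
#' Columns are ordered condition-major (all variables of the first
#' condition, then the next), named `variable_condition`.
#'
#' @param panel tidy data frame `sample_id, condition, variable, value`.
#' @param ids sample ids (row order of the result).
#' @param conditions conditions to include, in order.
#' @param variables variables to include (default: panel order of
#'   first appearance).
#' @return numeric matrix with one row per id.
#' @export
panel_wide <- function(panel, ids, conditions, variables = NULL) {
  variables <- variables %||% unique(panel$variable)
  cols <- list()
  for (cc in conditions) for (v in variables) {
    sub <- panel[panel$condition == cc & panel$variable == v, ]
    val <- sub$value[match(ids, sub$sample_id)]
    assert_that(!anyNA(val),
                paste0("panel incomplete for ", v, " condition ", cc))
    cols[[paste0(v, "_", cc)]] <- val
  }
  out <- do.call(cbind, cols)
  rownames(out) <- ids
  out
}

new_setting_block <- function(setting, source, X, Y,
                              X_test = NULL, Y_test = NULL, info = list()) {
  if (!is.null(X_test)) {
    assert_that(identical(colnames(X), colnames(X_test)),
                "train and test predictor columns must be identical")
    assert_that(length(intersect(rownames(X), rownames(X_test))) == 0 ||
                  isTRUE(info$allow_shared_ids),
                "a sample appears in both train and test")
  }
  structure(list(setting = setting, source = source,
                 X = X, Y = Y, X_test = X_test, Y_test = Y_test,
                 info = info),
            class = "setting_block")
}

#' @exportS3Method base::print
print.setting_block <- function(x, ...) {
  cat(sprintf("<setting_block %s | %s> train %d x %d -> %d responses",
              x$setting, x$source, nrow(x$X), ncol(x$X), ncol(x$Y)))
  if (!is.null(x$X_test)) cat(sprintf("; test %d rows", nrow(x$X_test)))
  cat("\n")
  invisible(x)
}

#' Assemble predictor/response blocks for an evaluation setting
#'
#' Builds the data blocks analysed by the four evaluation settings:
#' \describe{
#' \item{S1}{within-family cross-validation with traits and ChlF
#'   concatenated over all post-acclimation conditions: 9 response
#'   columns (3 traits x 3 conditions); ChlF predictors 54 columns, SNP
#'   predictors the full marker matrix.}
#' \item{S2}{single-condition cross-validation (default condition 3, the
#'   established-agroforestry treatment): 3 response columns; ChlF
#'   predictors 18 columns.}
#' \item{S2aug}{as S2 but with ChlF concatenated over all conditions (54
#'   predictor columns) while responses stay single-condition.}
#' \item{S3}{condition-ahead transfer: for each ordered pair
#'   (train condition -> test condition), the first `n_holdout` samples
#'   are held out of training and serve as the test set, with responses
#'   taken from the test condition. SNP predictors are identical across
#'   conditions (genotypes are recorded once); ChlF test predictors come
#'   from the test condition by default (`chlf_test_from = "test"`), the
#'   training condition optionally.}
#' \item{S4}{cross-family transfer: S1-style blocks for the training and
#'   test family; for SNP predictors the marker columns are intersected,
#'   for ChlF the parameter rosters must match.}
#' }
#'
#' @param setting one of `"S1"`, `"S2"`, `"S2aug"`, `"S3"`, `"S4"`.
#' @param genotypes QC'd, imputed samples x markers matrix.
#' @param phenomic,traits tidy panels for the family.
#' @param predictor_source `"snp"` or `"chlf"`.
#' @param conditions post-acclimation condition labels (default: those in
#'   `traits`).
#' @param target_condition response condition for S2/S2aug (default 3).
#' @param pairs list of train/test condition pairs for S3 (default
#'   `(2,3), (3,4), (2,4)`).
#' @param n_holdout held-out test samples for S3 (default 20).
#' @param holdout_order `"stored"` (default) holds out the first
#'   `n_holdout` samples in stored input order; `"random"` permutes
#'   sample order first under `holdout_seed`.
#' @param holdout_seed seed for `holdout_order = "random"`.
#' @param chlf_test_from `"test"` or `"train"`: condition whose ChlF
#'   measurements serve as predictors for the held-out S3 samples.
#' @param test_family for S4: list with `genotypes`, `phenomic`, `traits`
#'   of the other family.
#' @return a `setting_block`, or a list of them for S3.
#' @export
assemble_setting <- function(setting, genotypes, phenomic, traits,
                             predictor_source = c("snp", "chlf"),
                             conditions = NULL, target_condition = 3,
                             pairs = list(c(2, 3), c(3, 4), c(2, 4)),
                             n_holdout = 20,
                             holdout_order = c("stored", "random"),
                             holdout_seed = NULL,
                             chlf_test_from = c("test", "train"),
                             test_family = NULL) {
  setting <- match.arg(setting, c("S1", "S2", "S2aug", "S3", "S4"))
  predictor_source <- match.arg(predictor_source)
  holdout_order <- match.arg(holdout_order)
  chlf_test_from <- match.arg(chlf_test_from)
  ids <- rownames(genotypes)
  conditions <- conditions %||% sort(unique(traits$condition))
  trait_names <- unique(traits$variable)

  s1_block <- function(gm, ph, tr, ids) {
    Y <- panel_wide(tr, ids, conditions, trait_names)
    X <- if (predictor_source == "snp") gm[ids, , drop = FALSE]
         else panel_wide(ph, ids, conditions)
    list(X = X, Y = Y)
  }

  if (setting %in% c("S1", "S2", "S2aug")) {
    if (setting == "S1") {
      b <- s1_block(genotypes, phenomic, traits, ids)
      return(new_setting_block("S1", predictor_source, b$X, b$Y))
    }
    Y <- panel_wide(traits, ids, target_condition, trait_names)
    X <- if (predictor_source == "snp") genotypes[ids, , drop = FALSE]
         else if (setting == "S2") panel_wide(phenomic, ids, target_condition)
         else panel_wide(phenomic, ids, conditions)
    return(new_setting_block(setting, predictor_source, X, Y,
                             info = list(target_condition = target_condition)))
  }

  if (setting == "S3") {
    assert_that(length(ids) > n_holdout,
                "need more samples than the held-out count")
    ord <- if (holdout_order == "random")
      with_seed(holdout_seed, sample(ids)) else ids
    test_ids <- ord[seq_len(n_holdout)]
    train_ids <- ord[-seq_len(n_holdout)]
    blocks <- lapply(pairs, function(pr) {
      c_tr <- pr[1]; c_te <- pr[2]
      Y_tr <- panel_wide(traits, train_ids, c_tr, trait_names)
      Y_te <- panel_wide(traits, test_ids, c_te, trait_names)
      colnames(Y_te) <- colnames(Y_tr) <- trait_names
      if (predictor_source == "snp") {
        X_tr <- genotypes[train_ids, , drop = FALSE]
        X_te <- genotypes[test_ids, , drop = FALSE]
      } else {
        X_tr <- panel_wide(phenomic, train_ids, c_tr)
        c_px <- if (chlf_test_from == "test") c_te else c_tr
        X_te <- panel_wide(phenomic, test_ids, c_px)
        colnames(X_te) <- colnames(X_tr) <-
          sub("_[0-9]+$", "", colnames(X_tr))
      }
      new_setting_block("S3", predictor_source, X_tr, Y_tr, X_te, Y_te,
                        info = list(train_condition = c_tr,
                                    test_condition = c_te))
    })
    names(blocks) <- vapply(pairs, function(pr)
      paste0(pr[1], "to", pr[2]), character(1))
    return(blocks)
  }

  # S4
  assert_that(!is.null(test_family), "S4 requires test_family")
  ids_b <- rownames(test_family$genotypes)
  tr_a <- s1_block(genotypes, phenomic, traits, ids)
  tr_b <- s1_block(test_family$genotypes, test_family$phenomic,
                   test_family$traits, ids_b)
  if (predictor_source == "snp") {
    shared <- intersect(colnames(tr_a$X), colnames(tr_b$X))
    assert_that(length(shared) > 0, "no shared markers between families")
    tr_a$X <- tr_a$X[, shared, drop = FALSE]
    tr_b$X <- tr_b$X[, shared, drop = FALSE]
  } else {
    assert_that(identical(colnames(tr_a$X), colnames(tr_b$X)),
                "ChlF predictor rosters differ between families")
  }
  new_setting_block("S4", predictor_source, tr_a$X, tr_a$Y,
                    tr_b$X, tr_b$Y)
}
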