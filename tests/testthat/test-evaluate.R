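# Cross-validation mechanics, predictability scoring, the evaluation
# drivers, and selection ability.

test_that("fold partitions have the right sizes and are deterministic", {
  sch <- cv_scheme(seed = 7)
  ids74 <- sprintf("a%03d", 1:74)
  f74 <- kfold_partition(ids74, sch, 1)
  expect_setequal(lengths(f74), c(25, 25, 24))
  expect_setequal(unlist(f74), ids74)
  expect_length(intersect(f74[[1]], f74[[2]]), 0)
  ids119 <- sprintf("b%03d", 1:119)
  f119 <- kfold_partition(ids119, sch, 3)
  expect_setequal(lengths(f119), c(40, 40, 39))
  expect_identical(f119, kfold_partition(ids119, sch, 3))
  expect_false(identical(f119, kfold_partition(ids119, sch, 4)))
  expect_error(kfold_partition(ids74[1:2], sch), "at least K")
})

test_that("predictability applies the Pearson and zero-variance NA rules", {
  y <- c(1, 3, 2, 5, 4)
  expect_equal(predictability(y, y), 1)
  expect_equal(predictability(y, -y), -1)
  expect_true(is.na(predictability(y, rep(2, 5))))
  expect_true(is.na(predictability(rep(1, 5), y)))
  expect_equal(predictability(y, y * 2 + 3), 1)
  expect_error(predictability(y, y[1:3]), "lengths")
  expect_error(predictability(y[1:2], y[1:2]), "at least 3")
})

test_that("nested CV recovers a noise-free linear signal and stays honest on noise", {
  n <- 60; p <- 8
  X <- withr::with_seed(71, matrix(rnorm(n * p), n, p))
  B <- withr::with_seed(72, matrix(rnorm(p * 2), p, 2))
  blk <- toy_block(X, X %*% B)
  sch <- cv_scheme(repetitions = 2, seed = 5)
  rec <- nested_cv_evaluate(blk, gs_method("RR", list(n_lambda = 8)), sch)
  expect_gt(rec$mean, 0.99)
  expect_equal(rec$mean, mean(rec$per_rep), tolerance = 1e-12)
  # pure-noise responses hover near zero
  blk0 <- toy_block(X, withr::with_seed(73, matrix(rnorm(n * 2), n, 2)))
  rec0 <- nested_cv_evaluate(blk0, gs_method("RR", list(n_lambda = 8)), sch)
  expect_lt(abs(rec0$mean), 0.3)
  # determinism of the full record
  expect_identical(rec,
                   nested_cv_evaluate(blk,
                                      gs_method("RR", list(n_lambda = 8)),
                                      sch))
})

test_that("GBLUP is rejected for phenomic predictors", {
  X <- withr::with_seed(74, matrix(rnorm(90), 30, 3))
  blk <- toy_block(X, withr::with_seed(75, matrix(rnorm(60), 30, 2)),
                   source = "chlf")
  expect_error(nested_cv_evaluate(blk, "GBLUP", cv_scheme(repetitions = 1)),
               "not applicable")
})

test_that("condition-ahead evaluation scores held-out lines only", {
  cfg <- sim_config(n_individuals = 40, n_markers = 80, seed = 77)
  fam <- simulate_family(cfg)
  gm <- impute_mean(fam$genotypes)$genotypes
  blocks <- assemble_setting("S3", gm, fam$phenomic, fam$traits,
                             predictor_source = "chlf", n_holdout = 20)
  recs <- condition_ahead_evaluate(blocks["2to3"],
                                   gs_method("RR", list(n_lambda = 5)),
                                   cv_scheme(seed = 2))
  expect_length(recs, 1)
  expect_equal(colnames(recs[[1]]$per_rep_trait), c("LC", "TH", "TD"))
  # degenerate transfer: identical ChlF across conditions and identical
  # traits make S3 equal an ordinary within-condition fit
  ph <- fam$phenomic
  for (cc in 3:4) ph$value[ph$condition == cc] <- ph$value[ph$condition == 2]
  tr <- fam$traits
  for (cc in 3:4) tr$value[tr$condition == cc] <- tr$value[tr$condition == 2]
  b_deg <- assemble_setting("S3", gm, ph, tr, predictor_source = "chlf",
                            n_holdout = 20)
  r_23 <- condition_ahead_evaluate(b_deg["2to3"],
                                   gs_method("RR", list(n_lambda = 5)),
                                   cv_scheme(seed = 2))
  r_24 <- condition_ahead_evaluate(b_deg["2to4"],
                                   gs_method("RR", list(n_lambda = 5)),
                                   cv_scheme(seed = 2))
  expect_equal(r_23[[1]]$per_rep_trait, r_24[[1]]$per_rep_trait,
               tolerance = 1e-10)
})

test_that("condition-ahead GP stays accurate when the genetic signal persists", {
  # high heritability, no GxE: the genetic ranking carries over to the
  # next condition, so marker-based transfer prediction remains strong
  cfg <- sim_config(n_individuals = 119, n_markers = 60, n_qtl = 30,
                    seed = 55, var_G = 1, var_E = 0.2, var_GxE = 0,
                    var_eps = 0.11)
  fam <- simulate_family(cfg)
  gm <- impute_mean(fam$genotypes)$genotypes
  blocks <- assemble_setting("S3", gm, fam$phenomic, fam$traits,
                             predictor_source = "snp")
  recs <- condition_ahead_evaluate(blocks["2to3"],
                                   gs_method("RR", list(n_lambda = 8)),
                                   cv_scheme(seed = 5))
  expect_true(all(recs[[1]]$per_rep_trait >= 0.8))
})

test_that("cross-family transfer finds shared genetic signal and fails a shuffled null", {
  cfg <- sim_config(n_individuals = 60, n_markers = 120, seed = 88,
                    var_eps = 0.1, var_GxE = 0.1, n_qtl = 20)
  study <- simulate_study(cfg, n_individuals = c(60, 60))
  qa <- impute_mean(study[[1]]$genotypes)$genotypes
  qb <- impute_mean(study[[2]]$genotypes)$genotypes
  blk <- assemble_setting("S4", qa, study[[1]]$phenomic, study[[1]]$traits,
                          predictor_source = "snp",
                          test_family = list(genotypes = qb,
                                             phenomic = study[[2]]$phenomic,
                                             traits = study[[2]]$traits))
  recs <- cross_family_evaluate(blk, gs_method("RR", list(n_lambda = 8)),
                                cv_scheme(seed = 6))
  expect_gt(recs[["RR"]]$mean, 0)
  # shuffled test responses destroy the transfer
  blk_null <- blk
  blk_null$Y_test <- blk$Y_test[withr::with_seed(89,
                                                 sample(nrow(blk$Y_test))), ]
  rownames(blk_null$Y_test) <- rownames(blk$Y_test)
  recs0 <- cross_family_evaluate(blk_null,
                                 gs_method("RR", list(n_lambda = 8)),
                                 cv_scheme(seed = 6))
  expect_lt(abs(recs0[["RR"]]$mean), 0.25)
})

test_that("selection ability matches the set-intersection oracle", {
  y <- withr::with_seed(91, rnorm(40))
  expect_equal(selection_ability(y, y)$proportion, 100)
  # reversed ranking with n = 2 * n_selected gives disjoint top sets
  expect_equal(selection_ability(y, rank(-y), n_selected = 20)$proportion, 0)
  expect_error(selection_ability(y, y, n_selected = 50), "exceeds")
  # brute-force oracle over random instances
  for (s in 1:50) {
    obs <- withr::with_seed(1000 + s, rnorm(30))
    prd <- withr::with_seed(2000 + s, rnorm(30))
    got <- selection_ability(obs, prd, n_selected = 8)$proportion
    top_o <- order(obs, decreasing = TRUE)[1:8]
    top_p <- order(prd, decreasing = TRUE)[1:8]
    expect_equal(got, 100 * length(intersect(top_o, top_p)) / 8)
    gotw <- selection_ability(obs, prd, n_selected = 8, "worst")$proportion
    bot_o <- order(obs)[1:8]
    bot_p <- order(prd)[1:8]
    expect_equal(gotw, 100 * length(intersect(bot_o, bot_p)) / 8)
  }
})

test_that("random predictions hit the hypergeometric expectation", {
  # overlap of a random k-subset with a fixed k-subset of n has mean
  # k^2 / n: 20 of 100 -> 4 of 20 -> 20%
  props <- withr::with_seed(92, {
    obs <- rnorm(100)
    vapply(seq_len(1000), function(i)
      selection_ability(obs, rnorm(100), n_selected = 20)$proportion,
      numeric(1))
  })
  expect_lt(abs(mean(props) - 20), 5)
})

test_that("reports assemble tables, bars and files", {
  X <- withr::with_seed(93, matrix(rnorm(40 * 6), 40, 6))
  B <- withr::with_seed(94, matrix(rnorm(12), 6, 2))
  blk <- toy_block(X, X %*% B + withr::with_seed(95,
                                                 matrix(rnorm(80, 0, .3),
                                                        40, 2)))
  sch <- cv_scheme(repetitions = 2, seed = 9)
  recs <- list(a = nested_cv_evaluate(blk, gs_method("RR",
                                                     list(n_lambda = 5)),
                                      sch))
  recs$a$family <- "F1"
  out <- withr::local_tempdir()
  rep <- make_report(recs, out_dir = out)
  expect_true(file.exists(file.path(out, "predictability_long.csv")))
  expect_true(file.exists(file.path(out, "setting_S2.csv")))
  expect_true(file.exists(file.path(out, "metadata.json")))
  expect_equal(nrow(rep$tables), 2) # one row per trait
  empty <- make_report(list())
  expect_equal(nrow(empty$tables), 0)
  # out-of-fold predictions cover every sample
  pred <- cv_predictions(blk, gs_method("RR", list(n_lambda = 5)), sch)
  expect_false(anyNA(pred))
  expect_gt(cor(pred[, 1], blk$Y[, 1]), 0.8)
})
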