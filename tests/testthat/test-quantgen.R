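# Heritability, variance components, genetic effects and correlations,
# and Hotelling's T2.

test_that("broad-sense heritability follows the multi-environment formula", {
  expect_equal(broad_sense_h2(variance_components(1, 0, 0, 0, 3)), 1)
  expect_equal(broad_sense_h2(variance_components(0, 1, 1, 1, 3)), 0)
  h2 <- broad_sense_h2(variance_components(1, 1, 0.6, 0.6, 3))
  expect_equal(h2, 1 / 2.4, tolerance = 1e-15)
  expect_equal(round(h2, 4), 0.4167)
  # the environment variance enters undivided; the alternative
  # line-mean convention drops it
  expect_equal(broad_sense_h2(variance_components(1, 1, 0.6, 0.6, 3),
                              include_env = FALSE), 1 / 1.4)
  expect_error(broad_sense_h2(variance_components(0, 0, 0, 0, 3)),
               "degenerate")
  vc <- variance_components(1, -0.2, 0.5, 0.5, 3)
  expect_true(vc$truncated)
  expect_equal(vc$var_E, 0)
})

test_that("variance components come back sane on engineered designs", {
  ids <- sprintf("g%02d", 1:30)
  # all observations equal -> all components zero
  flat <- expand.grid(sample_id = ids, condition = 2:4)
  flat$value <- 5
  vc0 <- estimate_variance_components(flat)
  expect_equal(c(vc0$var_G, vc0$var_E, vc0$var_GxE, vc0$var_eps),
               rep(0, 4))
  # genotype value replicated across conditions with no noise:
  # everything loads on G, nothing on GxE or residual
  gval <- withr::with_seed(21, rnorm(30))
  dup <- expand.grid(sample_id = ids, condition = 2:4)
  dup$value <- gval[match(dup$sample_id, ids)]
  vc1 <- estimate_variance_components(dup)
  expect_gt(vc1$var_G, 0.5 * var(gval))
  expect_equal(vc1$var_GxE, 0)
  expect_lt(vc1$var_eps, 1e-6)
  expect_error(estimate_variance_components(flat[1:30, ]), "conditions")
})

test_that("REML recovers the generator's variance architecture", {
  cfg <- sim_config(n_individuals = 200, n_markers = 100, seed = 31,
                    var_G = 1, var_E = 1, var_GxE = 0.6, var_eps = 0.6)
  fam <- simulate_family(cfg)
  vc <- estimate_variance_components(fam$traits, trait = "TH")
  expect_equal(vc$var_G, var(fam$truth$g[, "TH"]), tolerance = 0.3)
  # with one observation per cell, GxE and residual are pooled
  expect_true(vc$gxe_confounded)
  expect_equal(vc$var_GxE + vc$var_eps, 1.2, tolerance = 0.35)
  expect_equal(broad_sense_h2(vc),
               unname(realized_h2(fam$truth, fam$traits)["TH"]),
               tolerance = 0.1)
})

test_that("genetic effects behave across signal regimes", {
  g <- rand_geno(150, 60, seed = 41)
  ids <- rownames(g)
  gv <- drop(scale(g, scale = FALSE) %*%
               withr::with_seed(42, rnorm(60, 0, 0.3)))
  make_panel <- function(v) data.frame(sample_id = rep(ids, 2),
                                       condition = rep(2:3, each = 150),
                                       variable = "LC",
                                       value = rep(v, 2))
  # noise-free signal
  ge <- genetic_effects(g, make_panel(gv))
  expect_gt(cor(ge$effects[, "LC_2"], gv), 0.99)
  # pure noise: estimated effects stay small and carry no signal for
  # an independent draw
  y0 <- withr::with_seed(43, rnorm(150))
  ge0 <- genetic_effects(g, make_panel(y0))
  expect_lt(sd(ge0$effects[, "LC_2"]) / sd(gv), 1)
  expect_lt(abs(cor(ge0$effects[, "LC_2"],
                    withr::with_seed(44, rnorm(150)))), 0.2)
  # constant response: all genetic effects equal
  gec <- genetic_effects(g, make_panel(rep(2, 150)))
  expect_equal(unname(var(gec$effects[, "LC_2"])), 0)
})

test_that("genetic correlation matrix is Pearson on effect vectors with NA flagging", {
  g <- rand_geno(80, 40, seed = 51)
  panel <- data.frame(sample_id = rep(rownames(g), 2),
                      condition = rep(2:3, each = 80),
                      variable = "LC",
                      value = rep(drop(scale(g[, 1:5]) %*% rep(1, 5)) +
                                    withr::with_seed(52, rnorm(80, 0, 0.3)), 2))
  ge <- genetic_effects(g, panel)
  cm <- genetic_correlation_matrix(ge)
  expect_equal(unname(diag(cm)), rep(1, 2), tolerance = 1e-12)
  expect_true(all(abs(cm) <= 1 + 1e-12, na.rm = TRUE))
  # zero-variance effects flag as NA
  gec <- ge
  gec$effects[, 2] <- 0
  cm2 <- genetic_correlation_matrix(gec, ge)
  expect_true(all(is.na(cm2[2, ])))
})

test_that("Hotelling's T2 matches its oracle and classical identities", {
  a <- withr::with_seed(61, matrix(rnorm(10 * 3), 10, 3))
  b <- withr::with_seed(62, matrix(rnorm(12 * 3, 0.8), 12, 3))
  res <- hotelling_t2(a, b)
  ref <- oracle_hotelling(a, b)
  expect_equal(res$statistic, ref$statistic, tolerance = 1e-12)
  expect_equal(res$p_value, ref$p_value, tolerance = 1e-12)
  # identical samples: no difference
  same <- hotelling_t2(a, a)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  # univariate case collapses to the squared two-sample t statistic
  x <- withr::with_seed(63, matrix(rnorm(8), 8, 1))
  y <- withr::with_seed(64, matrix(rnorm(9, 1), 9, 1))
  t_ref <- t.test(x, y, var.equal = TRUE)$statistic
  expect_equal(hotelling_t2(x, y)$statistic, unname(t_ref^2),
               tolerance = 1e-10)
  # fixed toy 2-D instance frozen against the direct formula
  A <- matrix(c(1, 2, 3, 4, 5, 2, 1, 3, 2, 4), 5, 2)
  B <- matrix(c(2, 3, 4, 5, 6, 4, 3, 5, 4, 6), 5, 2)
  toy <- hotelling_t2(A, B)
  toy_ref <- oracle_hotelling(A, B)
  expect_equal(toy$statistic, toy_ref$statistic, tolerance = 1e-12)
  expect_error(hotelling_t2(a[1:2, ], b[1:3, ]), "dimension")
})
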