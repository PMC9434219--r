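# The synthetic-data generator: cross structure, variance architecture,
# ChlF genetic loadings, missingness injection, reproducibility.

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_qtl = 100, n_markers = 50), "n_qtl")
  expect_error(sim_config(var_G = -1), "nonnegative")
  expect_error(sim_config(parent_heterozygosity = c(0.5, 0.5)), "three")
  expect_error(sim_config(missing_rate_markers = 1.5), "rates")
})

test_that("zero-noise traits equal the genetic values in every condition", {
  cfg <- sim_config(n_individuals = 30, n_markers = 100,
                    var_E = 0, var_GxE = 0, var_eps = 0, seed = 7)
  fam <- simulate_family(cfg)
  for (cc in 2:4) {
    sub <- fam$traits[fam$traits$condition == cc & fam$traits$variable == "TH", ]
    expect_equal(sub$value[match(rownames(fam$genotypes), sub$sample_id)],
                 unname(fam$truth$g[, "TH"]), tolerance = 1e-12)
  }
})

test_that("offspring codes are 0/1/2 and a fully heterozygous parent yields ~50% heterozygous offspring calls", {
  # gamete enumeration at a single site: het x hom -> P(offspring het) = 1/2
  cfg <- sim_config(n_individuals = 200, n_markers = 400,
                    parent_heterozygosity = c(1, 0, 0), seed = 3)
  fam <- simulate_family(cfg)
  g <- fam$genotypes
  expect_true(all(g %in% 0:2))
  het <- mean(g == 1)
  se <- sqrt(0.25 / length(g))
  expect_lt(abs(het - 0.5), 3 * se)
})

test_that("default parental heterozygosities are hit at 5000 markers", {
  cfg <- sim_config(n_individuals = 5, n_markers = 5000, seed = 11)
  study <- simulate_study(cfg)
  hets <- c(mean(study[[1]]$truth$shared_parent == 1),
            mean(study[[1]]$truth$line_parent == 1),
            mean(study[[2]]$truth$line_parent == 1))
  targets <- c(0.84, 0.14, 0.12)
  se <- sqrt(targets * (1 - targets) / 5000)
  expect_true(all(abs(hets - targets) < 3 * se))
  # shared parent genome really is shared
  expect_identical(study[[1]]$truth$shared_parent,
                   study[[2]]$truth$shared_parent)
})

test_that("fixed seed reproduces the simulation bit for bit", {
  cfg <- sim_config(n_individuals = 25, n_markers = 80, seed = 42)
  f1 <- simulate_family(cfg)
  f2 <- simulate_family(cfg)
  expect_identical(f1, f2)
})

test_that("empirical variance decomposition matches configured components at n=500", {
  cfg <- sim_config(n_individuals = 500, n_markers = 300, seed = 9,
                    var_G = 1, var_E = 1, var_GxE = 0.6, var_eps = 0.6)
  fam <- simulate_family(cfg)
  tr <- fam$truth
  expect_equal(var(tr$g[, "LC"]), 1, tolerance = 0.15)
  expect_equal(var(as.vector(tr$gxe[, , "LC"])), 0.6, tolerance = 0.15 * 0.6)
  # residuals reconstructed from the panel
  sub <- fam$traits[fam$traits$variable == "LC", ]
  resid <- sub$value -
    tr$g[sub$sample_id, "LC"] -
    tr$condition_effects[as.character(sub$condition), "LC"] -
    mapply(function(s, cc) tr$gxe[s, as.character(cc), "LC"],
           sub$sample_id, sub$condition)
  expect_equal(var(resid), 0.6, tolerance = 0.15 * 0.6)
  # e condition effects are present (their sample variance over e=3
  # draws carries no n-driven guarantee)
  expect_equal(nrow(tr$condition_effects), 3L)
})

test_that("ChlF genetic components realize the configured loadings at n=500", {
  cfg <- sim_config(n_individuals = 500, n_markers = 300, seed = 13)
  fam <- simulate_family(cfg)
  tr <- fam$truth
  for (t in 1:3) {
    r <- cor(tr$chlf_genetic[, t], tr$g[, t])
    expect_lt(abs(r - 0.35), 0.1)
  }
  # an unloaded pair stays near zero
  expect_lt(abs(cor(tr$chlf_genetic[, 7], tr$g[, 1])), 0.15)
})

test_that("missingness injection hits its rates and keeps the seed contract", {
  cfg <- sim_config(n_individuals = 100, n_markers = 1000, seed = 5,
                    missing_rate_markers = 0.05, missing_rate_samples = 0)
  g <- rand_geno(100, 1000, seed = 5)
  g0 <- inject_missingness(g, sim_config(n_individuals = 100,
                                         n_markers = 1000, seed = 5,
                                         missing_rate_markers = 0,
                                         missing_rate_samples = 0))
  expect_identical(g0, {gg <- g; storage.mode(gg) <- "double"; gg})
  g1 <- inject_missingness(g, sim_config(n_individuals = 100,
                                         n_markers = 1000, seed = 5,
                                         missing_rate_markers = 1,
                                         missing_rate_samples = 0))
  expect_true(all(is.na(g1)))
  gm <- inject_missingness(g, cfg)
  rate <- mean(is.na(gm))
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / length(g)))
  expect_identical(gm, inject_missingness(g, cfg))
})

test_that("elevated-missingness samples exceed the 10% sample filter", {
  cfg <- sim_config(n_individuals = 100, n_markers = 500, seed = 21,
                    missing_rate_markers = 0.01,
                    missing_rate_samples = 0.1, high_missing_rate = 0.2)
  g <- rand_geno(100, 500, seed = 2)
  gm <- inject_missingness(g, cfg)
  expect_gte(sum(rowMeans(is.na(gm)) > 0.10), 5)
})

test_that("realized heritability hits the closed-form limits", {
  cfg1 <- sim_config(n_individuals = 40, n_markers = 100, seed = 2,
                     var_G = 1, var_E = 0, var_GxE = 0, var_eps = 0)
  fam1 <- simulate_family(cfg1)
  expect_equal(unname(realized_h2(fam1$truth, fam1$traits)), rep(1, 3))
  cfg0 <- sim_config(n_individuals = 40, n_markers = 100, seed = 2,
                     var_G = 0, var_E = 1, var_GxE = 0.5, var_eps = 0.5)
  fam0 <- simulate_family(cfg0)
  expect_equal(unname(realized_h2(fam0$truth, fam0$traits)), rep(0, 3))
})
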