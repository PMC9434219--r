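#' Simulation configuration for synthetic three-way hybrid families
#'
#' Builds the configuration object consumed by [simulate_family()] and
#' [simulate_study()]. The generator emulates two segregating families
#' obtained by crossing a highly heterozygous, clonally propagated F1
#' hybrid (the shared maternal parent) with one of two largely homozygous
#' landrace lines. Offspring receive one random gamete from each parent at
#' independently segregating biallelic sites.
#'
#' Traits are generated per condition as
#' \deqn{y_{ict} = g_{it} + E_{ct} + (G \times E)_{ict} + \epsilon_{ict},}
#' where the additive genetic value \eqn{g} is driven by `n_qtl` causal
#' markers per trait and the remaining terms are Gaussian with the
#' configured variances. Chlorophyll-fluorescence (ChlF) endophenotypes are
#' generated with a genetic component that loads on the trait genetic
#' values (plus an independent marker-driven genetic background), so the
#' genetic correlation between a ChlF parameter and a trait is controlled
#' by `chlf_genetic_loading` in expectation, while heavy measurement noise
#' keeps ChlF heritability low.
#'
#' @param n_individuals offspring per family (default 74, the smaller
#'   family; [simulate_study()] uses `c(74, 119)`).
#' @param n_markers number of biallelic SNP markers (default 2000, a
#'   desk-scale stand-in for a genotyping panel).
#' @param n_conditions number of post-acclimation treatment conditions
#'   (default 3; labelled 2, 3, 4 to match a treatment design whose first
#'   condition is the acclimation and is not analysed).
#' @param n_chlf number of ChlF parameters per condition (default 18).
#' @param parent_heterozygosity length-3 fractions in \[0,1\]: heterozygous
#'   site frequency of the shared F1 parent and of the two line parents
#'   (defaults 0.84, 0.14, 0.12).
#' @param n_qtl causal markers per trait (default 50).
#' @param var_G,var_E,var_GxE,var_eps nonnegative per-trait variances
#'   (scalars recycled over the 3 traits). Defaults 1, 1, 0.6, 0.6.
#' @param chlf_genetic_loading traits x `n_chlf` matrix of target genetic
#'   correlations in \[-1,1\] between each trait's genetic value and each
#'   ChlF parameter's genetic component. Default: 0.35 for ChlF parameter
#'   `k = t` (trait `t`), 0 elsewhere, mirroring the modest maximal
#'   trait-ChlF genetic correlations seen in coffee hybrid data.
#' @param chlf_cond_sd standard deviation of per-condition ChlF shifts
#'   (default 0.7).
#' @param chlf_noise_sd ChlF measurement-noise standard deviation
#'   (default 3; together with a unit-variance genetic component this puts
#'   ChlF broad-sense heritability near 0.2).
#' @param missing_rate_markers background probability an entry is set
#'   missing by [inject_missingness()] (default 0.02).
#' @param missing_rate_samples fraction of samples given elevated
#'   missingness (default 0.05); see `high_missing_rate`.
#' @param high_missing_rate per-entry missing rate for the elevated
#'   samples (default 0.15, above the 10% sample filter).
#' @param traits trait names (default `c("LC", "TH", "TD")` for leaf
#'   count, tree height, trunk diameter).
#' @param seed integer seed for the generator.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 20, n_markers = 100, seed = 1)
#' fam <- simulate_family(cfg)
#' str(fam$truth$h2_true)
sim_config <- function(n_individuals = 74,
                       n_markers = 2000,
                       n_conditions = 3,
                       n_chlf = 18,
                       parent_heterozygosity = c(0.84, 0.14, 0.12),
                       n_qtl = 50,
                       var_G = 1,
                       var_E = 1,
                       var_GxE = 0.6,
                       var_eps = 0.6,
                       chlf_genetic_loading = NULL,
                       chlf_cond_sd = 0.7,
                       chlf_noise_sd = 3,
                       missing_rate_markers = 0.02,
                       missing_rate_samples = 0.05,
                       high_missing_rate = 0.15,
                       traits = c("LC", "TH", "TD"),
                       seed = 1L) {
  n_traits <- length(traits)
  rec <- function(v, what) {
    v <- rep_len(as.double(v), n_traits)
    assert_that(all(v >= 0), paste0(what, " must be nonnegative"))
    v
  }
  var_G <- rec(var_G, "var_G"); var_E <- rec(var_E, "var_E")
  var_GxE <- rec(var_GxE, "var_GxE"); var_eps <- rec(var_eps, "var_eps")
  assert_that(length(parent_heterozygosity) == 3 &&
                all(parent_heterozygosity >= 0 & parent_heterozygosity <= 1),
              "parent_heterozygosity must be three fractions in [0,1]")
  assert_that(n_qtl <= n_markers, "n_qtl must not exceed n_markers")
  assert_that(n_qtl >= 0, "n_qtl must be nonnegative")
  rates_ok <- all(c(missing_rate_markers, missing_rate_samples,
                    high_missing_rate) >= 0 &
                  c(missing_rate_markers, missing_rate_samples,
                    high_missing_rate) <= 1)
  assert_that(rates_ok, "missing rates must be in [0,1]")
  if (is.null(chlf_genetic_loading)) {
    chlf_genetic_loading <- matrix(0, n_traits, n_chlf)
    for (t in seq_len(min(n_traits, n_chlf)))
      chlf_genetic_loading[t, t] <- 0.35
  }
  chlf_genetic_loading <- as.matrix(chlf_genetic_loading)
  assert_that(all(dim(chlf_genetic_loading) == c(n_traits, n_chlf)),
              "chlf_genetic_loading must be traits x n_chlf")
  assert_that(all(abs(chlf_genetic_loading) <= 1),
              "chlf_genetic_loading entries must be in [-1,1]")
  assert_that(all(colSums(chlf_genetic_loading^2) <= 1),
              "per-ChlF squared loadings must sum to at most 1")
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_markers = as.integer(n_markers),
    n_conditions = as.integer(n_conditions),
    n_chlf = as.integer(n_chlf),
    parent_heterozygosity = as.double(parent_heterozygosity),
    n_qtl = as.integer(n_qtl),
    var_G = var_G, var_E = var_E, var_GxE = var_GxE, var_eps = var_eps,
    chlf_genetic_loading = chlf_genetic_loading,
    chlf_cond_sd = as.double(chlf_cond_sd),
    chlf_noise_sd = as.double(chlf_noise_sd),
    missing_rate_markers = as.double(missing_rate_markers),
    missing_rate_samples = as.double(missing_rate_samples),
    high_missing_rate = as.double(high_missing_rate),
    traits = traits,
    conditions = seq(2L, length.out = as.integer(n_conditions)),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' The 18-parameter chlorophyll-fluorescence roster
#'
#' Fast-induction ChlF parameter names used throughout the package
#' (fluorescence levels, quantum yields, flux ratios, and performance
#' indices measured on dark-adapted leaves).
#'
#' @return character vector of length 18.
#' @export
chlf_parameter_names <- function() {
  c("IBR", "PI_total", "phi_Ro", "phi_Eo", "psi_Eo", "phi_Po",
    "phi_Po_ratio", "dRo_ratio", "psi_Eo_ratio", "RC_ABS", "REo_RC",
    "DIo_RC", "ETo_RC", "TRo_RC", "ABS_RC", "Fo", "Fm", "Fv_Fm")
}

# Draw a parent genome: additive codes 0/1/2 with P(code == 1) = het and
# the homozygous mass split evenly between the two alleles.
sim_parent_genome <- function(n_markers, het) {
  u <- runif(n_markers)
  codes <- integer(n_markers)
  codes[u < het] <- 1L
  hom <- u >= het
  codes[hom] <- 2L * rbinom(sum(hom), 1L, 0.5)
  codes
}

# One gamete per offspring from a parent's additive codes: heterozygous
# sites transmit either allele with probability 1/2.
sim_gametes <- function(parent_codes, n_off) {
  p <- length(parent_codes)
  g <- matrix(rep(parent_codes / 2, each = n_off), n_off, p)
  het <- which(parent_codes == 1L)
  if (length(het))
    g[, het] <- matrix(rbinom(n_off * length(het), 1L, 0.5), n_off)
  g
}

chlf_names_for <- function(n_chlf) {
  base <- chlf_parameter_names()
  if (n_chlf <= length(base)) base[seq_len(n_chlf)]
  else c(base, paste0("ChlF", seq(length(base) + 1, n_chlf)))
}

#' Simulate one three-way hybrid family with known genetic ground truth
#'
#' Generates offspring genotypes (one gamete from the shared F1 parent,
#' one from the line parent, independent sites), per-condition traits with
#' the configured G, E, GxE and residual variance components, and ChlF
#' endophenotypes whose genetic components load on the trait genetic
#' values. All stochastic draws run under `config$seed` (offset by
#' `seed_offset`), so output is bit-reproducible.
#'
#' @param config a [sim_config()].
#' @param line_parent which line parent to cross with the shared F1 parent
#'   (1 or 2, selecting `parent_heterozygosity[2]` or `[3]`).
#' @param shared_parent optional pre-drawn additive codes for the shared
#'   F1 parent (used by [simulate_study()] so two families share it).
#' @param family_id label prefixed to sample ids.
#' @param seed_offset integer added to the derived seed stream, letting
#'   two families from one config differ.
#'
#' @return a list with elements
#'   \item{genotypes}{n x p integer matrix of 0/1/2 codes, sample ids as
#'     row names, marker ids as column names}
#'   \item{phenomic}{tidy data frame `sample_id, condition, variable,
#'     value` of ChlF parameters}
#'   \item{traits}{tidy data frame `sample_id, condition, variable, value`
#'     of traits}
#'   \item{truth}{`sim_truth` list: `marker_effects` (p x traits),
#'     `genetic_values` (n x traits x conditions, genetic value plus GxE
#'     deviation), `g` (n x traits additive values), `condition_effects`,
#'     `gxe`, `chlf_genetic` (n x n_chlf genetic components),
#'     `variance_components_true`, `h2_true`, and the parent genomes}
#' @export
simulate_family <- function(config, line_parent = 1,
                            shared_parent = NULL,
                            family_id = paste0("F", line_parent),
                            seed_offset = line_parent) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, seed_offset), {
    n <- config$n_individuals
    p <- config$n_markers
    e <- config$n_conditions
    n_traits <- length(config$traits)
    n_chlf <- config$n_chlf

    if (is.null(shared_parent))
      shared_parent <- sim_parent_genome(p, config$parent_heterozygosity[1])
    line_het <- config$parent_heterozygosity[1 + line_parent]
    line_genome <- sim_parent_genome(p, line_het)

    geno <- sim_gametes(shared_parent, n) + sim_gametes(line_genome, n)
    storage.mode(geno) <- "integer"
    rownames(geno) <- sprintf("%s_%03d", family_id, seq_len(n))
    colnames(geno) <- sprintf("M%05d", seq_len(p))

    Xc <- scale(geno, center = TRUE, scale = FALSE)

    # Additive genetic values: n_qtl causal markers per trait, effects
    # rescaled so the realized genetic variance equals var_G exactly.
    marker_effects <- matrix(0, p, n_traits,
                             dimnames = list(colnames(geno), config$traits))
    g <- matrix(0, n, n_traits,
                dimnames = list(rownames(geno), config$traits))
    for (t in seq_len(n_traits)) {
      if (config$n_qtl == 0 || config$var_G[t] == 0) next
      qtl <- sample.int(p, config$n_qtl)
      b <- rnorm(config$n_qtl)
      gv <- Xc[, qtl, drop = FALSE] %*% b
      s <- sd(gv)
      if (s > 0) {
        fac <- sqrt(config$var_G[t]) / s
        marker_effects[qtl, t] <- b * fac
        g[, t] <- gv * fac
      }
    }

    cond_eff <- matrix(rnorm(e * n_traits, 0, sqrt(rep(config$var_E, each = e))),
                       e, n_traits,
                       dimnames = list(config$conditions, config$traits))
    gxe <- array(rnorm(n * e * n_traits,
                       0, sqrt(rep(config$var_GxE, each = n * e))),
                 dim = c(n, e, n_traits),
                 dimnames = list(rownames(geno), config$conditions,
                                 config$traits))
    eps <- array(rnorm(n * e * n_traits,
                       0, sqrt(rep(config$var_eps, each = n * e))),
                 dim = dim(gxe), dimnames = dimnames(gxe))

    y <- array(0, dim = dim(gxe), dimnames = dimnames(gxe))
    genetic_values <- array(0, dim = c(n, n_traits, e),
                            dimnames = list(rownames(geno), config$traits,
                                            config$conditions))
    for (c_i in seq_len(e)) {
      for (t in seq_len(n_traits)) {
        y[, c_i, t] <- g[, t] + cond_eff[c_i, t] + gxe[, c_i, t] +
          eps[, c_i, t]
        genetic_values[, t, c_i] <- g[, t] + gxe[, c_i, t]
      }
    }

    # ChlF genetic components: loadings on standardized trait genetic
    # values plus an independent marker-driven genetic background, so the
    # target genetic correlations hold in expectation.
    z <- apply(g, 2, function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0)
    chlf_gen <- matrix(0, n, n_chlf,
                       dimnames = list(rownames(geno), chlf_names_for(n_chlf)))
    for (k in seq_len(n_chlf)) {
      load_k <- config$chlf_genetic_loading[, k]
      resid_var <- max(0, 1 - sum(load_k^2))
      bg <- 0
      if (resid_var > 0 && config$n_qtl > 0) {
        qtl <- sample.int(p, config$n_qtl)
        b <- rnorm(config$n_qtl)
        w <- Xc[, qtl, drop = FALSE] %*% b
        sw <- sd(w)
        bg <- if (sw > 0) (w - mean(w)) / sw * sqrt(resid_var) else 0
      }
      chlf_gen[, k] <- z %*% load_k + bg
    }
    chlf_cond <- matrix(rnorm(e * n_chlf, 0, config$chlf_cond_sd), e, n_chlf)
    chlf <- array(0, dim = c(n, e, n_chlf),
                  dimnames = list(rownames(geno), config$conditions,
                                  colnames(chlf_gen)))
    for (c_i in seq_len(e))
      chlf[, c_i, ] <- sweep(chlf_gen, 2, chlf_cond[c_i, ], "+") +
        matrix(rnorm(n * n_chlf, 0, config$chlf_noise_sd), n, n_chlf)

    vc_true <- data.frame(trait = config$traits,
                          var_G = config$var_G, var_E = config$var_E,
                          var_GxE = config$var_GxE, var_eps = config$var_eps)
    h2_true <- vapply(seq_len(n_traits), function(t)
      broad_sense_h2(variance_components(config$var_G[t], config$var_E[t],
                                         config$var_GxE[t], config$var_eps[t],
                                         e)), numeric(1))
    names(h2_true) <- config$traits

    truth <- structure(list(
      marker_effects = marker_effects,
      genetic_values = genetic_values,
      g = g,
      condition_effects = cond_eff,
      gxe = gxe,
      chlf_genetic = chlf_gen,
      variance_components_true = vc_true,
      h2_true = h2_true,
      n_conditions = e,
      shared_parent = shared_parent,
      line_parent = line_genome,
      family_id = family_id
    ), class = "sim_truth")

    list(genotypes = geno,
         phenomic = flatten_panel(chlf),
         traits = flatten_panel(y, t_last = TRUE),
         truth = truth)
  })
}

# Convert an n x condition x variable array (or n x condition x trait)
# into the tidy long format sample_id, condition, variable, value.
flatten_panel <- function(a, t_last = FALSE) {
  dn <- dimnames(a)
  n <- dim(a)[1]; e <- dim(a)[2]; k <- dim(a)[3]
  out <- expand.grid(sample_id = dn[[1]], condition = as.integer(dn[[2]]),
                     variable = dn[[3]], KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  out$value <- as.vector(a)
  out[order(out$sample_id, out$condition, match(out$variable, dn[[3]])), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Simulate a two-family study sharing the F1 parent
#'
#' Draws the shared F1 parent genome once and crosses it with each of the
#' two line parents, yielding two half-sib families of configurable sizes
#' (default 74 and 119).
#'
#' @param config a [sim_config()]; its `n_individuals` is overridden
#'   per family by `n_individuals`.
#' @param n_individuals length-2 integer vector of family sizes.
#' @param family_ids labels for the two families.
#' @return list of two family objects as returned by [simulate_family()].
#' @export
simulate_study <- function(config, n_individuals = c(74L, 119L),
                           family_ids = c("H1xA", "H1xB")) {
  stopifnot(inherits(config, "sim_config"))
  shared <- with_seed(derive_seed(config$seed, 0L),
                      sim_parent_genome(config$n_markers,
                                        config$parent_heterozygosity[1]))
  fams <- lapply(1:2, function(i) {
    cfg_i <- config
    cfg_i$n_individuals <- as.integer(n_individuals[i])
    simulate_family(cfg_i, line_parent = i, shared_parent = shared,
                    family_id = family_ids[i], seed_offset = i)
  })
  names(fams) <- family_ids
  fams
}

#' Inject missing genotype calls
#'
#' Sets entries of a genotype matrix to `NA` independently at the
#' background rate, and raises the rate for a chosen fraction of samples
#' (so the downstream sample-missingness filter has work to do).
#'
#' @param genotypes samples x markers matrix of 0/1/2 codes.
#' @param config a [sim_config()] providing `missing_rate_markers`,
#'   `missing_rate_samples`, `high_missing_rate` and `seed`.
#' @param seed_offset stream offset (default 99).
#' @return the matrix with `NA`s injected.
#' @export
inject_missingness <- function(genotypes, config, seed_offset = 99L) {
  stopifnot(inherits(config, "sim_config"))
  r <- config$missing_rate_markers
  with_seed(derive_seed(config$seed, seed_offset), {
    n <- nrow(genotypes); p <- ncol(genotypes)
    out <- genotypes
    storage.mode(out) <- "double"
    if (r > 0)
      out[matrix(runif(n * p) < r, n, p)] <- NA
    n_high <- floor(config$missing_rate_samples * n)
    if (n_high > 0 && config$high_missing_rate > 0) {
      rows <- sample.int(n, n_high)
      mask <- matrix(runif(n_high * p) < config$high_missing_rate, n_high, p)
      out[rows, ][mask] <- NA
    }
    out
  })
}

#' Heritability realized by a simulated family
#'
#' Empirical counterpart of the configured broad-sense heritability:
#' plugs the realized (sample) variance components of a simulated family
#' into the multi-environment heritability formula. Used as the ground
#' truth when checking variance-component recovery.
#'
#' @param truth the `sim_truth` of a simulated family.
#' @param traits the matching tidy trait panel.
#' @return named numeric vector of per-trait realized heritabilities.
#' @export
realized_h2 <- function(truth, traits) {
  stopifnot(inherits(truth, "sim_truth"))
  e <- truth$n_conditions
  trait_names <- colnames(truth$g)
  out <- vapply(seq_along(trait_names), function(t) {
    tn <- trait_names[t]
    obs <- traits[traits$variable == tn, ]
    assert_that(nrow(obs) > 0, "traits panel does not match truth")
    vG <- var(truth$g[, t])
    vE <- var(truth$condition_effects[, t])
    vGxE <- var(as.vector(truth$gxe[, , t]))
    resid <- vapply(seq_len(nrow(obs)), function(i) {
      ci <- match(obs$condition[i], as.integer(rownames(truth$condition_effects)))
      obs$value[i] - truth$g[obs$sample_id[i], t] -
        truth$condition_effects[ci, t] - truth$gxe[obs$sample_id[i], ci, t]
    }, numeric(1))
    vEps <- var(resid)
    tot <- vG + vE + vGxE + vEps
    assert_that(tot > 0, "degenerate simulation: zero total variance")
    broad_sense_h2(variance_components(vG, vE, vGxE, vEps, e))
  }, numeric(1))
  names(out) <- trait_names
  out
}
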