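#' Variance components of a multi-environment trait
#'
#' Container for the genetic (G), environment (E), genotype-by-environment
#' (GxE) and residual variance components of a trait measured in `e`
#' environments. Negative inputs (as can arise from method-of-moments
#' estimators) are truncated to zero and flagged.
#'
#' @param var_G,var_E,var_GxE,var_eps variance components.
#' @param e number of environments (integer >= 1).
#' @param gxe_confounded flag set by [estimate_variance_components()] when
#'   the design has one observation per genotype-environment cell, in
#'   which case GxE and residual variance are not separately identifiable
#'   (their sum, and hence heritability, still is).
#' @return object of class `variance_components`.
#' @export
variance_components <- function(var_G, var_E, var_GxE, var_eps, e,
                                gxe_confounded = FALSE) {
  v <- c(var_G = var_G, var_E = var_E, var_GxE = var_GxE, var_eps = var_eps)
  truncated <- v < 0
  v[truncated] <- 0
  assert_that(e >= 1, "e must be a positive integer")
  structure(list(var_G = v[["var_G"]], var_E = v[["var_E"]],
                 var_GxE = v[["var_GxE"]], var_eps = v[["var_eps"]],
                 e = as.integer(e), truncated = any(truncated),
                 gxe_confounded = isTRUE(gxe_confounded)),
            class = "variance_components")
}

#' Broad-sense heritability under the multi-environment variance partition
#'
#' Computes
#' \deqn{H^2 = \frac{\sigma_G^2}{\sigma_G^2 + \sigma_E^2 +
#'   \sigma_{G\times E}^2/e + \sigma_\epsilon^2/e},}
#' the proportion of phenotypic variance attributable to genetic effects
#' when a genotype's performance is averaged over `e` environments. Note
#' that the environment variance enters undivided in this convention; the
#' more common line-mean form that omits \eqn{\sigma_E^2} from the
#' denominator is available via `include_env = FALSE`.
#'
#' @param vc a [variance_components()] object.
#' @param include_env keep \eqn{\sigma_E^2} in the denominator
#'   (default `TRUE`, the primary convention here).
#' @return heritability in \[0,1\].
#' @export
#' @examples
#' broad_sense_h2(variance_components(1, 1, 0.6, 0.6, e = 3)) # 0.41667
broad_sense_h2 <- function(vc, include_env = TRUE) {
  stopifnot(inherits(vc, "variance_components"))
  denom <- vc$var_G + (if (include_env) vc$var_E else 0) +
    vc$var_GxE / vc$e + vc$var_eps / vc$e
  assert_that(denom > 0, "zero total variance: degenerate data")
  vc$var_G / denom
}

#' Estimate variance components by REML
#'
#' Fits the intercept-only linear mixed model
#' `value ~ 1 + (1|genotype) + (1|condition) + (1|genotype:condition)`
#' by restricted maximum likelihood (via \pkg{lme4}) and returns the
#' genetic, environment, GxE and residual variance components. When the
#' design has at most one observation per genotype-condition cell the
#' interaction is dropped (it is confounded with the residual); the
#' returned object then carries `gxe_confounded = TRUE`, `var_GxE = 0`,
#' and the GxE+residual sum in `var_eps`. Heritability from
#' [broad_sense_h2()] is unaffected because both terms are scaled by
#' `1/e`.
#'
#' @param data data frame with columns `sample_id` (genotype),
#'   `condition`, `value`; or a tidy panel from which one `variable` is
#'   selected via `trait`.
#' @param trait optional trait name selecting rows where
#'   `data$variable == trait`.
#' @return a [variance_components()] object.
#' @export
estimate_variance_components <- function(data, trait = NULL) {
  if (!is.null(trait)) {
    assert_that("variable" %in% names(data), "data has no 'variable' column")
    data <- data[data$variable == trait, , drop = FALSE]
    assert_that(nrow(data) > 0, paste("no rows for trait", trait))
  }
  assert_that(all(c("sample_id", "condition", "value") %in% names(data)),
              "data must have sample_id, condition, value columns")
  d <- data.frame(g = factor(data$sample_id), c = factor(data$condition),
                  value = as.double(data$value))
  assert_that(nlevels(d$g) >= 2, "need at least two genotypes")
  assert_that(nlevels(d$c) >= 2, "need at least two conditions")
  assert_that(nrow(d) > nlevels(d$g),
              "one observation per genotype: fully confounded design")
  e <- nlevels(d$c)
  replicated <- any(table(d$g, d$c) > 1)
  if (var(d$value) == 0)
    return(variance_components(0, 0, 0, 0, e,
                               gxe_confounded = !replicated))
  # deterministic additive data (zero residual) breaks the REML fit;
  # use the exact moment decomposition instead
  g_eff <- tapply(d$value, d$g, mean) - mean(d$value)
  c_eff <- tapply(d$value, d$c, mean) - mean(d$value)
  resid_add <- d$value - mean(d$value) -
    g_eff[as.character(d$g)] - c_eff[as.character(d$c)]
  if (var(resid_add) < 1e-12 * var(d$value))
    return(variance_components(var(g_eff), var(c_eff), 0, 0, e,
                               gxe_confounded = !replicated))
  form <- if (replicated)
    value ~ 1 + (1 | g) + (1 | c) + (1 | g:c)
  else
    value ~ 1 + (1 | g) + (1 | c)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = d,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(grp) {
    i <- which(vc$grp == grp)
    if (length(i)) vc$vcov[i[1]] else 0
  }
  variance_components(var_G = getv("g"), var_E = getv("c"),
                      var_GxE = if (replicated) getv("g:c") else 0,
                      var_eps = getv("Residual"), e = e,
                      gxe_confounded = !replicated)
}

#' Genomic BLUP genetic effects per trait and condition
#'
#' For every (variable, condition) combination in a tidy panel, fits the
#' marker-based ridge mixed model (see [fit_gblup()]) and returns the
#' per-individual genetic values (genomic BLUPs). Used both for the
#' target traits and, symmetrically, for the ChlF parameters.
#'
#' @param genotypes QC'd, imputed samples x markers matrix.
#' @param panel tidy data frame `sample_id, condition, variable, value`.
#' @param variables subset of variables (default: all in the panel).
#' @return object of class `genetic_effects`: a samples x
#'   (variable_condition) matrix `effects` plus the variable/condition
#'   index.
#' @export
genetic_effects <- function(genotypes, panel, variables = NULL) {
  vars <- variables %||% unique(panel$variable)
  conds <- sort(unique(panel$condition))
  ids <- rownames(genotypes)
  cols <- list()
  for (v in vars) for (cc in conds) {
    sub <- panel[panel$variable == v & panel$condition == cc, ]
    sub <- sub[match(ids, sub$sample_id), ]
    assert_that(!anyNA(sub$value),
                paste0("panel incomplete for ", v, " condition ", cc))
    fit <- fit_gblup(genotypes, sub$value)
    cols[[paste0(v, "_", cc)]] <- fit$u
  }
  eff <- do.call(cbind, cols)
  rownames(eff) <- ids
  structure(list(effects = eff,
                 index = expand.grid(condition = conds, variable = vars,
                                     KEEP.OUT.ATTRS = FALSE,
                                     stringsAsFactors = FALSE)),
            class = "genetic_effects")
}

#' Genetic correlation matrix between two sets of genetic effects
#'
#' Pearson correlations between genomic-BLUP genetic-effect vectors, the
#' operational definition of genetic correlation here. With 3 traits, 18
#' ChlF parameters and 3 conditions this is the 9 x 54 matrix pairing
#' every trait-condition with every ChlF-parameter-condition. Entries
#' where either effect vector has zero variance are `NA`.
#'
#' @param ge,ge2 `genetic_effects` objects sharing sample ids (`ge2`
#'   defaults to `ge` for a within-set matrix).
#' @return correlation matrix with `variable_condition` dimnames.
#' @export
genetic_correlation_matrix <- function(ge, ge2 = ge) {
  stopifnot(inherits(ge, "genetic_effects"), inherits(ge2, "genetic_effects"))
  A <- ge$effects; B <- ge2$effects
  assert_that(identical(rownames(A), rownames(B)),
              "genetic effects must share sample ids")
  out <- matrix(NA_real_, ncol(A), ncol(B),
                dimnames = list(colnames(A), colnames(B)))
  sdA <- apply(A, 2, sd); sdB <- apply(B, 2, sd)
  ok_a <- sdA > 0; ok_b <- sdB > 0
  if (any(ok_a) && any(ok_b))
    out[ok_a, ok_b] <- cor(A[, ok_a, drop = FALSE], B[, ok_b, drop = FALSE])
  out
}

#' Two-sample Hotelling's T-squared test
#'
#' Compares the mean vectors of two samples of multivariate performance
#' vectors (e.g. per-method mean predictabilities of two families) using
#' the pooled-covariance T-squared statistic and its exact F
#' transformation.
#'
#' @param a,b matrices with observations in rows and the same variables
#'   in columns.
#' @return list with `statistic` (T2), `f`, `df1`, `df2`, `p_value`.
#' @export
hotelling_t2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  assert_that(ncol(a) == ncol(b), "samples must share dimension")
  n1 <- nrow(a); n2 <- nrow(b); p <- ncol(a)
  assert_that(p < n1 + n2 - 2,
              "dimension too large for the combined sample size (singular pooled covariance)")
  m1 <- colMeans(a); m2 <- colMeans(b)
  S <- ((n1 - 1) * stats::cov(a) + (n2 - 1) * stats::cov(b)) / (n1 + n2 - 2)
  d <- m1 - m2
  t2 <- as.numeric((n1 * n2) / (n1 + n2) * crossprod(d, solve(S, d)))
  df1 <- p
  df2 <- n1 + n2 - p - 1
  f <- t2 * df2 / (df1 * (n1 + n2 - 2))
  list(statistic = t2, f = f, df1 = df1, df2 = df2,
       p_value = pf(f, df1, df2, lower.tail = FALSE))
}
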