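---
title: "Genomic versus phenomic prediction in three-way hybrid families: models and design"
author: "phenogp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic versus phenomic prediction in three-way hybrid families: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`phenogp` is a comparative toolkit for **genomic prediction** (GP, SNP
markers as predictors) versus **phenomic prediction** (PP,
chlorophyll-*a*-fluorescence endophenotypes as predictors) of
growth-related traits — leaf count (LC), tree height (TH), trunk
diameter (TD) — in segregating three-way hybrid (H3W) coffee families.
Two half-sib families share a highly heterozygous, clonally propagated
F1 parent crossed with one of two largely homozygous landrace lines.
Plants pass through a sequence of treatment conditions (full sun,
50% shade mimicking an agroforestry system, high-altitude full sun);
traits and 18 fast-induction ChlF parameters are recorded per plant
and condition.

Because no real dataset ships with the package, a synthetic-data
generator with fully known genetic architecture is a first-class
module: every downstream estimator can be checked against ground
truth.

# The synthetic-data generator

## Cross structure

Parental genomes are drawn per site as additive codes in $\{0,1,2\}$
with heterozygous-site frequencies 0.84 (shared F1 parent) and
0.14/0.12 (line parents), matching the relative heterozygosity levels
reported for such material. Each offspring receives one random gamete
from each parent; sites segregate independently. **No linkage or LD
model is imposed** — the underlying study gives no genetic map — which
is a documented limitation: marker-trait association decay, haplotype
structure and LD-based shrinkage behavior of real panels are not
emulated, so passing tests demonstrate correctness of the estimators,
not their field performance.

## Traits

For trait $t$ of individual $i$ in condition $c$,

$$y_{ict} = g_{it} + E_{ct} + (G{\times}E)_{ict} + \varepsilon_{ict},$$

where $g = X_c\beta$ is driven by `n_qtl` causal markers (effects
rescaled so the realized genetic variance equals `var_G` exactly),
$E_{ct}\sim N(0,\sigma^2_E)$ is drawn once per condition,
$(G{\times}E)_{ict}$ i.i.d. normal per individual-condition, and
$\varepsilon$ i.i.d. residual noise. Defaults
$(\sigma^2_G,\sigma^2_E,\sigma^2_{G\times E},\sigma^2_\varepsilon) =
(1, 1, 0.6, 0.6)$ give a broad-sense heritability of 0.42 under the
three-condition design, inside the range reported for growth traits in
this material (up to 0.62–0.77 for TH).

## ChlF endophenotypes

Each ChlF parameter $k$ has a genetic component
$f_k = \sum_t \rho_{tk}\, z_t + \sqrt{1-\sum_t\rho_{tk}^2}\; u_k$,
where $z_t$ is the standardized trait genetic value and $u_k$ an
independent marker-driven genetic background (its own QTL set), so the
genetic correlation between parameter $k$ and trait $t$ equals
$\rho_{tk}$ in expectation. Observed values add a per-condition shift
(sd 0.7) and heavy measurement noise (sd 3), which puts default ChlF
broad-sense heritability near 0.22 — deliberately low, as observed for
most ChlF parameters, while trait–ChlF genetic correlations remain
nonzero (default $\rho = 0.35$ for one parameter per trait, echoing
the 0.35/0.38 maxima reported in this system). The generator emits one
value per plant, condition and parameter; measurement replicates
within nights are considered pre-averaged.

# Genotype quality control

Markers with minor allele frequency strictly below 5% (computed on
non-missing calls, folded to $\le 0.5$) or call rate strictly below
95% are removed; samples with strictly more than 10% missing calls or
without phenomic/trait records are removed; remaining missing calls
are mean-imputed per marker (real-valued, not rounded). Filters run
markers → samples → markers: sample removal changes call rates, and a
second marker pass stabilizes the panel. Boundary conventions are
strict inequalities, so MAF exactly 0.05 and missingness exactly 10%
survive.

# The seven prediction models

All penalized objectives use the **unscaled convention**

$$\hat b = \arg\min_b \|y - Xb\|^2 + \lambda_1\|b\|^2 + \lambda_2\|b\|_1,$$

i.e. penalties are not divided by $n$; exposed $\lambda$ values live on
this scale. Predictors are standardized by default (training-split
statistics only), and coefficients are always mapped back to the
original predictor scale with an explicit intercept.

* **RR** — ridge regression, closed form via SVD (a whole $\lambda$
  path costs one factorization).
* **mLASSO** — multi-response LASSO with elementwise $L_1$ penalty;
  the problem separates over response columns and is solved by
  coordinate descent with an active-set strategy. Under the unscaled
  convention the soft-threshold level is $\lambda/2$ and the null
  solution appears at $\lambda_{\max} = 2\max|X^\top y|$.
* **EN** — elastic net, $\lambda_1$ on the ridge and $\lambda_2$ on
  the lasso term, same coordinate descent.
* **GBLUP** — mixed model $y = 1\mu + Zu + e$ with
  $\mathrm{var}(Zu) = K\sigma^2_u$, $K = ZZ^\top$ built from the
  column-centered marker matrix (a `scale_k` switch divides by the
  marker count; the variance ratio, hence predictions, are invariant).
  The variance ratio is profiled by REML on the spectrum of the
  intercept-projected $K$; new samples are predicted through the
  cross-relationship block. A $10^{-8}$ diagonal ridge guards singular
  $K$. GP only — GBLUP is not applied to ChlF predictors.
* **BL** — Bayesian LASSO: double-exponential priors via the
  normal–exponential scale mixture, Gibbs sampling with single-site
  coefficient updates, inverse-Gaussian mixing-variance updates, a
  scaled-inverse-$\chi^2$ residual variance, and a Gamma(1, 1)
  hyperprior on the squared regularization parameter. Default chain
  20,000 iterations with 5,000 burn-in; a desk-scale profile
  (2,000/500) is used in tests, where posterior summaries are already
  stable.
* **mBayesB** — multi-trait BayesB: each locus carries one inclusion
  indicator per trait (all $2^t$ patterns admissible); effect vectors
  are multivariate normal with a locus-specific covariance under an
  inverse-Wishart prior (df $t+4$, scale $0.1 I$), the residual
  covariance has its own inverse-Wishart prior, and the prior
  inclusion probability is $\pi = 0.05$ (all config-exposed).
  Indicator and effect are updated jointly per (locus, trait) with the
  effect integrated out of the inclusion odds; the locus covariance is
  carried as a precision matrix whose Wishart full-conditional scale
  comes from the Sherman–Morrison identity, avoiding per-locus matrix
  inversions.
* **L21-joint** — multivariate regression with a row-wise $L_{2,1}$
  penalty on $B$ (shared variable selection across traits) and an
  $L_1$-penalized precision matrix $\Omega$ of the residuals:

  $$J(B,\Omega) = \tfrac1s\,\mathrm{tr}\!\left[(Y-XB)\,\Omega\,(Y-XB)^\top\right]
    - \log|\Omega| + \lambda_1\|\Omega\|_1 + \lambda_2\|B\|_{2,1}.$$

  Here $s$ is the **training sample count** (the source leaves $s$
  undefined; this reading is fixed and documented rather than guessed
  silently elsewhere), and $\|\Omega\|_1$ penalizes **all** entries as
  printed. Alternating minimization: a FISTA proximal-gradient B-step
  with monotone backtracking (gradient formed as
  $X^\top((XB-Y)\Omega)$, linear in $p$), then a G-ISTA
  proximal-gradient step for $\Omega$ on the residual scatter
  (ridged by $10^{-8}$ if not positive definite). Both sub-solvers are
  descent methods, so the joint objective is non-increasing; the outer
  loop stops at relative decrease $10^{-6}$ or 500 iterations
  (defaults). With $\lambda_2 = 0$ the B-step is solved exactly
  ($\Omega$ drops out of the argmin), and with $\Omega$ frozen at $I$
  and zero penalties the fit is per-trait least squares. The graphical
  $\Omega$ step is written in-house as a proximal-gradient solver —
  the trait dimension never exceeds nine, so a tiny dense solver is the
  appropriate tool — and is cross-checked in the tests against an
  independent ADMM solver.

Variance components for heritability are fitted with **lme4** (the
standard REML engine for this model class); the genomic BLUP machinery
behind genetic effects is the package's own.

# Evaluation design

* **Predictability** is the Pearson correlation between observed and
  predicted trait values in a validation set, reported `NA` when
  either side has zero standard deviation (e.g. a fully shrunk LASSO
  predicting a constant).
* **Settings.** S1: responses and ChlF concatenated over the three
  post-acclimation conditions (9 responses, 54 ChlF predictors); S2:
  single condition (default the shade/agroforestry one); S2aug: S2
  responses with ChlF from all conditions (54 predictors); S3:
  condition-ahead — train on one condition without the first 20
  samples (stored input order by default; a seeded permutation option
  exists since input order is arbitrary), predict those 20 samples'
  traits in the next condition; S4: train on one family, test on the
  other (marker columns intersected; both directions reported).
* **S3 ChlF predictors for the held-out lines** come from the *test*
  condition by default: condition-specific ChlF is precisely what lets
  PP adapt across environments, and at prediction time the new
  condition's ChlF is observable while its traits are not. A
  `chlf_test_from = "train"` option gives the conservative variant.
  SNP predictors are identical across conditions (genotyping happens
  once).
* **Nested cross-validation.** Outer 3-fold, inner 3-fold on the
  training part for hyperparameter selection by mean validation
  predictability, refit at the chosen value, scored on the outer test
  fold; 20 repetitions by default. Aggregation averages per-trait
  predictabilities within a fold, then over folds, then over
  repetitions; repetitions yielding `NA` are excluded from means and
  counted. Hyperparameter grids: 20 log-spaced points on
  $[10^{-4}\lambda_{\max}, \lambda_{\max}]$; the EN grid crosses that
  with 5 mixing levels; L21-joint crosses a small $\lambda_1$ set with
  a log-spaced $\lambda_2$ path. Grid fits are warm-started along the
  path.
* **Selection ability**: the percentage of the truly best (worst) 20
  lines, ranked on line means over conditions, that the model's
  out-of-fold predictions place in its predicted best (worst) 20; ties
  break by stable sample order.
* **Family comparison**: two-sample Hotelling's $T^2$ with pooled
  covariance and the exact F transform, applied to the two families'
  method-by-trait mean-predictability matrices (each method–source
  combination contributes one observation; which matrix enters the
  test is underdetermined in the source and this choice is fixed
  here).
* Every split asserts an empty train/test id intersection, and the
  whole pipeline is bit-reproducible from one seed: partition seeds
  and sampler streams are derived deterministically (all derived seeds
  stay below $2^{31}$).

# Numerical choices and degenerate inputs

* Constant responses: GBLUP returns zero variance components and
  predicts the constant; correlation-based scores return `NA`.
* Markers with no observed calls are removed by the call-rate rule;
  columns that survive QC always have observed means for imputation.
* The heritability denominator follows the printed multi-environment
  convention $\sigma^2_G + \sigma^2_E + \sigma^2_{G\times E}/e +
  \sigma^2_\varepsilon/e$ with $\sigma^2_E$ *undivided*; since that
  form is unusual, `include_env = FALSE` gives the conventional
  line-mean variant. With one observation per genotype–condition cell
  (the generator's design), $\sigma^2_{G\times E}$ and
  $\sigma^2_\varepsilon$ are not separately identifiable; the fit then
  drops the interaction, flags the pooling, and heritability is
  unaffected because both terms enter scaled by $1/e$.
* Genetic correlations are Pearson correlations of genomic-BLUP
  effect vectors. Such estimates attenuate by roughly the product of
  the two BLUP accuracies; with many more markers than samples and
  noisy endophenotypes the attenuation is severe. The package's
  recovery experiments therefore run in an identifiable regime
  (samples exceeding markers, moderated ChlF noise with the
  low-heritability character preserved through large condition
  variance); under the default desk-scale study the same estimator is
  expected to understate the configured loadings. The phenotypic
  (non-BLUP) correlation reading is available by correlating the
  panels directly.

# Problem sizes

Desk-scale defaults keep the full pipeline fast: families of 74 and
119 individuals, 2,000 markers, three conditions, 18 ChlF parameters.
Test and example runs use 2 cross-validation repetitions, Bayesian
chains of 400–2,000 iterations, and compact hyperparameter grids;
production analyses should restore 20 repetitions and the 20,000/5,000
Bayesian chain defaults.

# Known limitations

* No linkage map, dominance, epistasis, or pedigree beyond the single
  three-way cross; no population-structure correction.
* One observation per plant–condition: G×E and residual variance are
  pooled (see above).
* The mBayesB hyperpriors are defaults of this implementation, not
  values fixed by the source material; results at small $n$ are
  sensitive to $\pi$.
* Hotelling's $T^2$ treats methods as independent observations of
  family performance; correlated methods make the test
  anti-conservative, so its p-value is a descriptive summary here.
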