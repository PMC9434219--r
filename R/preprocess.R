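# Genotype quality control: marker filters, sample filters, mean
# imputation, and the combined QC driver. Genotypes are plain numeric
# matrices (samples x markers, additive 0/1/2 codes, NA = missing) with
# sample ids as row names and marker ids as column names.

marker_maf <- function(g) {
  af <- colMeans(g, na.rm = TRUE) / 2
  af[is.nan(af)] <- 0 # no observed calls: monomorphic by convention
  pmin(af, 1 - af)
}

marker_callrate <- function(g) colMeans(!is.na(g))

new_qc_report <- function(axis, n_in, n_out, removed) {
  structure(list(axis = axis, n_in = n_in, n_out = n_out,
                 removed = removed,
                 n_imputed = 0L),
            class = "qc_report")
}

#' Filter markers on minor allele frequency and call rate
#'
#' Removes markers with MAF strictly below `maf_min` (allele frequency
#' computed on non-missing calls as `mean(code)/2`, folded to <= 0.5) or
#' call rate strictly below `callrate_min`. A marker with MAF exactly at
#' the threshold is kept. Markers with no observed calls fall to the
#' call-rate rule.
#'
#' @param g samples x markers genotype matrix with `NA` missing codes.
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param callrate_min minimum call rate (default 0.95).
#' @return list with the filtered `genotypes` and a `report` recording
#'   removed marker ids and reasons (`maf` or `callrate`).
#' @export
filter_markers <- function(g, maf_min = 0.05, callrate_min = 0.95) {
  g <- as.matrix(g)
  assert_that(all(g %in% c(0, 1, 2) | is.na(g)),
              "genotype codes must be 0/1/2 or NA")
  cr <- marker_callrate(g)
  maf <- marker_maf(g)
  bad_cr <- cr < callrate_min
  bad_maf <- !bad_cr & maf < maf_min
  reason <- ifelse(bad_cr, "callrate", ifelse(bad_maf, "maf", NA))
  keep <- !(bad_cr | bad_maf)
  removed <- data.frame(id = colnames(g)[!keep],
                        reason = as.character(reason[!keep]),
                        stringsAsFactors = FALSE)
  rep <- new_qc_report("marker", ncol(g), sum(keep), removed)
  list(genotypes = g[, keep, drop = FALSE], report = rep)
}

#' Filter samples on genotype missingness and panel matching
#'
#' Removes samples whose fraction of missing genotype calls is strictly
#' greater than `max_missing` (a sample at exactly the threshold is kept)
#' and samples without a record in the phenomic or trait panel. The order
#' of the surviving samples is preserved.
#'
#' @param g samples x markers genotype matrix.
#' @param phenomic,traits tidy panels (`sample_id, condition, variable,
#'   value`) used for matching; pass `NULL` to skip the matching rule.
#' @param max_missing maximum tolerated missing fraction (default 0.10).
#' @return list with the filtered `genotypes` and a `report` recording
#'   removed sample ids and reasons (`missingness` or `unmatched`).
#' @export
filter_samples <- function(g, phenomic = NULL, traits = NULL,
                           max_missing = 0.10) {
  g <- as.matrix(g)
  miss <- rowMeans(is.na(g))
  bad_miss <- miss > max_missing
  unmatched <- rep(FALSE, nrow(g))
  if (!is.null(phenomic))
    unmatched <- unmatched | !(rownames(g) %in% phenomic$sample_id)
  if (!is.null(traits))
    unmatched <- unmatched | !(rownames(g) %in% traits$sample_id)
  reason <- ifelse(bad_miss, "missingness",
                   ifelse(unmatched, "unmatched", NA))
  keep <- !(bad_miss | unmatched)
  assert_that(any(keep), "no samples survive filtering: check id matching")
  removed <- data.frame(id = rownames(g)[!keep],
                        reason = as.character(reason[!keep]),
                        stringsAsFactors = FALSE)
  rep <- new_qc_report("sample", nrow(g), sum(keep), removed)
  list(genotypes = g[keep, , drop = FALSE], report = rep)
}

#' Mean-impute missing genotype calls
#'
#' Replaces each missing entry by the mean of its marker's non-missing
#' calls (real-valued; codes are not rounded). Markers without any
#' observed call cannot be imputed and must have been removed upstream by
#' the call-rate filter.
#'
#' @param g samples x markers genotype matrix.
#' @return list with the imputed `genotypes` (no `NA` left) and the
#'   number of imputed entries `n_imputed`.
#' @export
impute_mean <- function(g) {
  g <- as.matrix(g)
  storage.mode(g) <- "double"
  nmiss <- sum(is.na(g))
  if (nmiss > 0) {
    mu <- colMeans(g, na.rm = TRUE)
    assert_that(!anyNA(mu) && !any(is.nan(mu)),
                "marker with no observed calls cannot be imputed")
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- mu[idx[, 2]]
  }
  list(genotypes = g, n_imputed = nmiss)
}

#' Run the full genotype QC pipeline
#'
#' Applies the marker filters, then the sample filters, then re-checks
#' the markers once (sample removal can change call rates and allele
#' frequencies), and finally mean-imputes what is left.
#'
#' @inheritParams filter_markers
#' @inheritParams filter_samples
#' @return list with imputed `genotypes` and `report`, a `qc_summary`
#'   holding the per-stage reports, overall in/out counts and the imputed
#'   entry count.
#' @export
run_qc <- function(g, phenomic = NULL, traits = NULL,
                   maf_min = 0.05, callrate_min = 0.95, max_missing = 0.10) {
  s1 <- filter_markers(g, maf_min, callrate_min)
  s2 <- filter_samples(s1$genotypes, phenomic, traits, max_missing)
  s3 <- filter_markers(s2$genotypes, maf_min, callrate_min)
  imp <- impute_mean(s3$genotypes)
  report <- structure(list(
    n_markers_in = ncol(as.matrix(g)),
    n_markers_out = ncol(imp$genotypes),
    n_samples_in = nrow(as.matrix(g)),
    n_samples_out = nrow(imp$genotypes),
    removed_markers = rbind(s1$report$removed, s3$report$removed),
    removed_samples = s2$report$removed,
    n_imputed = imp$n_imputed
  ), class = "qc_summary")
  list(genotypes = imp$genotypes, report = report)
}

#' @exportS3Method base::print
print.qc_summary <- function(x, ...) {
  cat("Genotype QC summary\n")
  cat(sprintf("  markers: %d in, %d removed, %d out\n", x$n_markers_in,
              nrow(x$removed_markers), x$n_markers_out))
  cat(sprintf("  samples: %d in, %d removed, %d out\n", x$n_samples_in,
              nrow(x$removed_samples), x$n_samples_out))
  cat(sprintf("  imputed entries: %d\n", x$n_imputed))
  invisible(x)
}
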