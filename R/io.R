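# Reading and writing the package's on-disk formats: genotype matrices
# as tab-delimited text or minimal VCF, tidy panels as CSV, simulation
# truth as JSON.

#' Write / read a genotype matrix as tab-delimited text
#'
#' Rows are samples, columns are markers (header row of marker ids,
#' first column `sample_id`), missing calls written as `NA`.
#'
#' @param g samples x markers matrix.
#' @param path output file.
#' @export
write_genotypes_tsv <- function(g, path) {
  df <- data.frame(sample_id = rownames(g), g, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_genotypes_tsv
#' @return for the reader, the genotype matrix.
#' @export
read_genotypes_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  g <- as.matrix(df[, -1, drop = FALSE])
  rownames(g) <- df[[1]]
  storage.mode(g) <- "double"
  g
}

#' Write / read a genotype matrix as a minimal VCF
#'
#' One synthetic contig, diploid unphased GT field only; additive codes
#' 0/1/2 map to `0/0`, `0/1`, `1/1` and missing to `./.`. Reading
#' requires the \pkg{vcfR} package.
#'
#' @param g samples x markers matrix of 0/1/2/NA codes.
#' @param path file path.
#' @export
write_genotypes_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=1>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(g)),
                     collapse = "\t")), con)
  gt_map <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(g))) {
    codes <- g[, j]
    gt <- ifelse(is.na(codes), "./.", gt_map[codes + 1])
    writeLines(paste(c("1", j, colnames(g)[j], "A", "T", ".", "PASS",
                       ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_genotypes_vcf
#' @return for the reader, the samples x markers matrix of additive
#'   codes with `NA` for missing calls.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  codes <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  codes[clean == "0/0"] <- 0
  codes[clean %in% c("0/1", "1/0")] <- 1
  codes[clean == "1/1"] <- 2
  t(codes)
}

#' Write / read a tidy panel as CSV
#'
#' Tidy long format with columns `sample_id, condition, variable, value`,
#' as produced by [simulate_family()] for both the ChlF and trait panels.
#'
#' @param panel tidy data frame.
#' @param path file path.
#' @export
write_panel_csv <- function(panel, path) {
  write.csv(panel, path, row.names = FALSE)
}

#' @rdname write_panel_csv
#' @return for the reader, the tidy data frame.
#' @export
read_panel_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize simulation ground truth to JSON
#'
#' @param truth a `sim_truth` object.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(marker_effects = truth$marker_effects,
         g = truth$g,
         condition_effects = truth$condition_effects,
         variance_components_true = truth$variance_components_true,
         h2_true = as.list(truth$h2_true),
         family_id = truth$family_id),
    path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Serialize a fit result to JSON
#'
#' Coefficients, intercepts, chosen hyperparameters and available
#' diagnostics of any `gs_fit`.
#'
#' @param fit a `gs_fit`.
#' @param path file path.
#' @export
write_fit_json <- function(fit, path) {
  out <- list(method = fit$method, B = fit$B,
              intercept = as.list(fit$intercept), hyper = fit$hyper)
  for (nm in intersect(c("Omega", "inclusion", "objective", "iterations",
                         "converged", "sigma2", "lambda2"), names(fit)))
    out[[nm]] <- fit[[nm]]
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
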