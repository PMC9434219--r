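# Report assembly and the end-to-end pipeline driver.

#' Out-of-fold cross-validated predictions on a setting block
#'
#' One K-fold pass: every sample is predicted by a model trained on the
#' folds it does not belong to (hyperparameters selected by the inner
#' loop on each training split). Used for selection-ability scoring,
#' where every line needs a predicted value.
#'
#' @param block a `setting_block` without a test side.
#' @param method a [gs_method()] or method id.
#' @param scheme a [cv_scheme()].
#' @param repetition which repetition's partition to use (default 1).
#' @return samples x responses matrix of out-of-fold predictions.
#' @export
cv_predictions <- function(block, method, scheme = cv_scheme(),
                           repetition = 1) {
  stopifnot(inherits(block, "setting_block"))
  if (is.character(method)) method <- gs_method(method)
  check_method_source(method, block$source)
  X <- block$X; Y <- block$Y
  ids <- rownames(X)
  pred <- matrix(NA_real_, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  with_seed(derive_seed(scheme$seed, 600000L + repetition), {
    folds <- kfold_partition(ids, scheme, repetition)
    for (f in seq_along(folds)) {
      tr <- !(ids %in% folds[[f]])
      hyper <- if (scheme$nested)
        select_hyper(method, X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                     scheme, repetition * 100L + f)
      else list()
      fit <- method$fit(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], hyper)
      pred[!tr, ] <- predict(fit, X[!tr, , drop = FALSE])
    }
  })
  pred
}

#' Selection-ability table for one setting block
#'
#' Computes, per method and trait, the percentage of the truly best and
#' worst `n_selected` lines that the model's out-of-fold predictions
#' rank among the predicted best and worst. Lines are scored by their
#' mean observed (and mean predicted) value over the block's conditions,
#' i.e. selection on line means.
#'
#' @param block a `setting_block` (S1-style concatenated responses).
#' @param methods method ids or [gs_method()]s.
#' @param scheme a [cv_scheme()].
#' @param n_selected lines retained on each side (default 20).
#' @param traits trait base names (default: deduced by stripping the
#'   condition suffix from response columns).
#' @return data frame with columns method, trait, direction, proportion.
#' @export
selection_ability_table <- function(block, methods,
                                    scheme = cv_scheme(),
                                    n_selected = 20, traits = NULL) {
  methods <- normalize_methods(methods)
  base <- sub("_[0-9]+$", "", colnames(block$Y))
  traits <- traits %||% unique(base)
  rows <- list()
  for (method in methods) {
    pred <- cv_predictions(block, method, scheme)
    for (tr in traits) {
      cols <- which(base == tr)
      obs_mean <- rowMeans(block$Y[, cols, drop = FALSE])
      pred_mean <- rowMeans(pred[, cols, drop = FALSE])
      for (dir in c("best", "worst")) {
        sa <- selection_ability(obs_mean, pred_mean, n_selected, dir)
        rows[[length(rows) + 1]] <-
          data.frame(method = method$id, trait = tr, direction = dir,
                     proportion = sa$proportion,
                     stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

records_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    trait_means <- colMeans(r$per_rep_trait, na.rm = TRUE)
    trait_means[is.nan(trait_means)] <- NA_real_
    if (is.null(names(trait_means)))
      names(trait_means) <- paste0("y", seq_along(trait_means))
    detail <- if (!is.null(r$info$train_condition))
      paste0(r$info$train_condition, "to", r$info$test_condition) else ""
    data.frame(setting = r$setting, source = r$source,
               family = r$family %||% NA, method = r$method,
               detail = detail,
               trait = names(trait_means), predictability = trait_means,
               mean_overall = r$mean, se_overall = r$se,
               n_na = r$n_na, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}

#' Assemble (and optionally write) the report bundle
#'
#' Collects evaluation records into per-setting tables shaped like the
#' familiar comparative layouts (methods x traits per setting and
#' predictor source), bar-plot data (mean and standard error per
#' method), selection-ability and heritability tables, the genetic
#' correlation matrices, and run metadata. With `out_dir` set,
#' everything is written as CSV/JSON.
#'
#' @param records flat named list of `evaluation_record`s.
#' @param selection optional selection-ability data frame(s).
#' @param heritability optional heritability table.
#' @param correlations optional named list of genetic-correlation
#'   matrices.
#' @param metadata named list echoed into the report (seeds, config).
#' @param out_dir optional output directory.
#' @return list with `tables` (long data frame), `bars`, `selection`,
#'   `heritability`, `correlations`, `metadata`.
#' @export
make_report <- function(records, selection = NULL, heritability = NULL,
                        correlations = NULL, metadata = list(),
                        out_dir = NULL) {
  tab <- if (length(records)) records_table(records) else
    data.frame(setting = character(), source = character(),
               family = character(), method = character(),
               trait = character(), predictability = numeric())
  bars <- if (length(records))
    unique(tab[, c("setting", "source", "family", "method", "detail",
                   "mean_overall", "se_overall", "n_na")])
  else NULL
  metadata <- c(metadata,
                list(package_version = as.character(utils::packageVersion("phenogp")),
                     generated = format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  out <- list(tables = tab, bars = bars, selection = selection,
              heritability = heritability, correlations = correlations,
              metadata = metadata)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tab, file.path(out_dir, "predictability_long.csv"),
              row.names = FALSE)
    if (!is.null(bars))
      write.csv(bars, file.path(out_dir, "predictability_summary.csv"),
                row.names = FALSE)
    for (sett in unique(tab$setting)) {
      sub <- tab[tab$setting == sett, ]
      wide <- stats::reshape(
        sub[, c("source", "family", "method", "detail", "trait",
                "predictability")],
        direction = "wide",
        idvar = c("source", "family", "method", "detail"),
        timevar = "trait")
      names(wide) <- sub("^predictability\\.", "", names(wide))
      write.csv(wide, file.path(out_dir,
                                paste0("setting_", sett, ".csv")),
                row.names = FALSE)
    }
    if (!is.null(selection))
      write.csv(selection, file.path(out_dir, "selection_ability.csv"),
                row.names = FALSE)
    if (!is.null(heritability))
      write.csv(heritability, file.path(out_dir, "heritability.csv"),
                row.names = FALSE)
    if (!is.null(correlations))
      for (nm in names(correlations))
        write.csv(correlations[[nm]],
                  file.path(out_dir,
                            paste0("genetic_correlation_", nm, ".csv")))
    jsonlite::write_json(metadata, file.path(out_dir, "metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(out)
}

#' Run the full comparative pipeline on synthetic families
#'
#' End-to-end driver: simulate two half-sib families sharing the F1
#' parent, inject genotype missingness, run QC, estimate heritabilities
#' and trait-ChlF genetic correlations, evaluate the requested methods
#' under the requested settings with both predictor sources, score
#' selection ability, compare the two families with Hotelling's T2 on
#' their method x trait predictability matrices, and assemble the
#' report.
#'
#' @param config a [sim_config()].
#' @param n_individuals family sizes (default `c(74, 119)`).
#' @param methods method ids (default the full roster).
#' @param method_opts options passed to every [gs_method()] (chain
#'   lengths, grids).
#' @param scheme a [cv_scheme()].
#' @param settings subset of `c("S1","S2","S2aug","S3","S4")`.
#' @param heritability_chlf also estimate ChlF heritabilities
#'   (default `TRUE`).
#' @param out_dir optional report directory.
#' @return the report bundle from [make_report()], plus `qc`,
#'   `records`, `hotelling`, and the simulated `study` (invisibly).
#' @export
run_pipeline <- function(config = sim_config(),
                         n_individuals = c(74L, 119L),
                         methods = method_roster(),
                         method_opts = list(),
                         scheme = cv_scheme(seed = config$seed),
                         settings = c("S1", "S2", "S2aug", "S3", "S4"),
                         heritability_chlf = TRUE,
                         out_dir = NULL) {
  study <- simulate_study(config, n_individuals)
  fams <- names(study)

  qc <- lapply(fams, function(f) {
    g_miss <- inject_missingness(study[[f]]$genotypes, config,
                                 seed_offset = 99L + match(f, fams))
    run_qc(g_miss, study[[f]]$phenomic, study[[f]]$traits)
  })
  names(qc) <- fams

  herit <- do.call(rbind, lapply(fams, function(f) {
    vars <- unique(study[[f]]$traits$variable)
    if (heritability_chlf)
      vars <- c(vars, unique(study[[f]]$phenomic$variable))
    do.call(rbind, lapply(vars, function(v) {
      panel <- if (v %in% study[[f]]$traits$variable) study[[f]]$traits
               else study[[f]]$phenomic
      vc <- estimate_variance_components(panel, trait = v)
      data.frame(family = f, variable = v,
                 var_G = vc$var_G, var_E = vc$var_E,
                 var_GxE = vc$var_GxE, var_eps = vc$var_eps,
                 H2 = broad_sense_h2(vc), stringsAsFactors = FALSE)
    }))
  }))

  correlations <- lapply(fams, function(f) {
    ge_tr <- genetic_effects(qc[[f]]$genotypes, study[[f]]$traits)
    ge_ch <- genetic_effects(qc[[f]]$genotypes, study[[f]]$phenomic)
    genetic_correlation_matrix(ge_tr, ge_ch)
  })
  names(correlations) <- fams

  methods_obj <- lapply(methods, gs_method, opts = method_opts)
  records <- list()
  add_rec <- function(rec, name, family) {
    rec$family <- family
    records[[name]] <<- rec
  }

  for (f in fams) {
    fam <- study[[f]]
    gm <- qc[[f]]$genotypes
    for (src in c("snp", "chlf")) {
      for (sett in intersect(settings, c("S1", "S2", "S2aug"))) {
        block <- assemble_setting(sett, gm, fam$phenomic, fam$traits,
                                  predictor_source = src)
        for (m in methods_obj) {
          if (!src %in% m$sources) next
          add_rec(nested_cv_evaluate(block, m, scheme),
                  paste(f, src, sett, m$id, sep = "."), f)
        }
      }
      if ("S3" %in% settings) {
        blocks <- assemble_setting("S3", gm, fam$phenomic, fam$traits,
                                   predictor_source = src)
        ok <- Filter(function(m) src %in% m$sources, methods_obj)
        recs <- condition_ahead_evaluate(blocks, ok, scheme)
        for (nm in names(recs))
          add_rec(recs[[nm]], paste(f, src, "S3", nm, sep = "."), f)
      }
    }
  }

  if ("S4" %in% settings && length(fams) == 2) {
    for (i in 1:2) {
      f_tr <- fams[i]; f_te <- fams[3 - i]
      for (src in c("snp", "chlf")) {
        block <- assemble_setting("S4", qc[[f_tr]]$genotypes,
                                  study[[f_tr]]$phenomic,
                                  study[[f_tr]]$traits,
                                  predictor_source = src,
                                  test_family = list(
                                    genotypes = qc[[f_te]]$genotypes,
                                    phenomic = study[[f_te]]$phenomic,
                                    traits = study[[f_te]]$traits))
        ok <- Filter(function(m) src %in% m$sources, methods_obj)
        recs <- cross_family_evaluate(block, ok, scheme)
        for (nm in names(recs))
          add_rec(recs[[nm]],
                  paste(f_tr, "to", f_te, src, "S4", nm, sep = "."),
                  f_te)
      }
    }
  }

  selection <- NULL
  if ("S1" %in% settings) {
    selection <- do.call(rbind, lapply(fams, function(f) {
      do.call(rbind, lapply(c("snp", "chlf"), function(src) {
        block <- assemble_setting("S1", qc[[f]]$genotypes,
                                  study[[f]]$phenomic, study[[f]]$traits,
                                  predictor_source = src)
        ok <- Filter(function(m) src %in% m$sources, methods_obj)
        n_sel <- min(20, nrow(block$Y))
        cbind(family = f, source = src,
              selection_ability_table(block, ok, scheme, n_sel))
      }))
    }))
  }

  hot <- NULL
  if ("S1" %in% settings) {
    perf <- lapply(fams, function(f) {
      rs <- Filter(function(r) r$setting == "S1" && r$family == f, records)
      t(vapply(rs, function(r) {
        v <- colMeans(r$per_rep_trait, na.rm = TRUE)
        v[is.nan(v)] <- 0
        unname(v)
      }, numeric(ncol(records[[1]]$per_rep_trait))))
    })
    if (nrow(perf[[1]]) > 2 && nrow(perf[[2]]) > 2 &&
        ncol(perf[[1]]) < nrow(perf[[1]]) + nrow(perf[[2]]) - 2)
      hot <- hotelling_t2(perf[[1]], perf[[2]])
  }

  report <- make_report(records, selection = selection,
                        heritability = herit,
                        correlations = correlations,
                        metadata = list(seed = config$seed,
                                        n_individuals = n_individuals,
                                        n_markers = config$n_markers,
                                        methods = methods,
                                        repetitions = scheme$repetitions,
                                        settings = settings),
                        out_dir = out_dir)
  report$qc <- lapply(qc, `[[`, "report")
  report$records <- records
  report$hotelling <- hot
  report$study <- study
  invisible(report)
}
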