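#' Configuration for the full study-replay pipeline
#'
#' Bundles the options of every stage: simulation (or input files),
#' preprocessing, the repeated REFS runs, evaluation, the chi-squared and
#' external-signature comparison, the CpG restriction + methylation REFS, and
#' the cross-platform transfer. All stage seeds derive deterministically from
#' `seed`.
#'
#' @param simulate A [synthetic_config()] describing the synthetic study, or
#'   `NULL` with `matrix_path`/`labels_path`/`annotation_path` pointing at
#'   TSV inputs.
#' @param runs Repeated REFS runs (default 10).
#' @param k_folds CV folds for REFS and evaluation (default 10).
#' @param reduce_frac,stop_accuracy,initial_keep REFS parameters (defaults
#'   0.2, 0.7, `NULL`).
#' @param chi2_k Signature size of the univariate chi-squared baseline
#'   (default 23).
#' @param external_signatures Named list of externally supplied gene lists to
#'   evaluate alongside (e.g. a published co-expression-network signature).
#' @param transfer_k_folds Folds for the cross-platform validation
#'   (default 5).
#' @param expression_axis,methylation_axis Scaling axes (defaults
#'   `"per_feature"`, `"per_sample"`).
#' @param n_estimators Trees/rounds of the tree-family classifiers
#'   (default 300).
#' @param scorer ROC scorer passed to [evaluate_signature()].
#' @param matrix_path,labels_path,annotation_path Optional file inputs used
#'   when `simulate` is `NULL`.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = synthetic_config(), runs = 10,
                            k_folds = 10, reduce_frac = 0.2,
                            stop_accuracy = 0.7, initial_keep = NULL,
                            chi2_k = 23, external_signatures = list(),
                            transfer_k_folds = 5,
                            expression_axis = "per_feature",
                            methylation_axis = "per_sample",
                            n_estimators = 300,
                            scorer = "logistic_regression",
                            matrix_path = NULL, labels_path = NULL,
                            annotation_path = NULL, seed = 1L) {
  if (is.null(simulate)) {
    for (f in c(matrix_path, labels_path)) {
      if (is.null(f) || !file.exists(f)) {
        stop_refsig("refsig_config_error",
                    "without `simulate`, matrix_path and labels_path must exist")
      }
    }
  }
  structure(list(simulate = simulate, runs = runs, k_folds = k_folds,
                 reduce_frac = reduce_frac, stop_accuracy = stop_accuracy,
                 initial_keep = initial_keep, chi2_k = chi2_k,
                 external_signatures = external_signatures,
                 transfer_k_folds = transfer_k_folds,
                 expression_axis = expression_axis,
                 methylation_axis = methylation_axis,
                 n_estimators = n_estimators, scorer = scorer,
                 matrix_path = matrix_path, labels_path = labels_path,
                 annotation_path = annotation_path,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Evaluate several signatures under identical folds
#'
#' Each signature (gene/feature list) is evaluated with the same fold
#' assignment and seeds, and the signatures are ranked by AUC then global
#' accuracy. A signature with no feature in the dataset is marked
#' unevaluable; the others proceed.
#'
#' @param ds Scaled `omics_dataset`.
#' @param signatures Named list of feature-ID vectors (or `signature_set`s).
#' @param k_folds,seed,specs,scorer As in [evaluate_signature()].
#' @return List with `reports` (named list of `evaluation_report` or `NULL`
#'   for unevaluable entries) and `ranking` (data.frame sorted by decreasing
#'   AUC, then accuracy).
#' @export
compare_selectors <- function(ds, signatures, k_folds = 10, seed = 1L,
                              specs = classifier_specs(),
                              scorer = "logistic_regression") {
  stopifnot(length(signatures) > 0, !is.null(names(signatures)))
  folds <- make_stratified_folds(ds$labels, k_folds, seed)
  reports <- lapply(signatures, function(sig) {
    tryCatch(
      evaluate_signature(ds, sig, specs = specs, scorer = scorer,
                         folds = folds, seed = seed),
      refsig_evaluation_error = function(e) NULL
    )
  })
  ok <- !vapply(reports, is.null, logical(1))
  ranking <- data.frame(
    signature = names(reports)[ok],
    n_features = vapply(reports[ok], function(r) r$n_features_used, 0L),
    global_accuracy = vapply(reports[ok], function(r) r$global_accuracy, 0),
    auc = vapply(reports[ok], function(r) r$auc, 0)
  )
  ranking <- ranking[order(-ranking$auc, -ranking$global_accuracy), ]
  rownames(ranking) <- NULL
  list(reports = reports, ranking = ranking)
}

#' Run the full signature-discovery pipeline
#'
#' Executes the study replay end to end: simulate (or load) the expression
#' cohort, re-annotate and scale, run REFS `runs` times and take the
#' consensus signature, evaluate it (accuracy table, ROC/AUC, MANOVA),
#' compare against the chi-squared baseline and any external signatures,
#' restrict the methylation array to CpGs of the signature genes and rerun
#' REFS there, and finally transfer the gene signature to the second
#' expression platform under small-sample CV. Stage outputs are pure
#' functions of (inputs, config, seed); rerunning with the same config
#' writes byte-identical reports.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional directory; when given, per-stage JSON/TSV artifacts
#'   and a `summary.json` are written there.
#' @param stages Subset of `c("expression", "comparison", "methylation",
#'   "transfer")` to run (the expression stage is always required).
#' @return Invisibly, the report bundle: a list with per-stage results and
#'   `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         stages = c("expression", "comparison",
                                    "methylation", "transfer")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  specs <- classifier_specs(n_estimators = config$n_estimators)
  bundle <- list(config = config)
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  emit <- function(name, obj) {
    if (!is.null(outdir)) {
      jsonlite::write_json(obj, file.path(outdir, paste0(name, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null")
    }
  }

  # --- expression stage -----------------------------------------------------
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_refsig("refsig_stage_error",
                  sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  sim <- NULL
  expr_stage <- run_stage("expression", {
    if (!is.null(config$simulate)) {
      sim <- generate_expression(config$simulate)
      ds_raw <- sim$dataset
      annotation <- sim$annotation
    } else {
      ds_raw <- read_matrix(config$matrix_path, config$labels_path)
      annotation <- if (!is.null(config$annotation_path)) {
        read_probe_annotation(config$annotation_path)
      } else NULL
    }
    ds <- if (!is.null(annotation)) reannotate_probes(ds_raw, annotation) else ds_raw
    ds <- standard_scale(ds, config$expression_axis)
    traces <- lapply(seq_len(config$runs), function(r) {
      run_refs(ds, k_folds = config$k_folds, reduce_frac = config$reduce_frac,
               stop_accuracy = config$stop_accuracy,
               initial_keep = config$initial_keep,
               seed = config$seed + r - 1L, specs = specs)
    })
    signature <- select_optimal(traces)
    genes <- if (!is.null(ds$gene_symbols)) {
      signature_genes(signature$feature_ids, ds)
    } else signature$feature_ids
    report <- evaluate_signature(ds, signature, k_folds = config$k_folds,
                                 seed = config$seed, specs = specs,
                                 scorer = config$scorer)
    manova <- if (length(signature$feature_ids) < n_samples(ds) - 1) {
      manova_two_group(ds, signature$feature_ids)
    } else NULL
    list(dataset = ds, annotation = annotation, traces = traces,
         signature = signature, genes = genes, report = report,
         manova = manova)
  })
  bundle$expression <- expr_stage
  emit("refs_trace_expression", lapply(expr_stage$traces, trace_iterations_list))
  emit("signature_expression", signature_list(expr_stage$signature))
  emit("evaluation_expression", report_list(expr_stage$report))
  if (!is.null(expr_stage$manova)) emit("manova_expression", unclass(expr_stage$manova))
  if (!is.null(outdir)) {
    utils::write.table(trace_accuracy_table(expr_stage$traces),
                       file.path(outdir, "accuracy_vs_m_expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- comparison stage -----------------------------------------------------
  if ("comparison" %in% stages) {
    bundle$comparison <- run_stage("comparison", {
      ds <- expr_stage$dataset
      sigs <- list(refs = expr_stage$signature$feature_ids)
      k2 <- min(config$chi2_k, n_features(ds))
      sigs$chi2 <- univariate_chi2_select(ds, k2)$feature_ids
      for (nm in names(config$external_signatures)) {
        ext <- config$external_signatures[[nm]]
        sigs[[nm]] <- if (!is.null(ds$gene_symbols)) {
          probes_for_genes(ds, ext)
        } else ext
      }
      compare_selectors(ds, sigs, k_folds = config$k_folds,
                        seed = config$seed, specs = specs,
                        scorer = config$scorer)
    })
    emit("comparison", list(
      ranking = bundle$comparison$ranking,
      reports = lapply(bundle$comparison$reports, function(r) {
        if (is.null(r)) NULL else report_list(r)
      })
    ))
  }

  # --- methylation stage ----------------------------------------------------
  if ("methylation" %in% stages && !is.null(sim)) {
    bundle$methylation <- run_stage("methylation", {
      cpg_ann <- make_cpg_annotation(sim$truth, config$simulate)
      meth <- generate_methylation(config$simulate, sim$truth, cpg_ann)
      genes <- candidate_gene_list(expr_stage$genes)
      sel <- select_candidate_cpgs(cpg_ann, genes)
      meth_ds <- standard_scale(meth$dataset, config$methylation_axis)
      rr <- restrict_and_rerun(meth_ds, sel$cpg_ids, n_runs = config$runs,
                               seed = derive_seed(config$seed, 21L),
                               k_folds = config$k_folds,
                               reduce_frac = config$reduce_frac,
                               stop_accuracy = config$stop_accuracy,
                               specs = specs)
      report <- evaluate_signature(meth_ds, rr$signature,
                                   k_folds = config$k_folds,
                                   seed = derive_seed(config$seed, 22L),
                                   specs = specs, scorer = config$scorer)
      manova <- if (length(rr$signature$feature_ids) < n_samples(meth_ds) - 1) {
        manova_two_group(meth_ds, rr$signature$feature_ids)
      } else NULL
      list(annotation = cpg_ann, selected_cpgs = sel, traces = rr$traces,
           signature = rr$signature, report = report, manova = manova,
           truth = meth$truth)
    })
    emit("cpg_selection", bundle$methylation$selected_cpgs$mapping)
    emit("signature_methylation", signature_list(bundle$methylation$signature))
    emit("evaluation_methylation", report_list(bundle$methylation$report))
    if (!is.null(bundle$methylation$manova)) {
      emit("manova_methylation", unclass(bundle$methylation$manova))
    }
  }

  # --- transfer stage -------------------------------------------------------
  if ("transfer" %in% stages && !is.null(sim)) {
    bundle$transfer <- run_stage("transfer", {
      p2 <- generate_second_platform(sim$truth, config$simulate)
      tmap <- map_signature(expr_stage$genes, p2$annotation)
      ds2 <- standard_scale(p2$dataset, config$expression_axis)
      report <- transfer_evaluate(ds2, tmap,
                                  k_folds = config$transfer_k_folds,
                                  seed = derive_seed(config$seed, 23L),
                                  specs = specs, scorer = config$scorer)
      list(platform = p2, map = tmap, report = report)
    })
    emit("transfer_map", list(
      requested = bundle$transfer$map$requested_genes,
      mapped = bundle$transfer$map$mapped,
      missing = bundle$transfer$map$missing
    ))
    emit("transfer_report", report_list(bundle$transfer$report))
  }

  # --- summary --------------------------------------------------------------
  summary <- list(
    seed = config$seed,
    expression = list(
      signature_size = length(expr_stage$signature$feature_ids),
      optimal_m = expr_stage$signature$optimal_m,
      global_accuracy = expr_stage$report$global_accuracy,
      auc = expr_stage$report$auc,
      manova = if (is.null(expr_stage$manova)) NULL else unclass(expr_stage$manova)
    )
  )
  if (!is.null(bundle$methylation)) {
    summary$methylation <- list(
      n_candidate_cpgs = length(bundle$methylation$selected_cpgs$cpg_ids),
      signature_size = length(bundle$methylation$signature$feature_ids),
      global_accuracy = bundle$methylation$report$global_accuracy,
      auc = bundle$methylation$report$auc,
      manova = if (is.null(bundle$methylation$manova)) NULL else
        unclass(bundle$methylation$manova)
    )
  }
  if (!is.null(bundle$transfer)) {
    summary$transfer <- list(
      genes_mapped = length(bundle$transfer$map$mapped),
      genes_missing = length(bundle$transfer$map$missing),
      global_accuracy = bundle$transfer$report$global_accuracy,
      auc = bundle$transfer$report$auc
    )
  }
  bundle$summary <- summary
  emit("summary", summary)
  emit("provenance", list(seed = config$seed, runs = config$runs,
                          k_folds = config$k_folds,
                          n_estimators = config$n_estimators,
                          package_version = as.character(utils::packageVersion("refsig"))))
  invisible(bundle)
}

# map external gene symbols to the dataset's probes via its gene_symbols
probes_for_genes <- function(ds, genes) {
  g <- candidate_gene_list(genes)
  hits <- vapply(ds$gene_symbols, function(s) any(toupper(s) %in% g), logical(1))
  names(ds$gene_symbols)[hits]
}

# serialisable views of the core objects (timestamp-free, so reruns with the
# same config and seed write byte-identical files)
trace_iterations_list <- function(trace) {
  lapply(trace$iterations, function(it) {
    list(m = it$m, global_accuracy = it$global_accuracy,
         classifier_accuracy = as.list(it$classifier_accuracy),
         features = it$features)
  })
}

signature_list <- function(sig) {
  list(feature_ids = sig$feature_ids, optimal_m = sig$optimal_m,
       selection_frequency = as.list(sig$selection_frequency),
       n_runs = sig$n_runs,
       accuracy_by_m = sig$accuracy_by_m)
}

report_list <- function(rep) {
  list(classifier_accuracy = rep$classifier_accuracy,
       global_accuracy = rep$global_accuracy,
       auc = rep$auc,
       roc_points = if (is.null(rep$roc)) NULL else rep$roc$points,
       n_features_used = rep$n_features_used,
       features = rep$features)
}
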