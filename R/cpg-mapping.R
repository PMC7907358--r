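#' Normalised candidate gene list
#'
#' Symbols are trimmed, upper-cased and de-duplicated; matching anywhere in
#' the package is exact token match on this normalised form.
#'
#' @param gene_symbols Character vector of gene symbols.
#' @return A `candidate_gene_list` (character vector).
#' @export
candidate_gene_list <- function(gene_symbols) {
  g <- unique(toupper(trimws(as.character(gene_symbols))))
  g <- g[nzchar(g)]
  if (length(g) == 0) {
    stop_refsig("refsig_value_error", "candidate gene list is empty")
  }
  structure(g, class = "candidate_gene_list")
}

#' Select CpGs annotated to candidate genes
#'
#' Returns every CpG whose parsed `UCSC_RefGene_Name`-style gene list
#' intersects the candidate genes (case-insensitive exact symbol match), in
#' annotation order; CpGs matching several candidates are kept once.
#'
#' @param ann A `cpg_annotation` (see [read_cpg_annotation()] /
#'   [make_cpg_annotation()]).
#' @param genes A [candidate_gene_list()] (plain character vectors are
#'   normalised first).
#' @return List with `cpg_ids` (selected, annotation order) and `mapping`
#'   (data.frame `cpg_id`, `matched_genes` semicolon-joined).
#' @export
select_candidate_cpgs <- function(ann, genes) {
  if (!inherits(genes, "candidate_gene_list")) genes <- candidate_gene_list(genes)
  if (!all(c("cpg_id", "parsed_genes") %in% names(ann))) {
    stop_refsig("refsig_format_error", "ann must be a parsed cpg_annotation")
  }
  matched <- lapply(ann$parsed_genes, function(g) intersect(toupper(g), genes))
  hit <- lengths(matched) > 0
  if (!any(hit)) {
    stop_refsig("refsig_empty_result_error",
                "no CpG is annotated to any candidate gene")
  }
  list(
    cpg_ids = ann$cpg_id[hit],
    mapping = data.frame(
      cpg_id = ann$cpg_id[hit],
      matched_genes = vapply(matched[hit], paste, "", collapse = ";"),
      stringsAsFactors = FALSE
    )
  )
}

#' Run REFS on a candidate-CpG-restricted methylation dataset
#'
#' Restricts the methylation dataset to the selected CpGs, runs [run_refs()]
#' `n_runs` times (fold seeds `seed`, `seed + 1`, ...), and derives the CpG
#' consensus signature with [select_optimal()].
#'
#' @param meth_ds Methylation `omics_dataset` (scaled per sample).
#' @param cpg_ids CpGs to retain (from [select_candidate_cpgs()]).
#' @param n_runs Repeated runs (default 10).
#' @param seed Base seed.
#' @param ... Passed to [run_refs()] (`k_folds`, `reduce_frac`,
#'   `stop_accuracy`, `specs`, ...).
#' @return List with `traces` (list of `refs_trace`) and `signature`
#'   (`signature_set`).
#' @export
restrict_and_rerun <- function(meth_ds, cpg_ids, n_runs = 10, seed = 1L, ...) {
  present <- intersect(cpg_ids, rownames(meth_ds$values))
  if (length(present) == 0) {
    stop_refsig("refsig_empty_result_error",
                "none of the selected CpGs is present in the methylation matrix")
  }
  sub <- ds_restrict(meth_ds, present)
  if (length(present) == 1) {
    # a single candidate CpG leaves nothing to eliminate: the "signature"
    # is that feature, and callers evaluate it directly
    sig <- structure(list(
      feature_ids = present, optimal_m = 1L,
      selection_frequency = stats::setNames(1, present),
      n_runs = as.integer(n_runs),
      accuracy_by_m = NULL
    ), class = "signature_set")
    return(list(traces = list(), signature = sig))
  }
  traces <- lapply(seq_len(n_runs), function(r) {
    run_refs(sub, seed = seed + r - 1L, ...)
  })
  list(traces = traces, signature = select_optimal(traces))
}
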