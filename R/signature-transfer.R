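#' Map a gene signature onto a second platform's probes
#'
#' Genes are matched case-insensitively against the target platform's
#' probe-to-gene annotation; genes with no probe go to `missing`, multi-probe
#' genes keep all their probes.
#'
#' @param genes A [candidate_gene_list()] (or character vector).
#' @param ann2 Target-platform annotation data.frame (`probe_id`,
#'   `gene_symbols`).
#' @return A `transfer_map`: list with `requested_genes`, `mapped` (named
#'   list gene -> probe IDs) and `missing` (gene vector). `mapped` and
#'   `missing` partition the request.
#' @export
map_signature <- function(genes, ann2) {
  if (!inherits(genes, "candidate_gene_list")) genes <- candidate_gene_list(genes)
  sym <- parse_refgene_field(ann2$gene_symbols)
  probe_genes <- lapply(sym, toupper)
  mapped <- lapply(genes, function(g) {
    ann2$probe_id[vapply(probe_genes, function(s) g %in% s, logical(1))]
  })
  names(mapped) <- genes
  missing <- genes[lengths(mapped) == 0]
  mapped <- mapped[lengths(mapped) > 0]
  if (length(mapped) == 0) {
    stop_refsig("refsig_transfer_error",
                "no requested gene maps to any probe on the target platform")
  }
  structure(list(requested_genes = as.character(genes),
                 mapped = mapped, missing = as.character(missing)),
            class = "transfer_map")
}

#' @export
print.transfer_map <- function(x, ...) {
  cat(sprintf("transfer_map: %d of %d genes mapped (%d missing), %d probes\n",
              length(x$mapped), length(x$requested_genes), length(x$missing),
              length(unlist(x$mapped))))
  invisible(x)
}

#' Evaluate a transferred signature on a second platform
#'
#' Cross-platform validation: the target dataset is restricted to the mapped
#' probes and evaluated with the standard ensemble under small-sample
#' stratified CV. No feature re-selection is performed on the target data.
#'
#' @param ds2 Target `omics_dataset` (scaled).
#' @param tmap A `transfer_map` from [map_signature()].
#' @param k_folds CV folds (default 5 for small cohorts).
#' @param seed Fold/classifier seed.
#' @param specs Ensemble from [classifier_specs()].
#' @param first_probe_only Use only the first probe of multi-probe genes
#'   (default `FALSE`: all probes become features).
#' @param ... Passed to [evaluate_signature()].
#' @return An `evaluation_report`; `n_features_used` equals the number of
#'   mapped probes present in `ds2`, and attribute `"genes_evaluated"` lists
#'   the genes actually represented.
#' @export
transfer_evaluate <- function(ds2, tmap, k_folds = 5, seed = 1L,
                              specs = classifier_specs(),
                              first_probe_only = FALSE, ...) {
  stopifnot(inherits(tmap, "transfer_map"))
  probes_by_gene <- if (first_probe_only) {
    lapply(tmap$mapped, `[`, 1L)
  } else {
    tmap$mapped
  }
  probes <- unique(unlist(probes_by_gene))
  present <- intersect(probes, rownames(ds2$values))
  if (length(present) == 0) {
    stop_refsig("refsig_transfer_error",
                "no mapped probe is present in the target dataset")
  }
  rep <- evaluate_signature(ds2, present, k_folds = k_folds, seed = seed,
                            specs = specs, ...)
  genes_eval <- names(probes_by_gene)[
    vapply(probes_by_gene, function(p) any(p %in% present), logical(1))]
  attr(rep, "genes_evaluated") <- genes_eval
  rep
}
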