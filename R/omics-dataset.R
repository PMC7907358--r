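#' Construct a case/control omics dataset
#'
#' The universal currency of the pipeline: a feature-by-sample numeric matrix
#' with unique feature and sample identifiers and a binary phenotype label per
#' sample (0 = control, 1 = case). Matrices with missing values are rejected
#' rather than imputed.
#'
#' @param values Numeric matrix, features in rows, samples in columns. Must
#'   have unique row names (feature IDs) and column names (sample IDs).
#' @param labels Binary labels, one per sample, values in \{0, 1\}. If named,
#'   they are aligned to the matrix columns by sample ID (every column must be
#'   covered); if unnamed, they are taken in column order.
#' @param feature_kind One of `"probe"`, `"gene"`, `"cpg"`.
#' @param gene_symbols Optional named list mapping feature IDs to character
#'   vectors of gene symbols (as attached by [reannotate_probes()]).
#' @param sample_source Optional character vector (one entry per sample)
#'   recording which source dataset each sample came from (set by
#'   [merge_datasets()]).
#'
#' @return An object of class `omics_dataset`: a list with elements `values`,
#'   `labels` (named integer vector), `feature_kind`, `gene_symbols`,
#'   `sample_source`.
#' @export
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("f", 1:3), c("s1", "s2")))
#' ds <- omics_dataset(m, c(s1 = 0, s2 = 1))
omics_dataset <- function(values, labels,
                          feature_kind = c("probe", "gene", "cpg"),
                          gene_symbols = NULL, sample_source = NULL) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_refsig("refsig_format_error", "`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_refsig("refsig_format_error",
                "`values` must carry feature IDs as rownames and sample IDs as colnames")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop_refsig("refsig_format_error",
                paste0("duplicate feature IDs: ", paste(utils::head(dup, 5), collapse = ", ")))
  }
  if (anyDuplicated(colnames(values))) {
    stop_refsig("refsig_format_error", "duplicate sample IDs in matrix")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop_refsig("refsig_missing_value_error",
                "matrix contains missing or non-finite values; imputation is not supported")
  }
  samples <- colnames(values)
  if (!is.null(names(labels))) {
    missing <- setdiff(samples, names(labels))
    if (length(missing) > 0) {
      stop_refsig("refsig_alignment_error",
                  paste0("no label for sample(s): ",
                         paste(utils::head(missing, 5), collapse = ", ")))
    }
    labels <- labels[samples]
  } else if (length(labels) != length(samples)) {
    stop_refsig("refsig_alignment_error",
                sprintf("%d labels for %d samples", length(labels), length(samples)))
  }
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop_refsig("refsig_value_error", "labels must be 0 (control) or 1 (case)")
  }
  names(labels) <- samples
  if (!is.null(sample_source)) {
    stopifnot(length(sample_source) == length(samples))
    sample_source <- stats::setNames(as.character(sample_source), samples)
  }
  structure(
    list(values = values, labels = labels, feature_kind = feature_kind,
         gene_symbols = gene_symbols, sample_source = sample_source),
    class = "omics_dataset"
  )
}

#' Number of features / samples in a dataset
#' @param ds An `omics_dataset`.
#' @return Integer count.
#' @export
n_features <- function(ds) nrow(ds$values)

#' @rdname n_features
#' @export
n_samples <- function(ds) ncol(ds$values)

#' Restrict a dataset to a subset of features
#'
#' @param ds An `omics_dataset`.
#' @param feature_ids Character vector of feature IDs to keep, in the order
#'   they should appear.
#' @param require_all If `TRUE` (default) an error is raised when any requested
#'   feature is absent; otherwise absent features are silently dropped.
#' @return An `omics_dataset` with only the requested features.
#' @export
ds_restrict <- function(ds, feature_ids, require_all = TRUE) {
  present <- feature_ids %in% rownames(ds$values)
  if (require_all && !all(present)) {
    stop_refsig("refsig_value_error",
                paste0("features not in dataset: ",
                       paste(utils::head(feature_ids[!present], 5), collapse = ", ")))
  }
  keep <- feature_ids[present]
  if (length(keep) == 0) {
    stop_refsig("refsig_empty_result_error", "no requested feature present in dataset")
  }
  gs <- ds$gene_symbols
  if (!is.null(gs)) gs <- gs[intersect(keep, names(gs))]
  omics_dataset(ds$values[keep, , drop = FALSE], ds$labels, ds$feature_kind,
                gene_symbols = gs, sample_source = ds$sample_source)
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf("omics_dataset (%s): %d features x %d samples (%d cases / %d controls)\n",
              x$feature_kind, n_features(x), n_samples(x),
              sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}
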