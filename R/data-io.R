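#' Write an omics dataset as TSV files
#'
#' The matrix file has features in rows (first column `feature_id`, remaining
#' columns one per sample, header = sample IDs); the labels file has two
#' columns (`sample_id`, `label`).
#'
#' @param ds An `omics_dataset`.
#' @param matrix_path,labels_path Output file paths.
#' @return Invisibly, the matrix path.
#' @export
write_omics_tsv <- function(ds, matrix_path, labels_path) {
  df <- data.frame(feature_id = rownames(ds$values), ds$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lab <- data.frame(sample_id = names(ds$labels), label = unname(ds$labels))
  utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}

#' Read a feature-by-sample matrix and its labels from TSV
#'
#' Inverse of [write_omics_tsv()]. Matrix and labels are aligned by sample ID;
#' a label missing for any matrix sample is an alignment error naming the
#' sample.
#'
#' @param path Matrix TSV (first column feature IDs, header sample IDs).
#' @param labels_path Two-column TSV (`sample_id`, `label`).
#' @param feature_kind Passed to [omics_dataset()].
#' @return An `omics_dataset`.
#' @export
read_matrix <- function(path, labels_path, feature_kind = "probe") {
  for (f in c(path, labels_path)) {
    if (!file.exists(f)) stop_refsig("refsig_io_error", paste0("file not found: ", f))
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_refsig("refsig_format_error", "matrix file needs >= 2 columns")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop_refsig("refsig_format_error",
                paste0("duplicate feature IDs in ", path))
  }
  vals <- df[, -1, drop = FALSE]
  non_num <- !vapply(vals, is.numeric, logical(1))
  if (any(non_num)) {
    stop_refsig("refsig_parse_error",
                paste0("non-numeric cells in column(s): ",
                       paste(names(vals)[non_num], collapse = ", ")))
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(lab))) {
    stop_refsig("refsig_format_error",
                "labels file must have columns sample_id and label")
  }
  labels <- stats::setNames(lab$label, lab$sample_id)
  omics_dataset(m, labels, feature_kind)
}

#' Read a GEO series-matrix style file
#'
#' Parses the text layout GEO uses to distribute processed matrices: "!"-
#' prefixed metadata lines and a tab-delimited value table between
#' `!series_matrix_table_begin` and `!series_matrix_table_end`. Quoted feature
#' and sample IDs are dequoted. Labels are not part of the table and must be
#' supplied separately -- either directly, or through a rule applied to a
#' metadata characteristics line.
#'
#' @param path Series-matrix file path.
#' @param labels Optional labels: a named vector (sample ID to 0/1) or a path
#'   to a two-column TSV as read by [read_matrix()].
#' @param characteristics Optional list `list(prefix = , map = )`: the first
#'   metadata line starting with `prefix` is split into per-sample tokens and
#'   each token is looked up in the named vector `map` (token to 0/1 label).
#' @param feature_kind Passed to [omics_dataset()].
#' @return An `omics_dataset` when labels are resolvable; otherwise the bare
#'   numeric matrix with the metadata lines attached as attribute
#'   `"metadata"`.
#' @export
read_series_matrix <- function(path, labels = NULL, characteristics = NULL,
                               feature_kind = "probe") {
  if (!file.exists(path)) stop_refsig("refsig_io_error", paste0("file not found: ", path))
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  fin <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1 || length(fin) != 1 || fin <= beg + 1) {
    stop_refsig("refsig_format_error",
                "missing !series_matrix_table_begin/end delimiters")
  }
  meta <- grep("^!", lines[seq_len(beg - 1)], value = TRUE)
  tab <- lines[(beg + 1):(fin - 1)]
  dequote <- function(x) gsub('^"|"$', "", x)
  header <- dequote(strsplit(tab[1], "\t", fixed = TRUE)[[1]])
  body <- strsplit(tab[-1], "\t", fixed = TRUE)
  ids <- dequote(vapply(body, `[[`, "", 1L))
  m <- matrix(NA_real_, length(body), length(header) - 1L,
              dimnames = list(ids, header[-1]))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1]))
    m[i, ] <- v
  }
  if (anyNA(m)) stop_refsig("refsig_parse_error", "non-numeric cells in series-matrix table")

  if (is.null(labels) && !is.null(characteristics)) {
    hit <- grep(paste0("^", characteristics$prefix), meta, value = TRUE)
    if (length(hit) == 0) {
      stop_refsig("refsig_format_error",
                  paste0("no metadata line starting with ", characteristics$prefix))
    }
    tokens <- dequote(strsplit(hit[1], "\t", fixed = TRUE)[[1]])[-1]
    if (length(tokens) != ncol(m)) {
      stop_refsig("refsig_alignment_error",
                  "characteristics line length does not match sample count")
    }
    unknown <- setdiff(unique(tokens), names(characteristics$map))
    if (length(unknown) > 0) {
      stop_refsig("refsig_value_error",
                  paste0("unmapped characteristics token(s): ",
                         paste(unknown, collapse = ", ")))
    }
    labels <- stats::setNames(characteristics$map[tokens], colnames(m))
  } else if (is.character(labels) && length(labels) == 1 && file.exists(labels)) {
    lab <- utils::read.delim(labels, stringsAsFactors = FALSE)
    labels <- stats::setNames(lab$label, lab$sample_id)
  }
  if (is.null(labels)) {
    attr(m, "metadata") <- meta
    return(m)
  }
  omics_dataset(m, labels, feature_kind)
}

#' Read / write a probe-to-gene annotation table
#'
#' TSV with columns `probe_id` and `gene_symbols` (semicolon-joined, empty for
#' unannotated probes).
#'
#' @param path File path.
#' @return A data.frame with columns `probe_id`, `gene_symbols`.
#' @export
read_probe_annotation <- function(path) {
  if (!file.exists(path)) stop_refsig("refsig_io_error", paste0("file not found: ", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("probe_id", "gene_symbols") %in% names(df))) {
    stop_refsig("refsig_format_error",
                "annotation must have columns probe_id and gene_symbols")
  }
  if (anyDuplicated(df$probe_id)) {
    stop_refsig("refsig_format_error", "duplicate probe_id in annotation")
  }
  df$gene_symbols[is.na(df$gene_symbols)] <- ""
  df[, c("probe_id", "gene_symbols")]
}

#' @rdname read_probe_annotation
#' @param ann Annotation data.frame to write.
#' @export
write_probe_annotation <- function(ann, path) {
  utils::write.table(ann[, c("probe_id", "gene_symbols")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Split raw semicolon-joined gene fields into unique, trimmed, non-empty
# token lists (the 450k UCSC_RefGene_Name dialect repeats symbols per
# transcript).
parse_refgene_field <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(tok) {
    tok <- trimws(tok)
    unique(tok[nzchar(tok)])
  })
}

#' Read a CpG annotation table (450k/EPIC datasheet style)
#'
#' Expects a TSV with a CpG identifier column and a `UCSC_RefGene_Name`-style
#' field of semicolon-joined gene symbols; the parsed, de-duplicated gene
#' lists are attached as a list column.
#'
#' @param path File path.
#' @param cpg_col,gene_col Column names (defaults `cpg_id`,
#'   `UCSC_RefGene_Name`; `refgene_names` is also recognised).
#' @return A `cpg_annotation` data.frame with columns `cpg_id`,
#'   `refgene_names`, `parsed_genes` (list column).
#' @export
read_cpg_annotation <- function(path, cpg_col = "cpg_id",
                                gene_col = "UCSC_RefGene_Name") {
  if (!file.exists(path)) stop_refsig("refsig_io_error", paste0("file not found: ", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!gene_col %in% names(df) && "refgene_names" %in% names(df)) {
    gene_col <- "refgene_names"
  }
  if (!all(c(cpg_col, gene_col) %in% names(df))) {
    stop_refsig("refsig_format_error",
                paste0("annotation must have columns ", cpg_col, " and ", gene_col))
  }
  raw <- df[[gene_col]]
  raw[is.na(raw)] <- ""
  ann <- data.frame(cpg_id = df[[cpg_col]], refgene_names = raw,
                    stringsAsFactors = FALSE)
  ann$parsed_genes <- parse_refgene_field(ann$refgene_names)
  class(ann) <- c("cpg_annotation", "data.frame")
  ann
}

#' @rdname read_cpg_annotation
#' @param ann A `cpg_annotation` to write (list column is dropped, the raw
#'   field is kept).
#' @export
write_cpg_annotation <- function(ann, path) {
  utils::write.table(ann[, c("cpg_id", "refgene_names")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop unannotated probes and attach gene symbols
#'
#' Probes with no gene symbol in the annotation are removed; surviving
#' features keep probe-level granularity (multiple probes per gene stay
#' distinct features) and carry their gene symbols as an attribute, with the
#' first listed symbol acting as the display symbol.
#'
#' @param ds An `omics_dataset` with `feature_kind = "probe"`.
#' @param ann Annotation data.frame (`probe_id`, `gene_symbols`).
#' @return The filtered `omics_dataset`, with `gene_symbols` populated and an
#'   attribute `"n_retained"` recording the retained probe count.
#' @export
reannotate_probes <- function(ds, ann) {
  if (ds$feature_kind != "probe") {
    stop_refsig("refsig_value_error", "reannotate_probes expects probe-level features")
  }
  symbols <- parse_refgene_field(ann$gene_symbols)
  names(symbols) <- ann$probe_id
  annotated <- names(symbols)[lengths(symbols) > 0]
  keep <- intersect(rownames(ds$values), annotated)
  if (length(keep) == 0) {
    stop_refsig("refsig_empty_result_error",
                "annotation covers none of the dataset's probes")
  }
  out <- omics_dataset(ds$values[keep, , drop = FALSE], ds$labels, "probe",
                       gene_symbols = symbols[keep],
                       sample_source = ds$sample_source)
  attr(out, "n_retained") <- length(keep)
  out
}

#' Gene symbols of a set of probe features
#'
#' Maps feature IDs to gene symbols using the `gene_symbols` attached by
#' [reannotate_probes()] (or an explicit annotation table), returning the
#' unique symbols in feature order (first listed symbol per probe).
#'
#' @param feature_ids Character vector of probe IDs.
#' @param ds_or_ann An `omics_dataset` carrying `gene_symbols`, or a probe
#'   annotation data.frame.
#' @return Character vector of unique gene symbols.
#' @export
signature_genes <- function(feature_ids, ds_or_ann) {
  if (inherits(ds_or_ann, "omics_dataset")) {
    gs <- ds_or_ann$gene_symbols
  } else {
    gs <- parse_refgene_field(ds_or_ann$gene_symbols)
    names(gs) <- ds_or_ann$probe_id
  }
  if (is.null(gs)) stop_refsig("refsig_value_error", "no gene symbols available")
  hit <- feature_ids[feature_ids %in% names(gs)]
  unique(vapply(gs[hit], `[[`, "", 1L))
}
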