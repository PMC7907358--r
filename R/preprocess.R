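#' Standard-scale a dataset along features or samples
#'
#' Z-scores each feature vector (`axis = "per_feature"`, the convention for
#' expression matrices) or each sample vector (`axis = "per_sample"`, used
#' for percentage-methylation profiles) to mean 0 and population SD 1.
#' Constant vectors cannot be scaled and are mapped to all-zeros with a
#' warning.
#'
#' @param ds An `omics_dataset`.
#' @param axis `"per_feature"` or `"per_sample"`.
#' @return The scaled `omics_dataset`.
#' @export
standard_scale <- function(ds, axis = c("per_feature", "per_sample")) {
  axis <- match.arg(axis)
  m <- ds$values
  if (axis == "per_sample") m <- t(m)
  mu <- rowMeans(m)
  sdv <- sqrt(rowMeans((m - mu)^2))
  const <- sdv == 0
  if (any(const)) {
    warn_refsig("refsig_constant_vector_warning",
                sprintf("%d constant %s vector(s) scaled to all-zeros",
                        sum(const), sub("per_", "", axis)))
    sdv[const] <- 1
  }
  m <- (m - mu) / sdv
  m[const, ] <- 0
  if (axis == "per_sample") m <- t(m)
  omics_dataset(m, ds$labels, ds$feature_kind,
                gene_symbols = ds$gene_symbols, sample_source = ds$sample_source)
}

#' Encode fatigue-severity categories as binary case/control labels
#'
#' Low severity is the control class (0); moderate and high severity are
#' cases (1).
#'
#' @param severity Character vector with values in
#'   `c("low", "moderate", "high")`.
#' @return Integer vector of 0/1 labels (names preserved).
#' @export
#' @examples
#' encode_labels(c("low", "moderate", "high")) # 0 1 1
encode_labels <- function(severity) {
  if (length(severity) == 0) return(integer(0))
  map <- c(low = 0L, moderate = 1L, high = 1L)
  unknown <- setdiff(unique(severity), names(map))
  if (length(unknown) > 0) {
    stop_refsig("refsig_value_error",
                paste0("unknown severity category: ", paste(unknown, collapse = ", ")))
  }
  stats::setNames(map[severity], names(severity))
}

#' Merge datasets on their common features
#'
#' Features are intersected (classifiers downstream reject missing values, so
#' union-with-NA is not an option), samples concatenated, and each sample's
#' source dataset recorded.
#'
#' @param ds_list List of >= 2 `omics_dataset`s of the same `feature_kind`
#'   (each already scaled per the study's policy). Names, if present, label
#'   the sources.
#' @return The merged `omics_dataset` with `sample_source` set.
#' @export
merge_datasets <- function(ds_list) {
  if (length(ds_list) < 2) {
    stop_refsig("refsig_merge_error", "need at least two datasets to merge")
  }
  kinds <- vapply(ds_list, function(d) d$feature_kind, "")
  if (length(unique(kinds)) != 1) {
    stop_refsig("refsig_merge_error", "datasets have different feature kinds")
  }
  feats <- Reduce(intersect, lapply(ds_list, function(d) rownames(d$values)))
  if (length(feats) == 0) {
    stop_refsig("refsig_merge_error", "feature intersection is empty")
  }
  all_samples <- unlist(lapply(ds_list, function(d) colnames(d$values)))
  if (anyDuplicated(all_samples)) {
    stop_refsig("refsig_merge_error",
                paste0("duplicate sample IDs across datasets: ",
                       paste(utils::head(unique(all_samples[duplicated(all_samples)]), 5),
                             collapse = ", ")))
  }
  src_names <- names(ds_list) %||% paste0("dataset", seq_along(ds_list))
  if (is.null(names(ds_list))) names(src_names) <- NULL
  values <- do.call(cbind, lapply(ds_list, function(d) d$values[feats, , drop = FALSE]))
  labels <- do.call(c, lapply(ds_list, function(d) d$labels))
  source <- unlist(mapply(function(d, nm) rep(nm, n_samples(d)),
                          ds_list, src_names, SIMPLIFY = FALSE))
  names(labels) <- all_samples
  colnames(values) <- all_samples
  omics_dataset(values, labels, kinds[1], sample_source = source)
}

#' Stratified cross-validation fold assignment
#'
#' Samples are shuffled within each class and dealt round-robin over the `k`
#' folds, so every fold's class counts are within one sample of the
#' class-proportional share -- the stratification used to accommodate
#' unbalanced case/control designs. Deterministic given `(labels, k, seed)`.
#'
#' @param labels Named binary label vector (0/1).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return A `fold_assignment`: list with `k`, `fold` (named integer vector,
#'   fold index in 1..k per sample), `seed`.
#' @export
make_stratified_folds <- function(labels, k, seed) {
  y <- as.integer(labels)
  n <- length(y)
  if (!is_count(k) || k < 2) {
    stop_refsig("refsig_value_error", "k must be an integer >= 2 (k = 1 leaves no held-out data)")
  }
  if (length(unique(y)) < 2) {
    stop_refsig("refsig_stratification_error", "both classes must be present")
  }
  if (k > n) stop_refsig("refsig_value_error", "more folds than samples")
  counts <- table(factor(y, levels = c(0L, 1L)))
  if (k > min(counts)) {
    warn_refsig("refsig_stratification_warning",
                sprintf("k = %d exceeds the minority class size (%d); some folds will lack a class",
                        k, min(counts)))
  }
  fold <- integer(n)
  with_seed(seed, {
    start <- 0L
    for (cl in c(1L, 0L)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
      start <- start + length(idx)
    }
  })
  names(fold) <- names(labels)
  structure(list(k = as.integer(k), fold = fold, seed = as.integer(seed)),
            class = "fold_assignment")
}
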