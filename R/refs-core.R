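#' Borda-count aggregation of importance vectors
#'
#' Each importance vector (one per classifier x fold) is converted to ranks
#' (largest importance = rank 1) and to Borda points `m - rank`; tied
#' importances receive the mean of the tied points. The aggregate score of a
#' feature is the sum of its points over all vectors.
#'
#' @param importance_vectors List of equal-length non-negative numeric
#'   vectors, all in the same feature order.
#' @param feature_ids Optional feature IDs; defaults to the names of the
#'   first vector.
#' @return A `feature_score_table`: named numeric vector of aggregate scores
#'   (all >= 0) with attribute `n_vectors`.
#' @export
#' @examples
#' borda_aggregate(list(c(a = 0.5, b = 0.2, c = 0.9))) # points 1, 0, 2
borda_aggregate <- function(importance_vectors, feature_ids = NULL) {
  if (!is.list(importance_vectors) || length(importance_vectors) == 0) {
    stop_refsig("refsig_input_error", "need a non-empty list of importance vectors")
  }
  m <- length(importance_vectors[[1]])
  if (any(lengths(importance_vectors) != m)) {
    stop_refsig("refsig_input_error", "importance vectors have unequal lengths")
  }
  feature_ids <- feature_ids %||% names(importance_vectors[[1]]) %||%
    paste0("f", seq_len(m))
  total <- numeric(m)
  for (v in importance_vectors) {
    total <- total + (m - rank(-as.numeric(v), ties.method = "average"))
  }
  structure(stats::setNames(total, feature_ids),
            n_vectors = length(importance_vectors),
            class = "feature_score_table")
}

#' One REFS iteration: fit the ensemble over all folds and score features
#'
#' For each of the k folds and each classifier: fit on the training part,
#' record held-out accuracy and the importance vector. Per-classifier
#' accuracy is the mean over folds; global accuracy is the unweighted mean
#' over classifiers; feature scores come from [borda_aggregate()] over all
#' (classifier, fold) importance vectors. A classifier that fails on a fold
#' is excluded from that (classifier, fold) cell with a warning.
#'
#' @param ds An `omics_dataset` restricted to the current feature set
#'   (already scaled).
#' @param folds A `fold_assignment` over the dataset's samples.
#' @param specs Ensemble from [classifier_specs()].
#' @param seed Base seed for the classifier fits.
#' @return List with `scores` (`feature_score_table`),
#'   `classifier_accuracy` (named numeric), `global_accuracy`, `n_vectors`
#'   and `failures` (character vector of failed classifier/fold cells).
#' @export
refs_iteration <- function(ds, folds, specs = classifier_specs(), seed = 1L) {
  X <- t(ds$values)
  y <- unname(ds$labels)
  fold_of <- folds$fold
  if (!is.null(names(fold_of)) && !is.null(rownames(X))) {
    fold_of <- fold_of[rownames(X)]
  }
  k <- folds$k
  acc <- matrix(NA_real_, length(specs), k,
                dimnames = list(names(specs), NULL))
  vectors <- list()
  failures <- character(0)
  for (j in seq_len(k)) {
    test <- which(fold_of == j)
    train <- which(fold_of != j)
    if (length(test) == 0) next
    for (i in seq_along(specs)) {
      fit <- tryCatch(
        fit_classifier(specs[[i]], X[train, , drop = FALSE], y[train],
                       seed = derive_seed(seed, i, j)),
        error = function(e) e
      )
      if (inherits(fit, "error")) {
        failures <- c(failures, sprintf("%s/fold%d: %s",
                                        names(specs)[i], j, conditionMessage(fit)))
        next
      }
      pred <- predict_classifier(fit, X[test, , drop = FALSE])
      acc[i, j] <- mean(pred == y[test])
      vectors[[length(vectors) + 1L]] <- importance_vector(fit)
    }
  }
  if (length(vectors) == 0) {
    stop_refsig("refsig_iteration_error", "every classifier failed on every fold")
  }
  if (length(failures) > 0) {
    warn_refsig("refsig_fit_warning",
                paste0(length(failures), " classifier fit(s) failed and were excluded"))
  }
  clf_acc <- rowMeans(acc, na.rm = TRUE)
  clf_acc[is.nan(clf_acc)] <- NA_real_
  list(scores = borda_aggregate(vectors, feature_ids = colnames(X)),
       classifier_accuracy = clf_acc,
       global_accuracy = mean(clf_acc, na.rm = TRUE),
       n_vectors = length(vectors),
       failures = failures)
}

# next retained count: drop reduce_frac of the features, keeping at least
# one-fewer so the schedule always advances
next_m <- function(m, reduce_frac = 0.2) {
  m2 <- ceiling((1 - reduce_frac) * m)
  if (m2 >= m) m2 <- m - 1L
  as.integer(m2)
}

#' The feature-count schedule of the recursive reduction
#'
#' Starting from `m0`, repeatedly retains `ceiling((1 - reduce_frac) * m)`
#' features (with a drop-1 guard when rounding would stall), down to a single
#' feature. This is the exact schedule [run_refs()] walks (it may stop early
#' when accuracy drops).
#'
#' @param m0 Starting feature count.
#' @param reduce_frac Fraction removed per step (default 0.2).
#' @return Integer vector of retained counts, `m0` first, strictly
#'   decreasing, ending at 1.
#' @export
#' @examples
#' reduction_schedule(100)[1:8] # 100 80 64 52 42 34 28 23
reduction_schedule <- function(m0, reduce_frac = 0.2) {
  stopifnot(is_count(m0), m0 >= 1)
  out <- as.integer(m0)
  m <- as.integer(m0)
  while (m > 1L) {
    m <- next_m(m, reduce_frac)
    out <- c(out, m)
  }
  out
}

#' Run the recursive ensemble feature selection
#'
#' Iteratively fits the classifier ensemble under stratified k-fold CV,
#' scores features by Borda aggregation of the per-(classifier, fold)
#' importance vectors, and retains the top `ceiling((1 - reduce_frac) * m)`
#' features for the next iteration. The loop continues while the global
#' accuracy stays strictly above `stop_accuracy` and more than one feature
#' remains; the terminating iteration is recorded in the trace.
#'
#' @param ds An `omics_dataset` (>= 2 features, both classes present),
#'   already scaled.
#' @param k_folds Folds for the stratified CV (default 10).
#' @param reduce_frac Fraction of features removed per iteration
#'   (default 0.20).
#' @param stop_accuracy Stop threshold on global accuracy (default 0.70,
#'   strict `>` continues).
#' @param initial_keep Optional feature count for an aggressive first cut:
#'   after the first iteration only the `initial_keep` best-scoring features
#'   are retained. `NULL` (default) uses the plain schedule throughout.
#' @param seed Seed for the fold assignment and (derived) classifier seeds.
#' @param specs Ensemble from [classifier_specs()].
#' @return A `refs_trace`: list of per-iteration records (`m`, `features`,
#'   `classifier_accuracy`, `global_accuracy`, `scores`) plus the run
#'   configuration. Retained counts are strictly decreasing and feature sets
#'   nested.
#' @export
run_refs <- function(ds, k_folds = 10, reduce_frac = 0.2, stop_accuracy = 0.7,
                     initial_keep = NULL, seed = 1L,
                     specs = classifier_specs()) {
  if (n_features(ds) < 2) {
    stop_refsig("refsig_value_error", "need at least two features")
  }
  folds <- make_stratified_folds(ds$labels, k_folds, seed)
  features <- rownames(ds$values)
  iterations <- list()
  iter <- 1L
  repeat {
    cur <- ds_restrict(ds, features)
    it <- refs_iteration(cur, folds, specs, seed = derive_seed(seed, 7L, iter))
    iterations[[iter]] <- list(
      m = length(features), features = features,
      classifier_accuracy = it$classifier_accuracy,
      global_accuracy = it$global_accuracy,
      scores = as.numeric(it$scores), score_features = names(it$scores),
      n_vectors = it$n_vectors
    )
    if (!(it$global_accuracy > stop_accuracy) || length(features) <= 1L) break
    m_new <- if (iter == 1L && !is.null(initial_keep)) {
      min(as.integer(initial_keep), length(features) - 1L)
    } else {
      next_m(length(features), reduce_frac)
    }
    if (m_new < 1L) break
    ord <- order(-as.numeric(it$scores), names(it$scores))
    features <- names(it$scores)[ord][seq_len(m_new)]
    iter <- iter + 1L
  }
  gc(verbose = FALSE)  # release external handles accumulated by the ensemble fits
  structure(list(iterations = iterations,
                 config = list(k_folds = k_folds, reduce_frac = reduce_frac,
                               stop_accuracy = stop_accuracy,
                               initial_keep = initial_keep, seed = seed),
                 folds = folds),
            class = "refs_trace")
}

#' @export
print.refs_trace <- function(x, ...) {
  m <- vapply(x$iterations, `[[`, 0, "m")
  g <- vapply(x$iterations, `[[`, 0, "global_accuracy")
  cat(sprintf("refs_trace: %d iterations, m %d -> %d, final global accuracy %.3f\n",
              length(m), m[1], m[length(m)], g[length(g)]))
  invisible(x)
}

#' Accuracy-versus-feature-count table of one or more REFS traces
#'
#' @param traces A `refs_trace` or list of them.
#' @return Data frame with columns `run`, `iteration`, `m`,
#'   `global_accuracy`.
#' @export
trace_accuracy_table <- function(traces) {
  if (inherits(traces, "refs_trace")) traces <- list(traces)
  do.call(rbind, lapply(seq_along(traces), function(r) {
    its <- traces[[r]]$iterations
    data.frame(run = r, iteration = seq_along(its),
               m = vapply(its, `[[`, 0, "m"),
               global_accuracy = vapply(its, `[[`, 0, "global_accuracy"))
  }))
}

#' Consensus signature over repeated REFS runs
#'
#' Global accuracies are averaged per retained count `m` across runs (only
#' counts visited by every run are eligible); the optimal signature size is
#' the `m` maximising the run-averaged accuracy (smallest `m` on ties). The
#' signature consists of the `optimal_m` features most frequently retained at
#' that size across runs; frequency ties are broken by higher mean Borda
#' score at that iteration, then lexicographic feature ID.
#'
#' @param traces List of `refs_trace` objects from repeated runs on the same
#'   dataset (a single trace is accepted).
#' @return A `signature_set`: list with `feature_ids`, `optimal_m`,
#'   `selection_frequency` (named, fraction of runs retaining each signature
#'   feature), `n_runs`, and `accuracy_by_m` (data.frame of run-averaged
#'   accuracies).
#' @export
select_optimal <- function(traces) {
  if (inherits(traces, "refs_trace")) traces <- list(traces)
  if (length(traces) == 0) stop_refsig("refsig_selection_error", "no traces given")
  m_lists <- lapply(traces, function(tr) vapply(tr$iterations, `[[`, 0, "m"))
  common_m <- Reduce(intersect, m_lists)
  if (length(common_m) == 0) {
    stop_refsig("refsig_selection_error", "runs share no common feature count")
  }
  acc_by_m <- vapply(common_m, function(m) {
    mean(vapply(seq_along(traces), function(r) {
      i <- match(m, m_lists[[r]])
      traces[[r]]$iterations[[i]]$global_accuracy
    }, 0))
  }, 0)
  ord <- order(-acc_by_m, common_m)
  optimal_m <- as.integer(common_m[ord[1]])

  n_runs <- length(traces)
  feats <- character(0); borda <- list()
  for (r in seq_len(n_runs)) {
    i <- match(optimal_m, m_lists[[r]])
    it <- traces[[r]]$iterations[[i]]
    feats <- c(feats, it$features)
    sc <- stats::setNames(it$scores, it$score_features)
    borda[[r]] <- sc[it$features]
  }
  freq <- table(feats) / n_runs
  mean_borda <- tapply(unlist(borda), unlist(lapply(borda, names)), mean)
  pool <- names(freq)
  ord <- order(-as.numeric(freq[pool]), -as.numeric(mean_borda[pool]), pool)
  chosen <- pool[ord][seq_len(min(optimal_m, length(pool)))]
  structure(list(
    feature_ids = chosen,
    optimal_m = optimal_m,
    selection_frequency = stats::setNames(as.numeric(freq[chosen]), chosen),
    n_runs = n_runs,
    accuracy_by_m = data.frame(m = common_m, mean_global_accuracy = acc_by_m)
  ), class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: %d features (optimal m = %d, %d run%s)\n",
              length(x$feature_ids), x$optimal_m, x$n_runs,
              if (x$n_runs == 1) "" else "s"))
  cat("  ", paste(utils::head(x$feature_ids, 10), collapse = ", "),
      if (length(x$feature_ids) > 10) "..." else "", "\n")
  invisible(x)
}

#' Univariate chi-squared baseline feature selection
#'
#' Scores each feature by the chi-squared statistic between its class-wise
#' non-negative totals and the expectation proportional to class sizes (the
#' usual "select k best by chi2" baseline), and returns the top `k`. Since
#' standardised matrices contain negative values, each feature is shifted to
#' a minimum of zero first (`shift = TRUE`, default); with `shift = FALSE`
#' negative values are an error.
#'
#' @param ds An `omics_dataset`.
#' @param k Number of features to keep (<= feature count).
#' @param shift Min-shift each feature to zero before scoring.
#' @return A `signature_set` with the `k` top-scoring features (ordered by
#'   decreasing statistic) and the chi-squared scores as attribute
#'   `"chi2_scores"`.
#' @export
univariate_chi2_select <- function(ds, k, shift = TRUE) {
  if (!is_count(k) || k < 1 || k > n_features(ds)) {
    stop_refsig("refsig_value_error", "k must be in 1..n_features")
  }
  X <- ds$values
  if (shift) {
    X <- X - apply(X, 1, min)
  } else if (any(X < 0)) {
    stop_refsig("refsig_value_error",
                "negative feature values; enable `shift` or supply non-negative data")
  }
  y <- ds$labels
  n1 <- sum(y == 1L); n0 <- sum(y == 0L); n <- n1 + n0
  O1 <- rowSums(X[, y == 1L, drop = FALSE])
  O0 <- rowSums(X[, y == 0L, drop = FALSE])
  tot <- O0 + O1
  E1 <- tot * n1 / n
  E0 <- tot * n0 / n
  term <- function(o, e) ifelse(e > 0, (o - e)^2 / e, 0)
  chi2 <- term(O0, E0) + term(O1, E1)
  ord <- order(-chi2, rownames(X))
  chosen <- rownames(X)[ord][seq_len(k)]
  out <- structure(list(
    feature_ids = chosen, optimal_m = as.integer(k),
    selection_frequency = stats::setNames(rep(1, k), chosen),
    n_runs = 1L,
    accuracy_by_m = NULL
  ), class = "signature_set")
  attr(out, "chi2_scores") <- chi2[ord][seq_len(k)]
  out
}
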