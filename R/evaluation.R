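#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the distinct score values (tied scores
#' form one threshold step), accumulating (FPR, TPR) points from (0, 0) to
#' (1, 1); the AUC is the trapezoidal area under the resulting polyline.
#'
#' @param scores Real-valued per-sample scores, higher = more case-like.
#' @param labels Binary 0/1 labels (both classes must be present).
#' @return List with `points` (data.frame `fpr`, `tpr`, both non-decreasing)
#'   and `auc` in \[0, 1\].
#' @export
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc # 0.75
roc_auc <- function(scores, labels) {
  y <- as.integer(labels)
  if (length(scores) != length(y)) {
    stop_refsig("refsig_input_error", "scores and labels differ in length")
  }
  if (any(!is.finite(scores))) {
    stop_refsig("refsig_value_error", "scores must be finite")
  }
  P <- sum(y == 1L); N <- sum(y == 0L)
  if (P == 0 || N == 0) {
    stop_refsig("refsig_value_error", "both classes must be present")
  }
  ord <- order(-scores)
  s <- scores[ord]; yy <- y[ord]
  # group tied scores into single threshold steps
  grp_end <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(yy)[grp_end]
  fp <- (grp_end - cumsum(yy)[grp_end])
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Cross-validated evaluation of a fixed feature signature
#'
#' Fits the full classifier ensemble on the dataset restricted to the
#' signature under stratified k-fold CV and reports, per classifier, the
#' mean and (population) standard deviation of the fold accuracies; the
#' global accuracy is the unweighted mean of the per-classifier means. ROC
#' and AUC are computed from the pooled out-of-fold decision scores of the
#' designated scorer.
#'
#' @param ds An `omics_dataset` (scaled) containing the signature features.
#' @param features Character vector of signature feature IDs, or a
#'   `signature_set`.
#' @param k_folds CV folds (default 10).
#' @param seed Fold/classifier seed.
#' @param specs Ensemble from [classifier_specs()].
#' @param scorer Classifier whose out-of-fold scores feed the ROC (default
#'   `"logistic_regression"`), or `"mean"` for the mean of all available
#'   classifier scores.
#' @param folds Optional pre-built `fold_assignment` (overrides
#'   `k_folds`/`seed` for the partition).
#' @return An `evaluation_report`: `classifier_accuracy` data.frame
#'   (`classifier`, `mu`, `sigma`), `global_accuracy`, `roc` (points + `auc`),
#'   `n_features_used`, `features`.
#' @export
evaluate_signature <- function(ds, features, k_folds = 10, seed = 1L,
                               specs = classifier_specs(),
                               scorer = "logistic_regression", folds = NULL) {
  if (inherits(features, "signature_set")) features <- features$feature_ids
  feats <- intersect(features, rownames(ds$values))
  if (length(feats) == 0) {
    stop_refsig("refsig_evaluation_error",
                "signature shares no features with the dataset")
  }
  sub <- ds_restrict(ds, feats)
  folds <- folds %||% make_stratified_folds(ds$labels, k_folds, seed)
  X <- t(sub$values)
  y <- unname(sub$labels)
  fold_of <- folds$fold
  if (!is.null(names(fold_of))) fold_of <- fold_of[rownames(X)]
  k <- folds$k
  acc <- matrix(NA_real_, length(specs), k,
                dimnames = list(names(specs), NULL))
  oof <- matrix(NA_real_, length(specs), length(y),
                dimnames = list(names(specs), NULL))
  for (j in seq_len(k)) {
    test <- which(fold_of == j); train <- which(fold_of != j)
    if (length(test) == 0) next
    for (i in seq_along(specs)) {
      fit <- tryCatch(
        fit_classifier(specs[[i]], X[train, , drop = FALSE], y[train],
                       seed = derive_seed(seed, i, j, 99L)),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      acc[i, j] <- mean(predict_classifier(fit, X[test, , drop = FALSE]) == y[test])
      oof[i, test] <- score_classifier(fit, X[test, , drop = FALSE])
    }
  }
  mu <- rowMeans(acc, na.rm = TRUE)
  sigma <- apply(acc, 1, function(a) pop_sd(a[!is.na(a)]))
  scores <- if (identical(scorer, "mean")) {
    colMeans(oof, na.rm = TRUE)
  } else {
    if (!scorer %in% rownames(oof)) {
      stop_refsig("refsig_config_error", paste0("scorer not in ensemble: ", scorer))
    }
    oof[scorer, ]
  }
  roc <- if (all(is.finite(scores))) roc_auc(scores, y) else NULL
  structure(list(
    classifier_accuracy = data.frame(classifier = names(specs),
                                     mu = unname(mu), sigma = unname(sigma)),
    global_accuracy = mean(mu, na.rm = TRUE),
    roc = roc,
    auc = if (is.null(roc)) NA_real_ else roc$auc,
    n_features_used = length(feats),
    features = feats,
    oof_scores = scores,
    scorer = scorer
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: %d features\n", x$n_features_used))
  tab <- x$classifier_accuracy
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-20s mu = %.4f  sigma = %.4f\n",
                tab$classifier[i], tab$mu[i], tab$sigma[i]))
  }
  cat(sprintf("  %-20s mu = %.4f\n", "Average", x$global_accuracy))
  if (!is.null(x$roc)) cat(sprintf("  AUC = %.4f\n", x$auc))
  invisible(x)
}

#' Wilks' lambda to F transformation for a two-group MANOVA
#'
#' For two groups the Wilks statistic converts exactly to an F statistic:
#' `F = (df_e / df_h) * (1 - lambda) / lambda`.
#'
#' @param lambda Wilks' lambda in (0, 1\].
#' @param df_h Hypothesis degrees of freedom (number of response features).
#' @param df_e Error degrees of freedom.
#' @return The F statistic.
#' @export
#' @examples
#' wilks_to_f(0.445, 23, 95) # 5.15 at 2 d.p.
wilks_to_f <- function(lambda, df_h, df_e) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0 || lambda > 1) {
    stop_refsig("refsig_value_error", "lambda must lie in (0, 1]")
  }
  if (df_h <= 0 || df_e <= 0) {
    stop_refsig("refsig_value_error", "degrees of freedom must be positive")
  }
  (df_e / df_h) * (1 - lambda) / lambda
}

#' Two-group MANOVA via Wilks' lambda
#'
#' Computes the within-group (E) and between-group (H) SSCP matrices of the
#' signature features, Wilks' lambda = det(E) / det(E + H), the exact
#' two-group F transformation with df_h = p and df_e = n - p - 1, its
#' p-value, and the uncentered R-squared = 1 - lambda.
#'
#' @param ds An `omics_dataset` restricted to the signature (or any dataset
#'   plus `features` to restrict by).
#' @param features Optional feature subset.
#' @return A `manova_result`: `wilks_lambda`, `f_stat`, `df_h`, `df_e`,
#'   `p_value`, `r2_uncentered`.
#' @export
manova_two_group <- function(ds, features = NULL) {
  if (!is.null(features)) ds <- ds_restrict(ds, features)
  Y <- t(ds$values)
  y <- unname(ds$labels)
  p <- ncol(Y); n <- nrow(Y)
  if (length(unique(y)) < 2) {
    stop_refsig("refsig_value_error", "both classes must be present")
  }
  if (p >= n - 1) {
    stop_refsig("refsig_dimension_error",
                sprintf("p = %d features require n > p + 1 samples (n = %d)", p, n))
  }
  grand <- colMeans(Y)
  E <- matrix(0, p, p)
  H <- matrix(0, p, p)
  for (g in c(0L, 1L)) {
    Yg <- Y[y == g, , drop = FALSE]
    mg <- colMeans(Yg)
    E <- E + crossprod(sweep(Yg, 2, mg))
    H <- H + nrow(Yg) * tcrossprod(mg - grand)
  }
  ldE <- determinant(E, logarithm = TRUE)
  ldT <- determinant(E + H, logarithm = TRUE)
  if (ldE$sign <= 0 || ldT$sign <= 0 || !is.finite(ldE$modulus) || !is.finite(ldT$modulus)) {
    rk <- qr(E + H)$rank
    stop_refsig("refsig_linear_algebra_error",
                sprintf("singular SSCP matrix (rank %d of %d); remove collinear features", rk, p))
  }
  lambda <- exp(as.numeric(ldE$modulus) - as.numeric(ldT$modulus))
  lambda <- min(lambda, 1)
  df_h <- p
  df_e <- n - p - 1
  f_stat <- wilks_to_f(lambda, df_h, df_e)
  structure(list(
    wilks_lambda = lambda, f_stat = f_stat, df_h = df_h, df_e = df_e,
    p_value = stats::pf(f_stat, df_h, df_e, lower.tail = FALSE),
    r2_uncentered = 1 - lambda
  ), class = "manova_result")
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf("MANOVA (two groups): F(%d, %d) = %.4f, p = %.3g\n",
              x$df_h, x$df_e, x$f_stat, x$p_value))
  cat(sprintf("  Wilks' lambda = %.4f, R-squared (uncentered) = %.4f\n",
              x$wilks_lambda, x$r2_uncentered))
  invisible(x)
}
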