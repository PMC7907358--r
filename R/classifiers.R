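#' Specifications of the eight-classifier ensemble
#'
#' The ensemble mixes tree-based and coefficient-based topologies: bagged
#' trees, gradient boosting and random forest (tree family, 300 estimators by
#' default) alongside logistic regression, passive-aggressive, SGD (hinge),
#' linear SVC and ridge (coefficient family). Feature importance is
#' split-usage based for the tree family and absolute coefficient magnitude
#' for the linear family.
#'
#' @param n_estimators Trees/boosting rounds for the tree-family members
#'   (default 300).
#' @param tree_importance `"impurity"` (default) scores tree features by
#'   impurity decrease; `"split_count"` by how often a feature is used to
#'   split.
#' @param include Optional character vector restricting the ensemble to a
#'   subset of classifier names.
#' @return A named list of `classifier_spec` objects with fields `name`,
#'   `family` and `hyperparams`.
#' @export
classifier_specs <- function(n_estimators = 300,
                             tree_importance = c("impurity", "split_count"),
                             include = NULL) {
  tree_importance <- match.arg(tree_importance)
  mk <- function(name, family, hp = list()) {
    structure(list(name = name, family = family, hyperparams = hp),
              class = "classifier_spec")
  }
  tree_hp <- list(n_estimators = n_estimators, tree_importance = tree_importance)
  specs <- list(
    gradient_boosting  = mk("gradient_boosting", "tree_ensemble",
                            c(tree_hp, list(max_depth = 3, eta = 0.1))),
    random_forest      = mk("random_forest", "tree_ensemble", tree_hp),
    logistic_regression = mk("logistic_regression", "coefficient_based",
                             list(C = 1)),
    passive_aggressive = mk("passive_aggressive", "coefficient_based",
                            list(C = 1, epochs = 5)),
    sgd                = mk("sgd", "coefficient_based",
                            list(alpha = 1e-4, eta0 = 0.1, epochs = 5)),
    svc_linear         = mk("svc_linear", "coefficient_based", list(cost = 1)),
    ridge              = mk("ridge", "coefficient_based", list(alpha = 1)),
    bagging            = mk("bagging", "tree_ensemble", tree_hp)
  )
  if (!is.null(include)) {
    unknown <- setdiff(include, names(specs))
    if (length(unknown) > 0) {
      stop_refsig("refsig_config_error",
                  paste0("unknown classifier(s): ", paste(unknown, collapse = ", ")))
    }
    specs <- specs[include]
  }
  specs
}

#' Fit one classifier of the ensemble
#'
#' @param spec A `classifier_spec` from [classifier_specs()].
#' @param X Numeric matrix, samples in rows, features in columns (with column
#'   names).
#' @param y Integer 0/1 labels, one per row of X.
#' @param seed Integer seed controlling every stochastic element of the fit.
#' @return A `refsig_fit` object with the fitted model, its per-feature
#'   importance vector and prediction closures.
#' @export
fit_classifier <- function(spec, X, y, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (!is.matrix(X)) X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- as.integer(y)
  hp <- spec$hyperparams
  fit <- switch(
    spec$name,
    gradient_boosting = fit_xgboost(X, y, hp, seed),
    random_forest = fit_ranger(X, y, hp, seed, bagged = FALSE),
    bagging = fit_ranger(X, y, hp, seed, bagged = TRUE),
    logistic_regression = fit_logistic(X, y, hp),
    passive_aggressive = fit_passive_aggressive(X, y, hp, seed),
    sgd = fit_sgd(X, y, hp, seed),
    svc_linear = fit_svc_linear(X, y, hp),
    ridge = fit_ridge(X, y, hp),
    stop_refsig("refsig_config_error", paste0("unknown classifier: ", spec$name))
  )
  fit$spec <- spec
  class(fit) <- c(paste0("refsig_fit_", spec$name), "refsig_fit")
  fit
}

#' Predicted class labels / decision scores of a fitted classifier
#'
#' @param fit A `refsig_fit`.
#' @param X New data matrix (samples x features, same columns as at fit time).
#' @return `predict_classifier`: integer 0/1 labels. `score_classifier`: a
#'   real-valued score per sample, higher meaning more case-like (class 1);
#'   probabilities for the probabilistic models, margins for the others.
#' @export
predict_classifier <- function(fit, X) {
  stopifnot(inherits(fit, "refsig_fit"))
  if (!is.matrix(X)) X <- as.matrix(X)
  fit$predict(X)
}

#' @rdname predict_classifier
#' @export
score_classifier <- function(fit, X) {
  stopifnot(inherits(fit, "refsig_fit"))
  if (!is.matrix(X)) X <- as.matrix(X)
  fit$score(X)
}

#' Per-feature importance of a fitted classifier
#'
#' Tree-family models report split-usage importance (impurity decrease or
#' split counts, per the spec's `tree_importance`), normalised to sum to 1
#' when any splits exist. Coefficient-family models report absolute
#' coefficient magnitude. The vector covers every feature the model was
#' fitted on (zeros for unused features) in training-column order.
#'
#' @param fit A `refsig_fit` (an unfitted object raises a state error).
#' @return Named non-negative numeric vector, one entry per feature.
#' @export
importance_vector <- function(fit) {
  if (!inherits(fit, "refsig_fit") || is.null(fit$importance)) {
    stop_refsig("refsig_state_error",
                "importance_vector requires a fitted classifier (refsig_fit)")
  }
  fit$importance
}

# ---- backends --------------------------------------------------------------

fit_xgboost <- function(X, y, hp, seed) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  params <- list(objective = "binary:logistic",
                 max_depth = hp$max_depth %||% 3,
                 eta = hp$eta %||% 0.1,
                 nthread = 1, seed = as.integer(seed))
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = hp$n_estimators %||% 300, verbose = 0)
  measure <- if ((hp$tree_importance %||% "impurity") == "split_count") "Frequency" else "Gain"
  imp <- stats::setNames(numeric(ncol(X)), colnames(X))
  tab <- tryCatch(xgboost::xgb.importance(model = booster), error = function(e) NULL)
  if (!is.null(tab) && nrow(tab) > 0) {
    imp[tab$Feature] <- tab[[measure]]
    if (sum(imp) > 0) imp <- imp / sum(imp)
  }
  list(
    model = booster, importance = imp,
    score = function(Xn) {
      as.numeric(stats::predict(booster, xgboost::xgb.DMatrix(Xn, nthread = 1)))
    },
    predict = function(Xn) {
      as.integer(stats::predict(booster, xgboost::xgb.DMatrix(Xn, nthread = 1)) > 0.5)
    }
  )
}

fit_ranger <- function(X, y, hp, seed, bagged) {
  # bagged trees = a random forest whose mtry spans all features
  mtry <- if (bagged) ncol(X) else max(1L, floor(sqrt(ncol(X))))
  fit <- ranger::ranger(
    x = X, y = factor(y, levels = c(0L, 1L)),
    num.trees = hp$n_estimators %||% 300, mtry = mtry,
    importance = "impurity", probability = TRUE,
    seed = as.integer(seed), num.threads = 1, verbose = FALSE
  )
  imp <- fit$variable.importance
  if ((hp$tree_importance %||% "impurity") == "split_count") {
    imp <- ranger_split_counts(fit, colnames(X))
  }
  imp <- pmax(imp[colnames(X)], 0)
  names(imp) <- colnames(X)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  list(
    model = fit, importance = imp,
    score = function(Xn) {
      as.numeric(stats::predict(fit, data = Xn, num.threads = 1)$predictions[, "1"])
    },
    predict = function(Xn) {
      as.integer(stats::predict(fit, data = Xn, num.threads = 1)$predictions[, "1"] > 0.5)
    }
  )
}

# how often each feature is used as a split variable, across all trees
ranger_split_counts <- function(fit, feature_names) {
  counts <- stats::setNames(numeric(length(feature_names)), feature_names)
  for (t in seq_len(fit$num.trees)) {
    info <- ranger::treeInfo(fit, tree = t)
    used <- info$splitvarName[!is.na(info$splitvarName)]
    if (length(used) > 0) {
      tab <- table(used)
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
  }
  counts
}

fit_logistic <- function(X, y, hp) {
  n <- nrow(X)
  if (ncol(X) >= 2) {
    # L2-penalised logistic; lambda = 1/(C*n) matches the usual C=1
    # convention. glmnet's small-class advisory is expected with tiny CV
    # folds and muted.
    fit <- suppressWarnings(
      glmnet::glmnet(X, factor(y, levels = c(0L, 1L)), family = "binomial",
                     alpha = 0, lambda = 1 / ((hp$C %||% 1) * n),
                     standardize = FALSE))
    beta <- as.numeric(stats::coef(fit))
  } else {
    co <- suppressWarnings(
      stats::glm.fit(cbind(1, X), y, family = stats::binomial())$coefficients)
    co[is.na(co)] <- 0
    beta <- co
  }
  b <- beta[1]
  w <- stats::setNames(beta[-1], colnames(X))
  linear_fit(w, b, link = "logistic")
}

fit_ridge <- function(X, y, hp) {
  # closed-form ridge regression on +-1 labels, intercept unpenalised
  alpha <- hp$alpha %||% 1
  y2 <- ifelse(y == 1L, 1, -1)
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  yc <- y2 - mean(y2)
  p <- ncol(X); n <- nrow(X)
  w <- if (p <= n) {
    as.numeric(solve(crossprod(Xc) + diag(alpha, p), crossprod(Xc, yc)))
  } else {
    as.numeric(crossprod(Xc, solve(tcrossprod(Xc) + diag(alpha, n), yc)))
  }
  b <- mean(y2) - sum(xm * w)
  linear_fit(stats::setNames(w, colnames(X)), b)
}

fit_svc_linear <- function(X, y, hp) {
  # suppress libsvm's small-class advisory; tiny CV folds are expected here
  fit <- suppressWarnings(
    e1071::svm(x = X, y = factor(y, levels = c(0L, 1L)),
               kernel = "linear", cost = hp$cost %||% 1, scale = FALSE))
  w <- as.numeric(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # libsvm orients the decision value towards whichever class it saw first;
  # recover the orientation from the model's own training predictions
  pred <- as.integer(as.character(stats::predict(fit, X)))
  margin_pred <- as.integer(X %*% w + b > 0)
  if (mean(margin_pred == pred) < 0.5) { w <- -w; b <- -b }
  linear_fit(stats::setNames(w, colnames(X)), b)
}

fit_passive_aggressive <- function(X, y, hp, seed) {
  # PA-I online updates, tau = min(C, hinge loss / ||x||^2); the returned
  # model is the iterate average, which is far more stable than the last
  # iterate on noisy data
  C <- hp$C %||% 1
  epochs <- hp$epochs %||% 5
  y2 <- ifelse(y == 1L, 1, -1)
  n <- nrow(X); p <- ncol(X)
  w <- numeric(p); b <- 0
  w_bar <- numeric(p); b_bar <- 0; steps <- 0
  with_seed(seed, {
    for (e in seq_len(epochs)) {
      for (i in sample.int(n)) {
        x <- X[i, ]
        loss <- max(0, 1 - y2[i] * (sum(w * x) + b))
        if (loss > 0) {
          tau <- min(C, loss / (sum(x * x) + 1))
          w <- w + tau * y2[i] * x
          b <- b + tau * y2[i]
        }
        w_bar <- w_bar + w; b_bar <- b_bar + b; steps <- steps + 1
      }
    }
  })
  linear_fit(stats::setNames(w_bar / steps, colnames(X)), b_bar / steps)
}

fit_sgd <- function(X, y, hp, seed) {
  # averaged SGD on hinge loss with L2 penalty and inverse-scaling rate
  alpha <- hp$alpha %||% 1e-4
  eta0 <- hp$eta0 %||% 0.1
  epochs <- hp$epochs %||% 5
  y2 <- ifelse(y == 1L, 1, -1)
  n <- nrow(X); p <- ncol(X)
  w <- numeric(p); b <- 0; t <- 0
  w_bar <- numeric(p); b_bar <- 0
  with_seed(seed, {
    for (e in seq_len(epochs)) {
      for (i in sample.int(n)) {
        eta <- eta0 / (1 + alpha * eta0 * t)
        x <- X[i, ]
        margin <- y2[i] * (sum(w * x) + b)
        w <- w * (1 - eta * alpha)
        if (margin < 1) {
          w <- w + eta * y2[i] * x
          b <- b + eta * y2[i]
        }
        w_bar <- w_bar + w; b_bar <- b_bar + b; t <- t + 1
      }
    }
  })
  linear_fit(stats::setNames(w_bar / t, colnames(X)), b_bar / t)
}

# shared wrapper for the linear models: decision score X w + b
linear_fit <- function(w, b, link = c("margin", "logistic")) {
  link <- match.arg(link)
  score <- function(Xn) {
    s <- as.numeric(Xn[, names(w), drop = FALSE] %*% w + b)
    if (link == "logistic") stats::plogis(s) else s
  }
  thr <- if (link == "logistic") 0.5 else 0
  list(
    model = list(w = w, b = b), importance = abs(w),
    score = score,
    predict = function(Xn) as.integer(score(Xn) > thr)
  )
}
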