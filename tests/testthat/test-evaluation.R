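# ROC/AUC, signature evaluation, and the two-group MANOVA.

# brute-force Mann-Whitney oracle: fraction of (case, control) pairs ranked
# correctly, ties counting one half
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

test_that("ROC handles the canonical worked examples", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(-c(0, 0, 1, 1), c(0, 0, 1, 1))$auc, 0.0)
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(utils::tail(r$points$fpr, 1), 1)
  expect_equal(utils::tail(r$points$tpr, 1), 1)
})

test_that("trapezoidal AUC equals the pairwise oracle, ties included", {
  set.seed(31)
  for (rep in 1:60) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, stats::rbinom(n - 2, 1, 0.5))
    scores <- round(stats::rnorm(n), sample(0:2, 1))  # rounding creates ties
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, auc_oracle(scores, labels), tolerance = 1e-12)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
  }
})

test_that("AUC agrees with the field-standard implementation", {
  skip_if_not_installed("pROC")
  set.seed(32)
  for (rep in 1:10) {
    n <- 40
    labels <- c(0, 1, stats::rbinom(n - 2, 1, 0.4))
    scores <- stats::rnorm(n) + labels
    ours <- roc_auc(scores, labels)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("degenerate score/label inputs are rejected", {
  expect_error(roc_auc(c(1, 2), c(1, 1)), class = "refsig_value_error")
  expect_error(roc_auc(c(1, Inf), c(0, 1)), class = "refsig_value_error")
  expect_error(roc_auc(c(1, 2, 3), c(0, 1)), class = "refsig_input_error")
})

test_that("perfectly separable data evaluates at ceiling", {
  pl <- planted_dataset(n1 = 40, n0 = 30, p = 6, k = 3, delta = 6, seed = 21)
  rep <- evaluate_signature(pl$ds, pl$truth$informative_probes,
                            k_folds = 5, seed = 1, specs = fast_specs())
  expect_true(all(rep$classifier_accuracy$mu > 0.97))
  expect_gt(rep$global_accuracy, 0.97)
  expect_gt(rep$auc, 0.99)
  expect_equal(rep$n_features_used, 3)
  expect_equal(rep$global_accuracy, mean(rep$classifier_accuracy$mu))
})

test_that("excluding a classifier averages over the remaining ones", {
  pl <- planted_dataset(n1 = 30, n0 = 20, p = 6, k = 2, delta = 3, seed = 22)
  seven <- fast_specs(include = setdiff(names(classifier_specs()), "bagging"))
  rep7 <- evaluate_signature(pl$ds, pl$truth$informative_probes,
                             k_folds = 5, seed = 1, specs = seven)
  expect_equal(nrow(rep7$classifier_accuracy), 7)
  expect_equal(rep7$global_accuracy, mean(rep7$classifier_accuracy$mu))
})

test_that("signature disjoint from the dataset is an evaluation error", {
  pl <- planted_dataset(n1 = 20, n0 = 20, p = 5, k = 2, delta = 2, seed = 23)
  expect_error(evaluate_signature(pl$ds, c("nope1", "nope2"), k_folds = 4),
               class = "refsig_evaluation_error")
})

test_that("wilks_to_f follows the exact two-group transformation", {
  expect_equal(wilks_to_f(1, 5, 50), 0)
  expect_equal(wilks_to_f(0.5, 10, 10), 1.0)
  expect_error(wilks_to_f(0, 5, 50), class = "refsig_value_error")
  expect_error(wilks_to_f(1.2, 5, 50), class = "refsig_value_error")
  expect_error(wilks_to_f(0.5, -1, 50), class = "refsig_value_error")
})

test_that("manova_two_group agrees with the stats::manova Wilks oracle", {
  set.seed(41)
  for (rep in 1:5) {
    n <- 50; p <- 4
    y <- rep(c(0L, 1L), c(20, 30))
    m <- t(matrix(rnorm(n * p), n, p) + outer(y, seq_len(p) / 4))
    dimnames(m) <- list(paste0("f", 1:p), paste0("s", 1:n))
    ds <- omics_dataset(m, stats::setNames(y, colnames(m)))
    got <- manova_two_group(ds)
    ref <- summary(stats::manova(t(m) ~ factor(y)), test = "Wilks")$stats
    expect_equal(got$wilks_lambda, unname(ref[1, "Wilks"]), tolerance = 1e-10)
    expect_equal(got$f_stat, unname(ref[1, "approx F"]), tolerance = 1e-10)
    expect_equal(got$df_h, unname(ref[1, "num Df"]))
    expect_equal(got$df_e, unname(ref[1, "den Df"]))
    expect_equal(got$p_value, unname(ref[1, "Pr(>F)"]), tolerance = 1e-10)
    # internal identities
    expect_identical(got$r2_uncentered, 1 - got$wilks_lambda)
    expect_equal(got$f_stat,
                 wilks_to_f(got$wilks_lambda, got$df_h, got$df_e))
  }
})

test_that("p = 1 MANOVA reduces to the one-way ANOVA F", {
  set.seed(42)
  y <- rep(c(0L, 1L), c(25, 35))
  x <- rnorm(60) + 0.8 * y
  m <- matrix(x, 1, 60, dimnames = list("f1", paste0("s", 1:60)))
  ds <- omics_dataset(m, stats::setNames(y, colnames(m)))
  got <- manova_two_group(ds)
  ref <- summary(stats::aov(x ~ factor(y)))[[1]]
  expect_equal(got$f_stat, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(got$p_value, ref[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("MANOVA guards dimensions and singular scatter", {
  set.seed(43)
  m <- matrix(rnorm(10 * 8), 10, 8,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:8)))
  ds <- omics_dataset(m, rep(c(0, 1), 4))
  expect_error(manova_two_group(ds), class = "refsig_dimension_error")
  # collinear features make E singular
  m2 <- matrix(rnorm(2 * 30), 2, 30)
  m2 <- rbind(m2, m2[1, ] * 2)
  dimnames(m2) <- list(paste0("f", 1:3), paste0("s", 1:30))
  ds2 <- omics_dataset(m2, rep(c(0, 1), 15))
  expect_error(manova_two_group(ds2), class = "refsig_linear_algebra_error")
})
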