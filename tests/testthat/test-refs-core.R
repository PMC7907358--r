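# Borda aggregation, the reduction schedule, the recursive loop, consensus
# selection and the chi-squared baseline.

# independent brute-force oracle: for each vector, points = m - rank with
# mean-shared ties, computed per feature by explicit pairwise comparison
borda_oracle <- function(vectors) {
  m <- length(vectors[[1]])
  total <- numeric(m)
  for (v in vectors) {
    for (i in seq_len(m)) {
      beaten <- sum(v < v[i])          # features strictly worse
      tied <- sum(v == v[i]) - 1       # share their points evenly
      total[i] <- total[i] + beaten + tied / 2
    }
  }
  total
}

test_that("borda points follow the m - rank rule with mean ties", {
  s <- borda_aggregate(list(c(a = 0.5, b = 0.2, c = 0.9)))
  expect_equal(unname(unclass(s))[1:3], c(1, 0, 2))
  expect_identical(names(s), c("a", "b", "c"))
  # two reversed rankings cancel
  s2 <- borda_aggregate(list(c(1, 2), c(2, 1)))
  expect_equal(unname(unclass(s2))[1:2], c(1, 1))
  # ties share points
  s3 <- borda_aggregate(list(c(3, 3, 1)))
  expect_equal(unname(unclass(s3))[1:3], c(1.5, 1.5, 0))
  expect_error(borda_aggregate(list(c(1, 2), c(1, 2, 3))),
               class = "refsig_input_error")
})

test_that("borda aggregation equals the brute-force oracle on random instances", {
  set.seed(101)
  for (rep in 1:100) {
    m <- sample(2:10, 1)
    nv <- sample(1:12, 1)
    vectors <- replicate(nv, {
      v <- stats::runif(m)
      if (stats::runif(1) < 0.3) v[sample(m, 2)] <- 0.5  # inject ties
      v
    }, simplify = FALSE)
    got <- as.numeric(borda_aggregate(vectors, paste0("f", 1:m)))
    expect_equal(got, borda_oracle(vectors), tolerance = 1e-12)
  }
})

test_that("the reduction schedule follows ceil(0.8 m) with the drop-1 guard", {
  sched <- reduction_schedule(100)
  expect_identical(sched[1:9], c(100L, 80L, 64L, 52L, 42L, 34L, 28L, 23L, 19L))
  expect_identical(utils::tail(sched, 5), c(5L, 4L, 3L, 2L, 1L))
  # strictly decreasing from any start, matching the recurrence
  for (m0 in c(2, 5, 17, 118, 4999, 20000)) {
    s <- reduction_schedule(m0)
    expect_identical(s[1], as.integer(m0))
    expect_true(all(diff(s) < 0))
    expect_identical(s[length(s)], 1L)
    for (i in seq_len(length(s) - 1)) {
      expected <- ceiling(0.8 * s[i])
      if (expected >= s[i]) expected <- s[i] - 1
      expect_identical(s[i + 1], as.integer(expected))
    }
  }
})

test_that("refs_iteration reports per-classifier and global accuracy", {
  pl <- planted_dataset(n1 = 40, n0 = 30, p = 8, k = 3, delta = 4, seed = 2)
  folds <- make_stratified_folds(pl$ds$labels, 5, seed = 1)
  it <- refs_iteration(pl$ds, folds, fast_specs(), seed = 1)
  expect_length(it$classifier_accuracy, 8)
  expect_equal(it$global_accuracy, mean(it$classifier_accuracy))
  expect_equal(attr(it$scores, "n_vectors"), 8 * 5)
  expect_s3_class(it$scores, "feature_score_table")
  expect_true(all(it$scores >= 0))
  # strong planted signal: near-ceiling accuracy
  expect_gt(it$global_accuracy, 0.9)
  # planted features outrank noise in the aggregate
  sc <- stats::setNames(as.numeric(it$scores), names(it$scores))
  planted <- pl$truth$informative_probes
  expect_gt(min(sc[planted]), max(sc[setdiff(names(sc), planted)]))
})

test_that("run_refs produces strictly decreasing, nested traces", {
  pl <- planted_dataset(n1 = 40, n0 = 30, p = 25, k = 4, delta = 3, seed = 3)
  tr <- run_refs(pl$ds, k_folds = 5, seed = 9, specs = fast_specs())
  m <- vapply(tr$iterations, `[[`, 0, "m")
  expect_true(all(diff(m) < 0))
  for (i in seq_len(length(m) - 1)) {
    expect_true(all(tr$iterations[[i + 1]]$features %in%
                      tr$iterations[[i]]$features))
  }
  # reruns with the same seed are bit-identical
  tr2 <- run_refs(pl$ds, k_folds = 5, seed = 9, specs = fast_specs())
  expect_equal(tr, tr2, tolerance = 0)
})

test_that("stop rule halts immediately when unattainable", {
  pl <- planted_dataset(n1 = 30, n0 = 20, p = 10, k = 2, delta = 3, seed = 4)
  tr <- run_refs(pl$ds, k_folds = 5, stop_accuracy = 1.0, seed = 1,
                 specs = fast_specs(include = c("logistic_regression", "ridge")))
  expect_length(tr$iterations, 1)
  expect_equal(tr$iterations[[1]]$m, 10)
})

test_that("initial_keep applies an aggressive first cut", {
  pl <- planted_dataset(n1 = 30, n0 = 20, p = 40, k = 3, delta = 3, seed = 5)
  tr <- run_refs(pl$ds, k_folds = 5, seed = 1, initial_keep = 12,
                 specs = fast_specs(include = c("logistic_regression", "ridge")))
  m <- vapply(tr$iterations, `[[`, 0, "m")
  expect_equal(m[1:2], c(40, 12))
})

test_that("single-class data cannot be folded", {
  m <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:10)))
  ds <- omics_dataset(m, rep(1L, 10))
  expect_error(run_refs(ds, k_folds = 5, seed = 1),
               class = "refsig_stratification_error")
})

test_that("select_optimal picks the accuracy-maximising size and is idempotent", {
  mk_iter <- function(m, acc) {
    feats <- paste0("f", seq_len(m))
    list(m = m, features = feats, classifier_accuracy = c(x = acc),
         global_accuracy = acc, scores = rev(seq_len(m)),
         score_features = feats, n_vectors = 1L)
  }
  tr <- structure(list(iterations = list(
    mk_iter(20, 0.80), mk_iter(10, 0.90), mk_iter(5, 0.95), mk_iter(2, 0.85)
  ), config = list()), class = "refs_trace")
  sig <- select_optimal(tr)
  expect_equal(sig$optimal_m, 5L)
  expect_setequal(sig$feature_ids, paste0("f", 1:5))
  expect_true(all(sig$selection_frequency == 1))
  # two identical runs give the same signature as one
  sig2 <- select_optimal(list(tr, tr))
  expect_identical(sig2$feature_ids, sig$feature_ids)
  expect_identical(sig2$optimal_m, sig$optimal_m)
  # exact accuracy ties resolve to the smallest m
  tr_tie <- structure(list(iterations = list(
    mk_iter(20, 0.9), mk_iter(10, 0.9), mk_iter(5, 0.8)
  ), config = list()), class = "refs_trace")
  expect_equal(select_optimal(tr_tie)$optimal_m, 10L)
})

test_that("chi-squared baseline matches the observed/expected hand computation", {
  # class totals equal; feature A sums (10, 30), feature B (20, 20)
  m <- matrix(c(5, 5, 15, 15,
                10, 10, 10, 10), 2, 4, byrow = TRUE,
              dimnames = list(c("A", "B"), paste0("s", 1:4)))
  ds <- omics_dataset(m, c(0, 0, 1, 1))
  sig <- univariate_chi2_select(ds, 2, shift = FALSE)
  expect_identical(sig$feature_ids, c("A", "B"))
  expect_equal(unname(attr(sig, "chi2_scores")), c(10, 0))
  # identical class-wise distribution -> statistic 0
  expect_equal(unname(attr(sig, "chi2_scores"))[2], 0)
  # k = all returns all features
  expect_setequal(univariate_chi2_select(ds, 2)$feature_ids, c("A", "B"))
  expect_error(univariate_chi2_select(ds, 3), class = "refsig_value_error")
})

test_that("chi-squared selection shifts standardized data and finds planted genes", {
  pl <- planted_dataset(n1 = 60, n0 = 40, p = 50, k = 5, delta = 3, seed = 6)
  sig <- univariate_chi2_select(pl$ds, 5)
  expect_gte(length(intersect(sig$feature_ids, pl$truth$informative_probes)), 4)
  neg <- pl$ds
  expect_error(univariate_chi2_select(neg, 5, shift = FALSE),
               class = "refsig_value_error")
})

test_that("permuted labels induce no selection bias toward planted features", {
  # under the null, signature/planted overlap must be hypergeometric-
  # consistent, and held-out accuracy must never exceed the majority-rate
  # binomial upper bound (no optimistic bias)
  pl <- planted_dataset(n1 = 47, n0 = 13, p = 60, k = 10, delta = 2, seed = 71)
  p0 <- 47 / 60
  upper <- p0 + 2.576 * sqrt(p0 * (1 - p0) / 60)
  for (perm in 1:3) {
    labp <- withr::with_seed(700 + perm, sample(pl$ds$labels))
    names(labp) <- names(pl$ds$labels)
    dsp <- omics_dataset(pl$ds$values, labp)
    tr <- run_refs(dsp, k_folds = 5, seed = 800 + perm, specs = fast_specs())
    accs <- vapply(tr$iterations, `[[`, 0, "global_accuracy")
    expect_true(all(accs <= upper))
    sig <- select_optimal(tr)
    overlap <- length(intersect(sig$feature_ids, pl$truth$informative_probes))
    s <- length(sig$feature_ids)
    band <- stats::qhyper(c(0.005, 0.995), 10, 50, s)
    expect_gte(overlap, band[1])
    expect_lte(overlap, band[2])
  }
})
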