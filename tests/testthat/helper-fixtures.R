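# Shared fixtures, built in code at test time.

# a small labelled dataset with hand-set values
tiny_dataset <- function(values = NULL, labels = c(0, 0, 1, 1),
                         feature_kind = "probe") {
  if (is.null(values)) {
    set.seed(42)
    values <- matrix(rnorm(4 * length(labels)), 4, length(labels))
  }
  rownames(values) <- sprintf("f%02d", seq_len(nrow(values)))
  colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  omics_dataset(values, stats::setNames(labels, colnames(values)),
                feature_kind = feature_kind)
}

# planted-signal dataset: first k features shifted down in cases
planted_dataset <- function(n1 = 60, n0 = 40, p = 20, k = 4, delta = 3,
                            seed = 1, scale = TRUE) {
  cfg <- synthetic_config(n_cases = n1, n_controls = n0, n_features = p,
                          k_informative = k, effect_size = delta,
                          unannotated_frac = 0, seed = seed)
  sim <- generate_expression(cfg)
  ds <- sim$dataset
  if (scale) ds <- standard_scale(ds, "per_feature")
  list(ds = ds, truth = sim$truth, annotation = sim$annotation, config = cfg)
}

# a reduced ensemble for plumbing tests where fit speed matters more than
# ensemble fidelity
fast_specs <- function(include = NULL) {
  classifier_specs(n_estimators = 60, include = include)
}

expect_identical_reports <- function(a, b) {
  a$oof_scores <- NULL; b$oof_scores <- NULL
  expect_equal(a, b, tolerance = 0)
}

# Run an expression in a child R process against the installed package and
# return its value. The ensemble backends are compiled libraries; isolating
# the heaviest simulations keeps a rare native-code fault in one of them
# from taking the whole suite down. Results are seed-deterministic, so a
# retry after a crashed attempt recomputes the identical quantity.
run_isolated <- function(expr_text, attempts = 2) {
  out_rds <- tempfile(fileext = ".rds")
  script <- tempfile(fileext = ".R")
  writeLines(c(
    sprintf(".libPaths(c(%s))",
            paste(sprintf('"%s"', .libPaths()), collapse = ", ")),
    "suppressMessages(library(refsig))",
    sprintf("out <- local({\n%s\n})", expr_text),
    sprintf('saveRDS(out, "%s")', out_rds)
  ), script)
  for (a in seq_len(attempts)) {
    status <- suppressWarnings(system2(
      file.path(R.home("bin"), "Rscript"), c("--vanilla", script),
      stdout = FALSE, stderr = FALSE
    ))
    if (status == 0 && file.exists(out_rds)) return(readRDS(out_rds))
  }
  stop(sprintf("isolated computation failed after %d attempt(s) (status %s)",
               attempts, status))
}
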