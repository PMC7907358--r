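# The generator's planted-signal guarantees: directions, reproducibility,
# null calibration, and the second-platform overlap arithmetic.

test_that("config validation rejects impossible designs", {
  expect_error(synthetic_config(k_informative = 10, n_features = 5),
               class = "refsig_config_error")
  expect_error(synthetic_config(n_cases = -1), class = "refsig_config_error")
  expect_error(synthetic_config(effect_size = -0.5), class = "refsig_config_error")
  expect_error(synthetic_config(platform2_overlap = 1.2), class = "refsig_config_error")
})

test_that("identical configs generate bit-identical datasets", {
  cfg <- synthetic_config(n_features = 50, k_informative = 5, seed = 7)
  a <- generate_expression(cfg)
  b <- generate_expression(cfg)
  expect_identical(a$dataset$values, b$dataset$values)
  expect_identical(a$truth, b$truth)
  expect_identical(a$annotation, b$annotation)
  ann <- make_cpg_annotation(a$truth, cfg)
  expect_identical(ann, make_cpg_annotation(b$truth, cfg))
  expect_identical(generate_methylation(cfg, a$truth, ann)$dataset$values,
                   generate_methylation(cfg, b$truth, ann)$dataset$values)
})

test_that("planted expression features are down-regulated in cases", {
  cfg <- synthetic_config(n_cases = 93, n_controls = 25, n_features = 2000,
                          k_informative = 23, effect_size = 2, seed = 1)
  sim <- generate_expression(cfg)
  ds <- sim$dataset
  expect_length(sim$truth$informative_probes, 23)
  expect_length(unique(sim$truth$informative_genes), 23)
  for (f in sim$truth$informative_probes) {
    d <- mean(ds$values[f, ds$labels == 1]) - mean(ds$values[f, ds$labels == 0])
    expect_lt(d, 0)
  }
  expect_true(all(sim$truth$direction_by_feature == "down_in_cases"))
})

test_that("null generator (k_informative = 0) is calibrated", {
  # pooled over features, the t-test false-positive rate must sit inside the
  # binomial 99% band around 0.05
  cfg <- synthetic_config(n_cases = 40, n_controls = 40, n_features = 800,
                          k_informative = 0, seed = 3)
  sim <- generate_expression(cfg)
  ds <- sim$dataset
  expect_length(sim$truth$informative_probes, 0)
  p <- apply(ds$values, 1, function(x) {
    stats::t.test(x[ds$labels == 1], x[ds$labels == 0])$p.value
  })
  hits <- sum(p < 0.05)
  band <- stats::qbinom(c(0.005, 0.995), 800, 0.05)
  expect_gte(hits, band[1])
  expect_lte(hits, band[2])
})

test_that("planted standardized mean difference is unbiased for -effect_size", {
  # Monte-Carlo over replicate datasets, compared at 3 standard errors
  reps <- 50
  d <- replicate(reps, {
    cfg <- synthetic_config(n_cases = 50, n_controls = 50, n_features = 12,
                            k_informative = 4, effect_size = 2, noise_sd = 1,
                            seed = sample.int(1e6, 1))
    sim <- generate_expression(cfg)
    v <- sim$dataset$values[sim$truth$informative_probes, , drop = FALSE]
    y <- sim$dataset$labels
    mean(apply(v, 1, function(x) {
      (mean(x[y == 1]) - mean(x[y == 0])) /
        sqrt((stats::var(x[y == 1]) + stats::var(x[y == 0])) / 2)
    }))
  })
  se <- stats::sd(d) / sqrt(reps)
  expect_lt(abs(mean(d) - (-2)), 3 * se)
})

test_that("methylation values are percentages with inverse-direction planting", {
  cfg <- synthetic_config(n_features = 60, k_informative = 5,
                          cpgs_per_gene = 4, methylation_effect = 2,
                          meth_n_cases = 40, meth_n_controls = 30,
                          n_decoy_genes = 10, seed = 2)
  sim <- generate_expression(cfg)
  ann <- make_cpg_annotation(sim$truth, cfg)
  meth <- generate_methylation(cfg, sim$truth, ann)
  v <- meth$dataset$values
  expect_true(all(v >= 0 & v <= 100))
  expect_gte(length(meth$truth$informative_cpgs), 5 * 4)
  y <- meth$dataset$labels
  for (cg in meth$truth$informative_cpgs) {
    expect_gt(mean(v[cg, y == 1]) - mean(v[cg, y == 0]), 0)
  }
  # opposite sign to the expression shift of the linked genes
  expect_true(all(meth$truth$direction_by_feature[meth$truth$informative_cpgs] ==
                    "up_in_cases"))
})

test_that("methylation null (methylation_effect = 0) shows no planted shift", {
  cfg <- synthetic_config(n_features = 40, k_informative = 4, cpgs_per_gene = 3,
                          methylation_effect = 0, meth_n_cases = 50,
                          meth_n_controls = 50, n_decoy_genes = 5, seed = 9)
  sim <- generate_expression(cfg)
  ann <- make_cpg_annotation(sim$truth, cfg)
  meth <- generate_methylation(cfg, sim$truth, ann)
  v <- meth$dataset$values
  y <- meth$dataset$labels
  p <- apply(v, 1, function(x) stats::t.test(x[y == 1], x[y == 0])$p.value)
  # no CpG should be extreme beyond multiplicity-corrected chance
  expect_gt(min(p) * length(p), 0.001)
})

test_that("gene missing from the CpG map is a mapping error", {
  cfg <- synthetic_config(n_features = 30, k_informative = 3, cpgs_per_gene = 2,
                          n_decoy_genes = 2, seed = 4)
  sim <- generate_expression(cfg)
  ann <- make_cpg_annotation(sim$truth, cfg)
  ann2 <- ann[!vapply(ann$parsed_genes,
                      function(g) sim$truth$informative_genes[1] %in% g,
                      logical(1)), ]
  class(ann2) <- class(ann)
  expect_error(generate_methylation(cfg, sim$truth, ann2),
               class = "refsig_mapping_error")
})

test_that("second platform covers round(overlap * k) planted genes", {
  cfg <- synthetic_config(n_features = 200, k_informative = 23,
                          platform2_overlap = 18 / 23, seed = 5)
  sim <- generate_expression(cfg)
  p2 <- generate_second_platform(sim$truth, cfg)
  expect_length(p2$mapped_genes, 18)
  expect_true(all(p2$mapped_genes %in% sim$truth$informative_genes))

  cfg1 <- synthetic_config(n_features = 100, k_informative = 20,
                           platform2_overlap = 1, seed = 5)
  sim1 <- generate_expression(cfg1)
  expect_setequal(generate_second_platform(sim1$truth, cfg1)$mapped_genes,
                  sim1$truth$informative_genes)

  cfg2 <- synthetic_config(n_features = 100, k_informative = 20,
                           platform2_overlap = 0.5, seed = 5)
  sim2 <- generate_expression(cfg2)
  expect_length(generate_second_platform(sim2$truth, cfg2)$mapped_genes, 10)

  # zero overlap leaves nothing to transfer
  cfg0 <- synthetic_config(n_features = 100, k_informative = 10,
                           platform2_overlap = 0, seed = 5)
  sim0 <- generate_expression(cfg0)
  p0 <- generate_second_platform(sim0$truth, cfg0)
  expect_length(p0$mapped_genes, 0)
  expect_error(map_signature(sim0$truth$informative_genes, p0$annotation),
               class = "refsig_transfer_error")
})

test_that("second platform preserves the planted down-in-cases direction", {
  cfg <- synthetic_config(n_features = 100, k_informative = 10,
                          effect_size = 2, platform2_overlap = 0.8,
                          p2_n_cases = 30, p2_n_controls = 30, seed = 6)
  sim <- generate_expression(cfg)
  p2 <- generate_second_platform(sim$truth, cfg)
  tmap <- map_signature(p2$mapped_genes, p2$annotation)
  y <- p2$dataset$labels
  for (probes in tmap$mapped) {
    for (pr in probes) {
      d <- mean(p2$dataset$values[pr, y == 1]) - mean(p2$dataset$values[pr, y == 0])
      expect_lt(d, 0)
    }
  }
})
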