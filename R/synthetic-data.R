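#' Configuration for the synthetic case/control data generator
#'
#' The generator emulates the study design the pipeline targets: an imbalanced
#' two-class expression cohort (default 93 cases / 25 controls), a small set of
#' planted genes down-regulated in cases, gene-linked CpGs whose methylation is
#' shifted up in cases (inverse correlation with expression), and a second,
#' smaller expression platform (default 8 cases / 7 controls) that shares only
#' part of the planted gene set.
#'
#' @param n_cases,n_controls Expression cohort sizes (defaults 93 / 25).
#' @param n_features Number of expression probes (default 2000).
#' @param k_informative Number of planted (differential) genes (default 23).
#' @param effect_size Standardized mean shift of planted genes, in units of the
#'   per-feature noise SD; cases are shifted \emph{down} (default 2).
#' @param noise_sd Per-feature Gaussian noise SD (default 1).
#' @param cpgs_per_gene CpGs annotated to each informative (and decoy) gene
#'   (default 12).
#' @param methylation_effect Case shift of planted CpGs on the latent logit
#'   scale (default 2); planted CpGs are shifted \emph{up} in cases.
#' @param platform2_overlap Fraction of planted genes annotated on the second
#'   platform (default 18/23).
#' @param meth_n_cases,meth_n_controls Methylation cohort sizes (defaults
#'   99 / 50).
#' @param p2_n_cases,p2_n_controls Second-platform cohort sizes (defaults 8 / 7).
#' @param n_features_p2 Probe count on the second platform (default 300).
#' @param n_decoy_genes Non-planted genes that still receive CpG annotation
#'   rows (default 50).
#' @param unannotated_frac Fraction of expression probes with no gene symbol,
#'   exercising the re-annotation filter (default 0.10).
#' @param multi_gene_frac Fraction of CpG annotation rows carrying a
#'   semicolon-joined multi-gene field (default 0.05).
#' @param seed Integer seed; identical configurations generate bit-identical
#'   datasets.
#'
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cases = 93, n_controls = 25, n_features = 2000,
                             k_informative = 23, effect_size = 2, noise_sd = 1,
                             cpgs_per_gene = 12, methylation_effect = 2,
                             platform2_overlap = 18 / 23,
                             meth_n_cases = 99, meth_n_controls = 50,
                             p2_n_cases = 8, p2_n_controls = 7,
                             n_features_p2 = 300, n_decoy_genes = 50,
                             unannotated_frac = 0.10, multi_gene_frac = 0.05,
                             seed = 1L) {
  cfg <- list(n_cases = n_cases, n_controls = n_controls,
              n_features = n_features, k_informative = k_informative,
              effect_size = effect_size, noise_sd = noise_sd,
              cpgs_per_gene = cpgs_per_gene,
              methylation_effect = methylation_effect,
              platform2_overlap = platform2_overlap,
              meth_n_cases = meth_n_cases, meth_n_controls = meth_n_controls,
              p2_n_cases = p2_n_cases, p2_n_controls = p2_n_controls,
              n_features_p2 = n_features_p2, n_decoy_genes = n_decoy_genes,
              unannotated_frac = unannotated_frac,
              multi_gene_frac = multi_gene_frac, seed = as.integer(seed))
  counts <- c("n_cases", "n_controls", "n_features", "k_informative",
              "cpgs_per_gene", "meth_n_cases", "meth_n_controls",
              "p2_n_cases", "p2_n_controls", "n_features_p2", "n_decoy_genes")
  for (nm in counts) {
    if (!is_count(cfg[[nm]])) {
      stop_refsig("refsig_config_error", paste0("`", nm, "` must be a non-negative integer"))
    }
  }
  if (cfg$k_informative > cfg$n_features) {
    stop_refsig("refsig_config_error", "k_informative must not exceed n_features")
  }
  if (cfg$effect_size < 0) {
    stop_refsig("refsig_config_error", "effect_size must be >= 0")
  }
  if (cfg$noise_sd <= 0) {
    stop_refsig("refsig_config_error", "noise_sd must be > 0")
  }
  if (cfg$platform2_overlap < 0 || cfg$platform2_overlap > 1) {
    stop_refsig("refsig_config_error", "platform2_overlap must lie in [0, 1]")
  }
  if (cfg$unannotated_frac < 0 || cfg$unannotated_frac >= 1) {
    stop_refsig("refsig_config_error", "unannotated_frac must lie in [0, 1)")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic case/control expression dataset with planted signal
#'
#' Non-informative probes are drawn from one class-independent Gaussian per
#' probe (`N(mu_j, noise_sd)`). Each of the `k_informative` planted probes is
#' shifted down by `effect_size * noise_sd` in cases. A probe-to-gene
#' annotation table is generated alongside, with `unannotated_frac` of the
#' probes left without a gene symbol and a small fraction of genes covered by
#' two probes, so the re-annotation filter has work to do. Planted probes are
#' always annotated, each to a distinct gene.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements
#'   \describe{
#'     \item{dataset}{`omics_dataset` (probes x samples, labels 1 = case).}
#'     \item{truth}{`synthetic_truth`: `informative_probes`,
#'       `informative_genes`, `direction_by_feature` (all `"down_in_cases"`).}
#'     \item{annotation}{Probe annotation `data.frame` with columns `probe_id`
#'       and `gene_symbols` (semicolon-joined; empty for unannotated probes).}
#'   }
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_cases + config$n_controls
  p <- config$n_features
  if (p < 1 || n < 2) {
    stop_refsig("refsig_config_error", "need at least one feature and two samples")
  }
  with_seed(config$seed, {
    probes <- sprintf("probe_%05d", seq_len(p))
    samples <- sprintf("sample_%03d", seq_len(n))
    labels <- stats::setNames(c(rep(1L, config$n_cases), rep(0L, config$n_controls)),
                              samples)

    # annotation: drop a fraction, give ~10% of annotated genes a second probe
    n_ann <- max(config$k_informative, round((1 - config$unannotated_frac) * p))
    annotated <- sort(sample.int(p, n_ann))
    n_genes <- max(1L, ceiling(n_ann / 1.1))
    gene_pool <- sprintf("G%05d", seq_len(n_genes))
    gene_of <- rep(NA_character_, p)
    gene_of[annotated] <- c(gene_pool, sample(gene_pool, n_ann - n_genes, replace = FALSE))

    # planted probes: annotated, each with a distinct gene
    ann_idx <- annotated[!duplicated(gene_of[annotated])]
    informative <- sort(sample(ann_idx, config$k_informative))

    mu <- stats::rnorm(p, mean = 7, sd = 1.5)
    values <- mu + config$noise_sd * matrix(stats::rnorm(p * n), p, n)
    if (config$k_informative > 0) {
      shift <- config$effect_size * config$noise_sd
      values[informative, labels == 1L] <-
        values[informative, labels == 1L, drop = FALSE] - shift
    }
    dimnames(values) <- list(probes, samples)

    truth <- structure(
      list(informative_probes = probes[informative],
           informative_genes = gene_of[informative],
           informative_cpgs = character(0),
           direction_by_feature = stats::setNames(
             rep("down_in_cases", length(informative)), probes[informative])),
      class = "synthetic_truth"
    )
    annotation <- data.frame(
      probe_id = probes,
      gene_symbols = ifelse(is.na(gene_of), "", gene_of),
      stringsAsFactors = FALSE
    )
    list(dataset = omics_dataset(values, labels, "probe"),
         truth = truth, annotation = annotation)
  })
}

#' Generate a CpG annotation table for the planted and decoy genes
#'
#' Each informative gene (from `truth`) and each of `n_decoy_genes` decoy genes
#' receives `cpgs_per_gene` CpG probes; `multi_gene_frac` of the rows carry a
#' semicolon-joined multi-gene field (with a deliberately duplicated token,
#' mimicking the 450k `UCSC_RefGene_Name` dialect).
#'
#' @param truth A `synthetic_truth` from [generate_expression()].
#' @param config The [synthetic_config()] used to generate it.
#' @return A `cpg_annotation` data.frame with columns `cpg_id`,
#'   `refgene_names` (raw string) and `parsed_genes` (list column).
#' @export
make_cpg_annotation <- function(truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(derive_seed(config$seed, 11L), {
    decoys <- sprintf("DECOY%04d", seq_len(config$n_decoy_genes))
    genes <- c(truth$informative_genes, decoys)
    rows <- data.frame(
      gene = rep(genes, each = config$cpgs_per_gene),
      stringsAsFactors = FALSE
    )
    n_cpg <- nrow(rows)
    rows$cpg_id <- sprintf("cg%08d", sample.int(99999999L, n_cpg))
    refgene <- rows$gene
    n_multi <- round(config$multi_gene_frac * n_cpg)
    if (n_multi > 0 && length(genes) > 1) {
      idx <- sample.int(n_cpg, n_multi)
      extra <- vapply(rows$gene[idx], function(g) sample(setdiff(genes, g), 1L), "")
      # duplicated first token mirrors real UCSC_RefGene_Name fields
      refgene[idx] <- paste(rows$gene[idx], rows$gene[idx], extra, sep = ";")
    }
    ann <- data.frame(cpg_id = rows$cpg_id, refgene_names = refgene,
                      stringsAsFactors = FALSE)
    ann$parsed_genes <- parse_refgene_field(ann$refgene_names)
    class(ann) <- c("cpg_annotation", "data.frame")
    ann
  })
}

#' Generate a synthetic case/control methylation dataset
#'
#' Values are percentage methylation in \[0, 100\], produced as
#' `100 * plogis(z)` from Gaussian latent values `z`. CpGs annotated to an
#' informative gene get a latent case shift of `+methylation_effect`, so their
#' methylation is raised in cases -- the inverse of the planted expression
#' direction.
#'
#' @param config A [synthetic_config()]; `meth_n_cases` / `meth_n_controls`
#'   set the cohort size.
#' @param truth A `synthetic_truth` from [generate_expression()].
#' @param gene_map A `cpg_annotation` covering every informative gene (as from
#'   [make_cpg_annotation()]).
#' @return A list with `dataset` (`omics_dataset`, feature_kind `"cpg"`) and
#'   `truth` (input truth with `informative_cpgs` and their directions filled
#'   in as `"up_in_cases"`).
#' @export
generate_methylation <- function(config, truth, gene_map) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!all(c("cpg_id", "parsed_genes") %in% names(gene_map))) {
    stop_refsig("refsig_format_error", "gene_map must be a cpg_annotation table")
  }
  covered <- unique(toupper(unlist(gene_map$parsed_genes)))
  missing <- setdiff(toupper(truth$informative_genes), covered)
  if (length(missing) > 0) {
    stop_refsig("refsig_mapping_error",
                paste0("informative gene(s) absent from gene_map: ",
                       paste(utils::head(missing, 5), collapse = ", ")))
  }
  n <- config$meth_n_cases + config$meth_n_controls
  p <- nrow(gene_map)
  with_seed(derive_seed(config$seed, 12L), {
    samples <- sprintf("msample_%03d", seq_len(n))
    labels <- stats::setNames(
      c(rep(1L, config$meth_n_cases), rep(0L, config$meth_n_controls)), samples)
    informative_cpg <- vapply(
      gene_map$parsed_genes,
      function(g) any(toupper(g) %in% toupper(truth$informative_genes)),
      logical(1)
    )
    b <- stats::rnorm(p, mean = 0, sd = 1.5)
    z <- b + matrix(stats::rnorm(p * n), p, n)
    if (any(informative_cpg)) {
      z[informative_cpg, labels == 1L] <-
        z[informative_cpg, labels == 1L, drop = FALSE] + config$methylation_effect
    }
    values <- 100 * stats::plogis(z)
    dimnames(values) <- list(gene_map$cpg_id, samples)
    truth$informative_cpgs <- gene_map$cpg_id[informative_cpg]
    truth$direction_by_feature <- c(
      truth$direction_by_feature,
      stats::setNames(rep("up_in_cases", sum(informative_cpg)),
                      gene_map$cpg_id[informative_cpg])
    )
    list(dataset = omics_dataset(values, labels, "cpg"), truth = truth)
  })
}

#' Generate a second expression platform sharing part of the planted genes
#'
#' Emulates cross-platform validation data: a small cohort (default 8 cases /
#' 7 controls) measured on a platform whose annotation covers only
#' `round(platform2_overlap * k_informative)` of the planted genes (under new
#' probe IDs), plus background genes. Planted effect directions are preserved
#' (down in cases, same `effect_size`). The first mapped gene receives two
#' probes, exercising the multi-probe transfer path.
#'
#' @param truth A `synthetic_truth` from [generate_expression()].
#' @param config The matching [synthetic_config()].
#' @return A list with `dataset` (`omics_dataset`), `annotation` (probe
#'   annotation data.frame) and `mapped_genes` (planted genes present on the
#'   platform).
#' @export
generate_second_platform <- function(truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  k <- length(truth$informative_genes)
  n_mapped <- round(config$platform2_overlap * k)
  n <- config$p2_n_cases + config$p2_n_controls
  with_seed(derive_seed(config$seed, 13L), {
    mapped_genes <- if (n_mapped > 0) {
      sort(sample(truth$informative_genes, n_mapped))
    } else character(0)
    # one probe per mapped gene, the first mapped gene gets a second probe
    gene_per_probe <- c(mapped_genes, if (n_mapped > 0) mapped_genes[1])
    n_signal <- length(gene_per_probe)
    p <- max(config$n_features_p2, n_signal)
    n_bg <- p - n_signal
    gene_per_probe <- c(gene_per_probe, sprintf("P2BG%04d", seq_len(n_bg)))
    probes <- sprintf("p2probe_%05d", seq_len(p))
    samples <- sprintf("vsample_%02d", seq_len(n))
    labels <- stats::setNames(
      c(rep(1L, config$p2_n_cases), rep(0L, config$p2_n_controls)), samples)
    mu <- stats::rnorm(p, mean = 7, sd = 1.5)
    values <- mu + config$noise_sd * matrix(stats::rnorm(p * n), p, n)
    if (n_signal > 0) {
      shift <- config$effect_size * config$noise_sd
      values[seq_len(n_signal), labels == 1L] <-
        values[seq_len(n_signal), labels == 1L, drop = FALSE] - shift
    }
    dimnames(values) <- list(probes, samples)
    annotation <- data.frame(probe_id = probes, gene_symbols = gene_per_probe,
                             stringsAsFactors = FALSE)
    list(dataset = omics_dataset(values, labels, "probe"),
         annotation = annotation, mapped_genes = mapped_genes)
  })
}
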