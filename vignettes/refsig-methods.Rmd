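---
title: "Recursive ensemble feature selection for case/control omics signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recursive ensemble feature selection for case/control omics signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refsig)
```

## The problem

Case/control omics studies — peripheral-blood expression arrays, 450k/EPIC
methylation arrays — routinely measure tens of thousands of features on at
most a few hundred samples. The goal `refsig` addresses is to find a *small*
feature signature (tens of genes or CpGs) that discriminates cases from
controls robustly, rather than the study-specific lists that single-statistic
univariate filters tend to produce.

The core procedure is **recursive ensemble feature selection (REFS)**: a
panel of eight classifiers of deliberately different topologies is fitted
under stratified k-fold cross-validation; each (classifier, fold) fit emits a
per-feature importance vector; the vectors are aggregated by a Borda count;
and the worst-scoring 20% of features is eliminated. The cycle repeats while
the ensemble's *global accuracy* — the unweighted mean of the per-classifier
cross-validated accuracies — stays above a stop threshold (70% by default).
Repeating the whole procedure (ten runs by default, differing in their fold
assignment) and taking a frequency consensus at the accuracy-optimal feature
count yields the final signature.

## The model and its parts

### Ensemble and importance semantics

The eight classifiers are bagged trees, gradient boosting, random forest
(tree family, 300 estimators each by default), and logistic regression,
passive-aggressive, SGD (hinge), linear SVC, and ridge (coefficient family).
Feature importance is split-usage based for the tree family (impurity
decrease by default; split counts are available via
`classifier_specs(tree_importance = "split_count")`) and absolute
coefficient magnitude for the linear family. Both conventions make
importances non-negative, and only their *ranks* enter the aggregation, so
per-classifier scale differences are irrelevant.

Backends: gradient boosting is `xgboost` (depth 3, learning rate 0.1),
random forest and bagged trees are `ranger` (bagging = `mtry` spanning all
features), logistic regression is ridge-penalised `glmnet`
(lambda = 1/n, the C = 1 convention), and the linear SVC is `e1071`. The
passive-aggressive (PA-I) and SGD-hinge learners are implemented directly as
seeded online-update loops; both return the *iterate average* rather than
the last iterate. Averaging is the standard stabilisation for online
learners — without it the returned hyperplane is a single noisy snapshot of
the update walk, and on weak or null signal its held-out accuracy swings by
tens of percentage points between seeds.

### Borda aggregation

Each importance vector over the current m features is converted to ranks
(largest importance = rank 1) and to points `m - rank`; tied importances
share the mean of their points, which keeps aggregation deterministic. A
feature's score for the iteration is its summed points over all
(classifier × fold) vectors. Any strictly rank-monotone points scheme
preserves the top-k set; this one is the simplest.

### Reduction schedule and stop rule

From m features the next iteration keeps `ceiling(0.8 * m)`, with a drop-1
guard when rounding would stall (that guard only binds for m ≤ 4, so the
schedule always reaches 1):

```{r}
reduction_schedule(100)
```

The loop continues while global accuracy is strictly above
`stop_accuracy = 0.7`; the terminating iteration is recorded. An optional
`initial_keep` permits an aggressive first cut; it is off by default because
the plain 20% schedule is fully specified, whereas "reduce to the most
significant features first" is not quantifiable.

### Consensus over repeated runs

Runs differ by the fold-assignment seed (`seed`, `seed + 1`, ...);
classifier seeds derive from the run seed. Per retained count m, global
accuracies are averaged across runs (only m values visited by *all* runs are
eligible); the optimal size is the argmax, ties resolved to the smaller m.
The signature is the optimal-m features most frequently retained at that
size across runs, frequency ties broken by mean Borda score and then
feature ID — fully deterministic.

### Evaluation

A fixed signature is evaluated with the same ensemble under stratified CV:
per-classifier fold-accuracy mean and population SD, the global accuracy,
and an ROC curve with trapezoidal AUC from pooled out-of-fold scores. The
scorer defaults to the logistic-regression probability (configurable to the
mean of all classifier scores) because no single published convention
exists for multi-classifier ROC pooling. Group separation of a signature is
quantified by a two-group MANOVA: Wilks' lambda from the within/between
SSCP determinants, the exact two-group transformation
`F = (df_e/df_h) (1 - lambda)/lambda` with `df_h = p`, `df_e = n - p - 1`,
and the uncentered R-squared `1 - lambda`. Published MANOVA triples can be
checked as printed via `wilks_to_f()` independently of the df convention a
report used; note that a printed F(23, 95) alongside n = 118 is internally
inconsistent with the standard two-group formula (which gives df_e = 94) —
`refsig` implements the standard formula and leaves any printed triple
checkable as stated.

```{r}
wilks_to_f(0.445, df_h = 23, df_e = 95)
```

### Candidate-gene CpG restriction and cross-platform transfer

For methylation arrays the search space is first restricted to CpGs whose
`UCSC_RefGene_Name`-style annotation intersects the candidate genes from the
expression signature (exact, case-insensitive token match on the
semicolon-split field; multi-gene CpGs kept once). Cross-platform validation
maps the signature genes onto a second platform's probe annotation (genes
without probes are reported as missing, multi-probe genes keep all probes by
default) and re-evaluates under small-sample CV without any re-selection.

## Preprocessing conventions

* **Scaling** uses population-SD z-scores: per feature for expression (the
  conventional axis for feature standardisation; the source procedure is
  ambiguous, so the axis is a parameter), per sample for percentage
  methylation (explicit in the emulated design). Constant vectors scale to
  zeros with a warning. Scaling is fitted on the full dataset before CV,
  reproducing the emulated study's order of operations; note this leaks
  fold information slightly, and fold-internal scaling can be performed by
  scaling training/test partitions externally if a leakage-free estimate is
  needed.
* **Labels**: fatigue-severity categories encode low = 0 (control),
  moderate/high = 1 (case).
* **Merging** multiple (already scaled) datasets intersects features and
  concatenates samples, recording per-sample provenance; union-with-missing
  is not offered because the classifiers reject missing values, and no
  imputation is performed anywhere.
* **Stratified folds** deal shuffled class members round-robin, so per-fold
  class counts are within one of proportionality; with 93 cases / 25
  controls and k = 10 every fold holds 9–10 cases and 2–3 controls. The
  chi-squared baseline min-shifts each (standardised, hence negative-valued)
  feature to zero before scoring, since the statistic is defined for
  non-negative totals.

## The synthetic-data generator

Because the emulated study's matrices live behind external repositories, the
package ships a generator that reproduces the *design*, not the data: an
imbalanced expression cohort (93 cases / 25 controls by default) with
`k_informative` planted genes shifted down in cases by `effect_size` (in
units of the per-feature noise SD, default 2); a probe-to-gene annotation
with a fraction (default 10%) of unannotated probes and occasional
multi-probe genes; a methylation cohort (99/50 by default) whose values are
inverse-logit-transformed Gaussians scaled to [0, 100], with CpGs of planted
genes shifted *up* in cases on the latent scale — the inverse of the
expression direction; and a second, small expression platform (8/7) covering
only `platform2_overlap` of the planted genes (default 18/23). Identical
configurations generate bit-identical data.

What the generator does *not* emulate: batch effects, covariates,
probe-intensity artefacts, correlated co-expression/co-methylation
structure, or realistic effect-size spectra. Passing tests on this generator
therefore demonstrate algorithmic correctness and calibration of the
machinery, not performance on real cohorts.

### A note on effect-size saturation

With the default planted shift of two noise-SDs, a handful of planted
features already classifies near-perfectly, so the accuracy-versus-m curve
is *flat* from a few features up to a few dozen: differences across that
plateau are smaller than fold-resampling noise (on the order of 10^-3).
The argmax-of-mean-accuracy size rule then lands essentially at random on
the plateau, and with the smallest-m tie preference it tends to undershoot
the planted k. This is a property of the selection *rule* under saturation,
not of the feature ranking — planted features survive every cut down to
m = k essentially always, and the consensus signature is composed of
planted features whatever its size. Larger starting feature counts
(hundreds) restore a visible accuracy contrast between the noisy early
iterations and the all-planted region and make the selected size track k
more closely; weaker effects (delta near 1) produce the peaked curve the
rule was designed for. This phenomenon is documented here because it sets
realistic expectations for the planted-recovery checks in the test suite.

The null calibration of the ensemble deserves the same honesty: on
label-permuted (null) high-dimensional data the tree ensembles and the
intercept-dominated linear models predict close to the majority-class rate,
but the weakly regularised linear models (logistic at C = 1, ridge, SVC,
and especially the online learners) partially interpolate noise and score
*below* the majority rate on held-out folds. The ensemble's null global
accuracy therefore sits systematically below a majority-rate binomial band.
The same direction of bias appears in pooled out-of-fold ROC scores: under
the null, what a classifier learned from training-fold noise reverses on
the held-out fold, so the null AUC is centred slightly *below* 0.5 (about
0.47 in the shipped permutation checks), the classic pessimistic bias of
cross-validated nulls. What does hold — and what matters for selection
validity — is the absence of *optimistic* bias: null accuracy never exceeds
the band's upper edge, and the permutation distribution of the AUC
straddles 0.5.

## Numerical choices and degenerate inputs

* Ranks use mean-ties throughout; all tie-breaks end in lexicographic
  feature ID, so every result is reproducible bit-for-bit under a fixed
  seed (`ranger` and `xgboost` are run single-threaded with explicit
  seeds).
* Wilks' lambda is computed from log-determinants; a non-positive-definite
  SSCP raises a linear-algebra error naming the rank rather than returning
  a spurious statistic. `p >= n - 1` is a dimension error.
* ROC threshold sweeps group tied scores into single steps; AUC is exactly
  the Mann-Whitney pair fraction, which the tests verify against a
  brute-force oracle.
* Single-feature datasets: the logistic backend falls back from `glmnet`
  (which requires two columns) to an unpenalised GLM; a single candidate
  CpG short-circuits REFS to a size-one signature.
* Classifier failures on a fold are caught, warned about, and excluded from
  that (classifier, fold) cell; the iteration errors only if every cell
  failed.

## Problem sizes used in the shipped tests

The test-suite simulations are sized for a single-CPU laptop run: planted
recovery uses cohorts of 118 samples (93/25) with a few hundred starting
features and ten REFS runs; the permutation-null and determinism checks use
60–100 features; the MANOVA calibration uses 500 null replicates at p = 3,
n = 60. These sizes were chosen so the full suite exercises every stage of
the pipeline, including the ten-run consensus, at the smallest scale where
the studied effects are visible.

## Known limitations

* The "ten runs" consensus varies only fold assignment between runs; other
  reasonable definitions (bootstrap resampling, classifier-seed variation)
  exist and would change selection frequencies.
* The optimal-size rule is degenerate under accuracy saturation (above).
* No hyperparameter tuning is performed for the eight classifiers; the
  defaults mirror common fixed settings (300 estimators for the tree
  family).
* Probe-to-gene re-annotation is a static table lookup; no attempt is made
  to reproduce web-service-based annotation, and CpG-to-gene assignment
  matches annotation fields only (no genomic-coordinate logic).
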