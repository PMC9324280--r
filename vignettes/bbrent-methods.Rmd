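---
title: "Stable radiomic feature selection with bagged-boosted repeated elastic nets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stable radiomic feature selection with bagged-boosted repeated elastic nets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bbrent)
```

## The problem

Radiomic analyses summarise a delineated image region by a few hundred
quantitative descriptors (shape, first-order intensity, texture) and fit a
classifier on top — here, discriminating a malignant from a benign class of
nasopharyngeal lesion on MRI.  The Achilles heel of such pipelines is the
feature-selection step: with ~400 correlated features and a few hundred
patients, small perturbations of the training data can change the selected
feature set substantially, undermining the credibility of any downstream
"signature".  This package implements a pipeline built around that concern:

1. **Preliminary filtering** (`run_prefilter()`): features must (i) not be
   constant, (ii) be robust to re-delineation — intraclass correlation
   (ICC) between two delineations of the same lesions at least 0.9 with
   F-test p ≤ 0.05 — and (iii) show a univariate association with the
   label (Student t or Mann–Whitney U depending on a per-class
   Shapiro–Wilk normality gate, p ≤ 0.05).  Exclusion rules are applied as
   printed conventions: boundary values are kept.
2. **BB-RENT selection** (`bb_rent()`): the repeated elastic net (RENT)
   retains a feature when, across `K` subsampled elastic-net fits, its
   coefficient is (i) non-zero in at least τ₁ = 90% of runs, (ii)
   sign-stable in at least τ₂ = 90% of its non-zero runs, and (iii)
   significantly non-zero by a one-sample t-test at τ₃ = 0.05.  BB-RENT
   replaces each single elastic net with a discrete-AdaBoost chain of at
   most `N` elastic-net logistic learners, wraps the whole procedure in
   `Q` bootstrap bags, and finally keeps features nominated in strictly
   more than η·Q bags.  Full-scale defaults follow the source method:
   `N = 25`, `K = 200`, `Q = 150`, `η = 50%`.
3. **Stability quantification** (`stability_experiment()`): M resampling
   runs (80% of patients, without replacement) per selector; mean pairwise
   Jaccard index and the Nogueira stability estimator
   Φ = 1 − (d⁻¹Σ_f s_f²)/((k̄/d)(1−k̄/d)), with an asymptotic z-test for
   differences in Φ.
4. **Modelling** (`cross_validate()`, `build_ensemble()`): per stratified
   fold, the filter and selector run on the training split only, features
   are Z-scored with training parameters, a classifier (linear SVR on 0/1
   targets, logistic regression, random forest, perceptron, or kNN) is
   trained, and the held-out fold supplies the AUC and the Youden-index
   operating point.  The five fold-level linear models are aggregated
   with weights wᵢ = 1/(5·thresholdᵢ), which normalises the ensemble
   decision threshold to exactly 1.

## Numerical and design choices

**Elastic-net solver.**  The selector needs on the order of 10⁵–10⁶
penalised logistic fits per experiment, so the solver is implemented in
C++ (IRLS with active-set cyclic coordinate descent) using the standard
penalised-likelihood parameterisation `mean logistic loss +
λ(α‖β‖₁ + (1−α)/2‖β‖₂²)`.  It is validated two ways: against a generic
convex optimiser on the identical objective (≤ 1e-6 gap) and against
glmnet (objective agreement ~1e-9).  Probabilities are clamped to
[1e-5, 1−1e-5] inside IRLS; inner sweeps are capped (the outer
re-linearisation restores precision) so quasi-separable reweighted
subproblems — routine inside AdaBoost — stay cheap.

**Penalty strength.**  λ is chosen once per selector invocation by
stratified 5-fold cross-validation on the full input and reused across
all repeated fits — per-fit tuning would multiply cost by ~150 and add
tuning jitter to every stability comparison.  The default applies the
1-SE parsimony rule: the deviance-minimising λ produces dense coefficient
vectors under which the RENT non-zero-frequency criterion saturates and
selection degenerates toward "everything significant"; the 1-SE rule
reproduces the sparsity levels radiomic selection pipelines actually
report (a single elastic net retaining ~30 of 422 features).  In the
stability experiment one λ is resolved on the full prefiltered cohort and
shared by every run and method, so the experiment measures the stability
of a *fixed* selector under data perturbation.

**AdaBoost variant.**  Discrete two-class AdaBoost with prediction
threshold 0.5, βₘ = ½log((1−εₘ)/εₘ), stopping at εₘ ≥ 0.5 or εₘ = 0 or
`N` learners; a first learner with ε ≥ 0.5 degenerates to a flagged
single-learner chain.  The aggregated coefficient vector uses boosting
weights normalised to sum 1, keeping the RENT sign criterion meaningful.

**ICC form.**  Two-way mixed-effects, single-measurement, absolute
agreement — the recommended form for intra-observer reliability —
computed from two-way ANOVA mean squares; the p-value is the F-test of
no subject effect (MS_rows/MS_error on (n−1, n−1) df).  A consistency
form is available by configuration.

**Youden threshold.**  Candidates are the unique score values; decision
rule `score ≥ t → positive`; ties in J resolve to the smallest maximising
threshold (favouring sensitivity).  With all scores equal the degenerate
all-positive rule (J = 0) results.

**Bootstrap CIs.**  Percentile intervals from 1000 class-stratified
resamples; resamples on which a metric is undefined are redrawn and
counted.

**Classifier implementations.**  The target environment ships no SVM,
tree, or perceptron package, so these are implemented in-package: linear
ε-SVR solved in the primal with a lightly smoothed hinge (smoothing
μ = 1e-3; the optimum is within O(μ) of the exact solution) under BFGS; a
compact CART random forest (Gini, bootstrap bags, √p feature subsampling)
in C++; an averaged perceptron whose reported score is the
logistic-squashed decision value, making it bounded and
threshold-comparable.  kNN scores are positive-neighbour fractions via
FNN.  Logistic regression deliberately returns binary 0/1 predictions
(its ROC curve has three points), mirroring the modelling convention of
the pipeline this package reproduces.

**Nogueira significance test.**  The variance of Φ̂ is estimated with the
delta-method influence-function estimator; our derivation fixes the sign
of the Φ/2 correction term (it enters positively).  Verified numerically:
estimator/empirical-variance ratio ≈ 1.01 and null rejection rates inside
the 99% binomial band at M = 200 under a heterogeneous-probability null.
A caveat worth knowing: at an *exactly exchangeable* null (every feature
selected with the same probability, so Φ ≈ 0) the first-order influence
term vanishes identically — numerator and denominator perturbations
cancel — and the test becomes strongly conservative.  This is a property
of the published estimator, not an implementation artefact.

**Jaccard t-tests.**  As conventionally reported, the C(M,2) pairwise
Jaccard values are treated as independent observations in an unpaired
t-test.  They are not independent (each run contributes to M−1 pairs),
so the p-values are optimistic; because the same M subsamples are shared
across methods, a paired variant is reported alongside.

## The synthetic stated world

`synthetic_config()` defaults describe a cohort of 221 samples per class
and 422 features:

* three strong, mutually independent informative features
  (d = 1.2, 1.0, 0.7) — the stable "shape-like" core that real pipelines
  select in essentially every run;
* six blocks of 30 highly correlated features (ρ = 0.85) carrying thin
  weak effects (d = 0.25, 0.25, 0.20, 0.20, 0.15, 0.15 per member), plus
  two null blocks — the "texture-like" redundancy whose
  representative-switching under the L1 penalty is the main driver of
  selection instability;
* independent noise features filling the pool to 422;
* a replicate measurement with additive noise (sd 0.2 per feature; with
  unit between-sample variance the implied ICC is 1/(1+σ²));
* a shifted second cohort (scale 1.2, offset +0.5, extra noise sd 0.3)
  emulating acquisition under a different protocol, e.g. a lower field
  strength;
* an optional log-normal transform to exercise the Mann–Whitney branch
  of the univariate filter (effect sizes then apply on the latent scale).

Block sizes and ρ are package conventions — the inter-feature correlation
of real radiomic tables is not characterised in our source material — and
the effect profile was calibrated to reproduce printed *selection
signatures* (single elastic net ≈ 30 selected of 422; small RENT sets
with a stable core and an oscillating weak tail; boosted-RENT sets larger
than RENT sets), not to any acceptance threshold.  What a green test on
this world establishes is that the machinery behaves correctly on data
with the assumed location/scale/correlation structure; it does not
establish performance on real MRI radiomics, whose feature distributions,
correlation topology and label noise are richer than any
location-scale-correlation model.

## Known limitations

* **Reduced-scale stability ordering.**  At full scale the source method
  reports stability Φ(BB-RENT) > Φ(RENT) > Φ(boosted RENT).  At the
  reduced scale used for desk-sized testing (N = 5, K = 30, Q = 20) our
  experiments robustly reproduce the *degradation* arm — boosting makes
  selection less stable than RENT — and bagging recovers part of that
  loss, but BB-RENT does not overtake plain RENT: short boosting chains
  cannot chase enough noise for the bag vote to have much to repair,
  while a 20-bag vote contributes binomial noise of its own.  The
  corresponding acceptance criterion is left failing by design rather
  than weakened; the acceptance test reports the measured ordering
  counts.
* **Recovery precision at reduced K.**  With K = 30 repetitions the
  non-zero-frequency criterion is a markedly easier bar for
  chance-associated features than at K = 200 (binomial noise around the
  0.9 cutoff), so BB-RENT retains two-to-three "lucky" null features per
  run at n = 400; measured mean precision ≈ 0.65 against the 0.7 target,
  with recall 1.0.
* The serialized published-ensemble fixture carries placeholder Z-score
  parameters (means 0, sds 1) because the original standardisation
  constants are not distributed; structural and arithmetic properties of
  the ensemble are exactly reproducible, scores on real feature values
  are not.
* Full-scale BB-RENT (N·K·Q ≈ 750k fits) is an hours-long computation by
  construction; the package keeps it tractable (C++ core, shared λ) but
  tests and examples run at reduced N/K/Q throughout.
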