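test_that("z-score fit/apply honour their contracts", {
  set.seed(1)
  X <- matrix(rnorm(60, mean = 5, sd = 3), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  zs <- zscore_fit(X)
  S <- zscore_apply(X, zs)
  expect_lt(max(abs(colMeans(S))), 1e-9)
  expect_lt(max(abs(apply(S, 2, sd) - 1)), 1e-9)
  expect_error(zscore_fit(cbind(X, const = rep(2, 20))), "variance_filter")
  # shifted data keeps ordering, gains non-zero means
  S2 <- zscore_apply(1.5 * X + 2, zs)
  expect_gt(min(abs(colMeans(S2))), 0.1)
  expect_identical(order(S2[, 1]), order(S[, 1]))
})

test_that("every classifier separates a separable toy; logistic is binary", {
  set.seed(2)
  n <- 40
  X <- rbind(matrix(rnorm(n * 2, -2, 0.4), n, 2),
             matrix(rnorm(n * 2, 2, 0.4), n, 2))
  colnames(X) <- c("u", "v")
  y <- rep(c(0, 1), each = n)
  zs <- zscore_fit(X)
  S <- zscore_apply(X, zs)
  for (kind in c("svr-linear", "logistic", "random-forest", "perceptron",
                 "knn")) {
    m <- train_classifier(classifier_spec(kind, seed = 7), S, y)
    sc <- predict_scores(m, S)
    expect_equal(roc_auc(sc, y), 1,
                 info = kind, tolerance = if (kind == "logistic") 0 else 1e-9)
    if (kind == "logistic") expect_true(all(sc %in% c(0, 1)))
    if (kind == "perceptron") expect_true(all(sc >= 0 & sc <= 1))
  }
  expect_error(train_classifier(classifier_spec("knn"), S, rep(1, 2 * n)),
               "single-class")
})

test_that("label-permuted data gives chance-level internal CV AUC", {
  set.seed(3)
  X <- scale(matrix(rnorm(160 * 5), 160, 5))
  colnames(X) <- paste0("f", 1:5)
  y <- sample(rep(c(0, 1), 80))
  folds <- stratified_folds(y, 4, seed = 5)
  aucs <- vapply(1:4, function(f) {
    m <- train_classifier(classifier_spec("svr-linear", seed = f),
                          X[folds != f, ], y[folds != f])
    roc_auc(predict_scores(m, X[folds == f, ]), y[folds == f])
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
})

test_that("roc_auc equals brute-force pairwise concordance", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(1:6, c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(roc_auc(rep(2, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  set.seed(6)
  for (r in 1:25) {
    n <- sample(6:30, 1)
    s <- sample(round(runif(n), 2))  # duplicates force tie handling
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    pos <- s[y == 1]; neg <- s[y == 0]
    conc <- 0
    for (a in pos) for (b in neg)
      conc <- conc + (a > b) + 0.5 * (a == b)
    expect_equal(roc_auc(s, y), conc / (length(pos) * length(neg)),
                 tolerance = 1e-12)
  }
})

test_that("youden_threshold equals an exhaustive scan", {
  got <- youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(got$threshold, 0.8)
  expect_equal(got$j, 1)
  flat <- youden_threshold(rep(0.3, 8), rep(c(0, 1), 4))
  expect_equal(flat$j, 0)
  # anti-ordered scores: the all-positive rule at the minimum score wins
  anti <- youden_threshold(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1))
  expect_equal(anti$threshold, 0.1)
  expect_equal(anti$j, 0)
  set.seed(7)
  for (r in 1:25) {
    n <- sample(5:25, 1)
    s <- round(runif(n), 2)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    best <- -Inf; best_t <- Inf
    for (t in sort(unique(s))) {
      j <- mean(s[y == 1] >= t) + mean(s[y == 0] < t) - 1
      if (j > best + 1e-12) { best <- j; best_t <- t }
    }
    got <- youden_threshold(s, y)
    expect_equal(got$threshold, best_t)
    expect_equal(got$j, best, tolerance = 1e-12)
  }
})

test_that("bootstrap CI behaves on constants and contains the point", {
  y <- rep(c(0, 1), each = 20)
  s <- c(rnorm(20), rnorm(20, 1))
  const <- bootstrap_ci(function(s, l) 0.7, s, y, B = 50, seed = 1)
  expect_equal(const$lo, 0.7)
  expect_equal(const$hi, 0.7)
  ci <- bootstrap_ci(roc_auc, s, y, B = 200, seed = 2)
  expect_lte(ci$lo, ci$point)
  expect_gte(ci$hi, ci$point)
  # mean-statistic CI endpoints close to the analytic normal interval
  set.seed(8)
  v <- rnorm(200)
  ym <- rep(c(0, 1), 100)
  ci_m <- bootstrap_ci(function(s, l) mean(s), v, ym, B = 1000, seed = 3)
  half_boot <- (ci_m$hi - ci_m$lo) / 2
  half_norm <- qnorm(0.975) * sd(v) / sqrt(200)
  expect_lt(abs(half_boot - half_norm) / half_norm, 0.15)
})

test_that("stratified folds are maximally balanced", {
  f442 <- stratified_folds(rep(c(0, 1), each = 221), 5, seed = 1)
  expect_equal(sort(as.integer(table(f442)), decreasing = TRUE),
               c(89, 89, 88, 88, 88))
  f10 <- stratified_folds(rep(c(0, 1), each = 5), 5, seed = 2)
  tab <- table(f10, rep(c(0, 1), each = 5))
  expect_true(all(tab == 1))  # one sample of each class per fold
})

test_that("cross-validation recovers planted signal end to end", {
  co <- generate_cohort(recovery_config(seed = 910))
  cv <- cross_validate(co$pair, co$labels,
                       spec = classifier_spec("svr-linear", seed = 1),
                       cfg = reduced_bbrent(seed = 1, K = 15L, Q = 10L),
                       k = 5, seed = 1, B = 100L)
  auc <- cv$mean_summary$mean[cv$mean_summary$metric == "auc"]
  expect_gt(auc, 0.75)
  sel <- unique(unlist(lapply(cv$fold_models, `[[`, "feature_ids")))
  expect_gte(jaccard(sel, co$truth$informative), 0.3)
  expect_length(cv$fold_models, 5)
  for (fm in cv$fold_models) {
    expect_true(fm$auc >= 0 && fm$auc <= 1)
    expect_true(is.finite(fm$youden_threshold))
  }
})

test_that("ensemble construction enforces and satisfies its invariants", {
  co <- generate_cohort(recovery_config(seed = 920))
  cv <- cross_validate(co$pair, co$labels,
                       spec = classifier_spec("svr-linear", seed = 2),
                       cfg = reduced_bbrent(seed = 2, K = 10L, Q = 6L),
                       k = 5, seed = 2, B = 50L)
  em <- build_ensemble(cv$fold_models, provenance = "test")
  th <- vapply(em$folds, `[[`, 0, "youden_threshold")
  expect_lt(max(abs(em$weights * th - 1 / 5)), 1e-12)
  # a probe scoring exactly threshold_i on every fold model scores 1:
  # verified through the weight identity sum_i w_i * t_i = 1
  expect_equal(sum(em$weights * th), 1, tolerance = 1e-12)
  scores <- predict_ensemble(em, co$pair$primary)
  expect_length(scores, length(co$labels))
  # non-positive thresholds are rejected
  broken <- cv$fold_models
  broken[[1]]$youden_threshold <- -0.1
  expect_error(build_ensemble(broken), "non-positive")
  # non-linear classifiers cannot be aggregated
  cvk <- cross_validate(co$pair, co$labels,
                        spec = classifier_spec("knn", seed = 3),
                        cfg = reduced_bbrent(seed = 2, K = 10L, Q = 6L),
                        k = 5, seed = 2, B = 10L)
  expect_error(build_ensemble(cvk$fold_models), "linear")
})

test_that("published fixture reproduces its printed arithmetic", {
  m <- npc_ensemble_fixture()
  # all-zero standardised features leave only the weighted intercepts
  probe <- matrix(0, 1, 17, dimnames = list("p", ensemble_features(m)))
  expect_equal(predict_ensemble(m, probe)[[1]], 1.0160, tolerance = 5e-4)
  # thresholds implied by the printed weights average to the printed 0.51
  th <- vapply(m$folds, `[[`, 0, "youden_threshold")
  expect_equal(round(mean(th), 2), 0.51)
})

test_that("recalibration reports both thresholds and flags degeneracy", {
  co <- generate_cohort(recovery_config(seed = 930))
  cv <- cross_validate(co$pair, co$labels,
                       spec = classifier_spec("svr-linear", seed = 4),
                       cfg = reduced_bbrent(seed = 4, K = 10L, Q = 6L),
                       k = 5, seed = 4, B = 50L)
  em <- build_ensemble(cv$fold_models)
  rec <- recalibrate_threshold(em, co$pair$primary, B = 50L, seed = 4)
  expect_true(rec$threshold >= min(rec$scores) &&
                rec$threshold <= max(rec$scores))
  expect_identical(attr(rec$summary_normalized, "threshold_origin"),
                   "training-normalized")
  expect_identical(attr(rec$summary_recalibrated, "threshold_origin"),
                   "recalibrated")
  # all scores above the normalised threshold: specificity 0, flagged
  em2 <- em
  for (i in seq_along(em2$folds)) em2$folds[[i]]$intercept <-
      em2$folds[[i]]$intercept + 100
  rec2 <- suppressMessages(
    recalibrate_threshold(em2, co$pair$primary, B = 20L, seed = 5))
  expect_true(rec2$degenerate)
})
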