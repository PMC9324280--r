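#' Classifier specification
#'
#' The classifier zoo: linear support vector regression on 0/1 targets
#' (continuous scores near `[0, 1]`), logistic regression (binary 0/1
#' predictions), random forest, perceptron (logistic-squashed decision
#' value, so the score is bounded and threshold-comparable) and k-nearest
#' neighbours (score = positive-neighbour fraction).  For every kind a
#' larger score means "more likely class 1".
#'
#' @param kind one of `"svr-linear"`, `"logistic"`, `"random-forest"`,
#'   `"perceptron"`, `"knn"`.
#' @param grid named list of hyperparameter vectors searched by internal
#'   stratified cross-validation; `NULL` uses the per-kind default
#'   (`svr-linear`: C in 0.1/1/10; `random-forest`: 100/300 trees, depth
#'   unlimited/10; `knn`: k in 5/11/21).
#' @param seed RNG seed for fitting and the internal grid search.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svr-linear", "logistic",
                                     "random-forest", "perceptron", "knn"),
                            grid = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(grid))
    grid <- switch(kind,
      "svr-linear" = list(C = c(0.1, 1, 10)),
      "logistic" = list(),
      "random-forest" = list(ntree = c(100, 300), maxdepth = c(0, 10)),
      "perceptron" = list(epochs = 100),
      "knn" = list(k = c(5, 11, 21)))
  structure(list(kind = kind, grid = grid, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Stratified fold assignment
#'
#' Seeded shuffle within each class, then round-robin assignment with a
#' per-class rotated starting fold, which yields maximally balanced fold
#' sizes (e.g. 442 samples split 221/221 give folds of 89/89/88/88/88).
#'
#' @param labels 0/1 class labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer vector of fold indices in `1:k`.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  labels <- as.integer(labels)
  set.seed(derive_seed(seed, 41L))
  folds <- integer(length(labels))
  classes <- sort(unique(labels))
  for (ci in seq_along(classes)) {
    idx <- which(labels == classes[ci])
    idx <- if (length(idx) > 1) sample(idx) else idx
    folds[idx] <- ((seq_along(idx) - 1L + (ci - 1L)) %% k) + 1L
  }
  folds
}

# ---- individual learners ---------------------------------------------------

# Linear epsilon-insensitive support vector regression on 0/1 targets,
# solved in the primal with a lightly smoothed hinge (smoothing mu keeps
# the objective differentiable; the optimum is within O(mu) of the exact
# SVR solution).
fit_svr_linear <- function(X, y, C = 1, epsilon = 0.1, mu = 1e-3) {
  n <- nrow(X); p <- ncol(X)
  hub <- function(t) ifelse(t <= 0, 0, ifelse(t < mu, t^2 / (2 * mu), t - mu / 2))
  dhub <- function(t) ifelse(t <= 0, 0, ifelse(t < mu, t / mu, 1))
  obj <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1]
    res <- y - drop(X %*% w) - b
    0.5 * sum(w^2) + C * sum(hub(abs(res) - epsilon))
  }
  grad <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1]
    res <- y - drop(X %*% w) - b
    g <- dhub(abs(res) - epsilon) * sign(res)
    c(w - C * drop(crossprod(X, g)), -C * sum(g))
  }
  fit <- optim(rep(0, p + 1), obj, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  list(coefficients = setNames(fit$par[seq_len(p)], colnames(X)),
       intercept = fit$par[p + 1])
}

# Averaged perceptron on {-1, +1}; the reported score is the
# logistic-squashed averaged decision value.
fit_perceptron <- function(X, y, epochs = 100, seed = 1L) {
  set.seed(derive_seed(seed, 47L))
  n <- nrow(X); p <- ncol(X)
  yy <- ifelse(y == 1, 1, -1)
  w <- rep(0, p); b <- 0
  wsum <- rep(0, p); bsum <- 0; updates <- 0
  for (e in seq_len(epochs)) {
    for (i in sample.int(n)) {
      if (yy[i] * (sum(w * X[i, ]) + b) <= 0) {
        w <- w + yy[i] * X[i, ]
        b <- b + yy[i]
      }
      wsum <- wsum + w; bsum <- bsum + b; updates <- updates + 1
    }
  }
  list(coefficients = setNames(wsum / updates, colnames(X)),
       intercept = bsum / updates)
}

train_one <- function(kind, X, y, params, seed) {
  switch(kind,
    "svr-linear" = {
      f <- fit_svr_linear(X, y, C = params$C)
      list(kind = kind, coefficients = f$coefficients,
           intercept = f$intercept)
    },
    "logistic" = {
      df <- data.frame(y = y, X, check.names = FALSE)
      f <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
      list(kind = kind, glm_coef = stats::coef(f),
           feature_names = colnames(X))
    },
    "random-forest" = {
      mtry <- max(1L, floor(sqrt(ncol(X))))
      forest <- rf_fit_cpp(X, as.integer(y), as.integer(params$ntree),
                           mtry, as.integer(params$maxdepth), 2L,
                           derive_seed(seed, 53L))
      list(kind = kind, forest = forest)
    },
    "perceptron" = {
      f <- fit_perceptron(X, y, epochs = params$epochs, seed = seed)
      list(kind = kind, coefficients = f$coefficients,
           intercept = f$intercept)
    },
    "knn" = list(kind = kind, train_x = X, train_y = y, k = params$k))
}

score_one <- function(model, X) {
  switch(model$kind,
    "svr-linear" = drop(X %*% model$coefficients) + model$intercept,
    "logistic" = {
      beta <- model$glm_coef
      beta[is.na(beta)] <- 0
      eta <- drop(X %*% beta[-1]) + beta[1]
      as.numeric(eta >= 0)  # binary 0/1 prediction
    },
    "random-forest" = as.numeric(rf_predict_cpp(model$forest, X)),
    "perceptron" = plogis(drop(X %*% model$coefficients) + model$intercept),
    "knn" = {
      k <- min(model$k, nrow(model$train_x))
      nn <- FNN::get.knnx(model$train_x, X, k = k)$nn.index
      rowMeans(matrix(model$train_y[nn], nrow(X), k))
    })
}

#' Train a classifier with internal grid search
#'
#' Fits the requested classifier on standardised predictors.  When the
#' hyperparameter grid has more than one combination, the combination with
#' the best internal stratified 3-fold cross-validated AUC is selected.
#'
#' @param spec a [classifier_spec()].
#' @param X standardised predictor matrix.
#' @param y 0/1 response (both classes must be present).
#' @return a `trained_classifier`; obtain scores with [predict_scores()].
#' @export
train_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("response is single-class")
  combos <- if (length(spec$grid)) expand.grid(spec$grid) else
    data.frame(row.names = 1)
  best <- 1L
  if (nrow(combos) > 1) {
    folds <- stratified_folds(y, 3L, seed = derive_seed(spec$seed, 59L))
    cvauc <- vapply(seq_len(nrow(combos)), function(ci) {
      aucs <- vapply(1:3, function(f) {
        tr <- folds != f
        if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2)
          return(NA_real_)
        m <- train_one(spec$kind, X[tr, , drop = FALSE], y[tr],
                       as.list(combos[ci, , drop = FALSE]), spec$seed)
        roc_auc(score_one(m, X[!tr, , drop = FALSE]), y[!tr])
      }, 0)
      mean(aucs, na.rm = TRUE)
    }, 0)
    best <- which.max(cvauc)
  }
  params <- as.list(combos[best, , drop = FALSE])
  model <- train_one(spec$kind, X, y, params, spec$seed)
  structure(list(spec = spec, model = model, params = params,
                 feature_ids = colnames(X)),
            class = "trained_classifier")
}

#' Continuous classification scores
#'
#' @param object a [train_classifier()] result.
#' @param X standardised predictor matrix with the training columns.
#' @return numeric score vector (larger = more likely class 1; logistic
#'   regression returns binary 0/1).
#' @export
predict_scores <- function(object, X) {
  stopifnot(inherits(object, "trained_classifier"))
  score_one(object$model, as.matrix(X))
}

# ---- metrics ---------------------------------------------------------------

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability with ties counted
#' one half, via midranks.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (both classes required).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-index threshold
#'
#' Scans all candidate thresholds (the unique score values) under the
#' decision rule `score >= threshold -> class 1` and returns the smallest
#' threshold maximising `J = sensitivity + specificity - 1`.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return list with `threshold`, `sensitivity`, `specificity`, `j`.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("both classes must be present")
  cand <- sort(unique(scores))
  sens <- vapply(cand, function(t) mean(scores[labels == 1L] >= t), 0)
  spec <- vapply(cand, function(t) mean(scores[labels == 0L] < t), 0)
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1]  # smallest maximising threshold
  list(threshold = cand[best], sensitivity = sens[best],
       specificity = spec[best], j = j[best])
}

#' Percentile bootstrap confidence interval
#'
#' Resamples the samples with replacement, stratified by class, and
#' returns the 2.5/97.5 percentile interval of the metric.  Resamples on
#' which the metric is undefined are redrawn (the count is reported).
#'
#' @param metric `function(scores, labels) -> scalar`.
#' @param scores,labels data to resample.
#' @param B bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95).
#' @return list with `point`, `lo`, `hi`, `redraws`.
#' @export
bootstrap_ci <- function(metric, scores, labels, B = 1000L, seed = 1L,
                         conf = 0.95) {
  labels <- as.integer(labels)
  point <- metric(scores, labels)
  idx1 <- which(labels == 1L); idx0 <- which(labels == 0L)
  set.seed(derive_seed(seed, 61L))
  stats <- numeric(B)
  redraws <- 0L
  for (b in seq_len(B)) {
    val <- NA_real_
    for (attempt in 1:100) {
      idx <- c(sample(idx1, length(idx1), replace = TRUE),
               sample(idx0, length(idx0), replace = TRUE))
      val <- tryCatch(metric(scores[idx], labels[idx]),
                      error = function(e) NA_real_)
      if (is.finite(val)) break
      redraws <- redraws + 1L
    }
    stats[b] <- val
  }
  a <- (1 - conf) / 2
  qs <- quantile(stats, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  list(point = point, lo = qs[1], hi = qs[2], redraws = redraws)
}

# Point metrics + bootstrap CIs at a fixed decision threshold.
perf_summary <- function(scores, labels, threshold, B = 1000L, seed = 1L,
                         threshold_origin = "training-normalized") {
  acc_fn <- function(s, l) mean((s >= threshold) == l)
  sens_fn <- function(s, l) mean(s[l == 1L] >= threshold)
  spec_fn <- function(s, l) mean(s[l == 0L] < threshold)
  cis <- list(auc = bootstrap_ci(roc_auc, scores, labels, B, seed),
              accuracy = bootstrap_ci(acc_fn, scores, labels, B, seed + 1L),
              sensitivity = bootstrap_ci(sens_fn, scores, labels, B, seed + 2L),
              specificity = bootstrap_ci(spec_fn, scores, labels, B, seed + 3L))
  out <- data.frame(metric = names(cis),
                    point = vapply(cis, `[[`, 0, "point"),
                    lo = vapply(cis, `[[`, 0, "lo"),
                    hi = vapply(cis, `[[`, 0, "hi"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "threshold_origin") <- threshold_origin
  out
}

# ---- cross-validation and the fold-model ensemble --------------------------

#' Stratified k-fold cross-validation of the full pipeline
#'
#' For each fold: the preliminary filter and the BB-RENT selector run on
#' the training split only, Z-score parameters are fitted on the training
#' split, the classifier is trained, and the AUC / Youden threshold /
#' sensitivity / specificity / accuracy are computed on the held-out fold.
#' The replicate table is used only for the ICC gate; modelling uses the
#' primary table.
#'
#' @param pair a [replicate_pair()].
#' @param labels 0/1 labels (default: the primary table's).
#' @param spec a [classifier_spec()].
#' @param cfg a [bbrent_config()] for the selector.
#' @param prefilter a [prefilter_config()].
#' @param k number of folds (default 5).
#' @param seed RNG seed (controls the fold split and all fold-level fits).
#' @param B bootstrap replicates for the per-fold confidence intervals.
#' @return a `cv_result`: list with `fold_models` (each carrying the
#'   selected features, z-score parameters, trained classifier, AUC and
#'   Youden operating point), `fold_summaries`, `mean_summary` and
#'   `folds` (the assignment vector).
#' @export
cross_validate <- function(pair, labels = pair$primary$labels,
                           spec = classifier_spec("svr-linear"),
                           cfg = bbrent_config(),
                           prefilter = prefilter_config(), k = 5L,
                           seed = 1L, B = 1000L) {
  stopifnot(inherits(pair, "replicate_pair"))
  if (is.null(labels)) stop("labels are required")
  labels <- as.integer(labels)
  if (min(table(labels)) < k) stop("each class needs at least k samples")
  folds <- stratified_folds(labels, k, seed = seed)
  fold_models <- vector("list", k)
  fold_summaries <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    sub <- rp_subset(pair, samples = which(tr))
    rep_f <- run_prefilter(sub, labels[tr], prefilter)
    keep <- prefilter_passing(rep_f)
    if (length(keep) == 0)
      stop(sprintf("fold %d: no feature passed the preliminary filter", f))
    fold_cfg <- cfg
    fold_cfg$seed <- derive_seed(seed, 100L + f)
    sel <- bb_rent(sub$primary$values[, keep, drop = FALSE], labels[tr],
                   fold_cfg)
    features <- sel$selected
    selection_fallback <- length(features) == 0
    if (selection_fallback) features <- keep  # degenerate selection guard
    Xtr <- sub$primary$values[, features, drop = FALSE]
    zs <- zscore_fit(Xtr)
    fspec <- spec
    fspec$seed <- derive_seed(seed, 200L + f)
    model <- train_classifier(fspec, zscore_apply(Xtr, zs), labels[tr])
    Xte <- zscore_apply(
      pair$primary$values[!tr, features, drop = FALSE], zs)
    te_scores <- predict_scores(model, Xte)
    te_labels <- labels[!tr]
    auc <- roc_auc(te_scores, te_labels)
    yt <- youden_threshold(te_scores, te_labels)
    acc <- mean((te_scores >= yt$threshold) == te_labels)
    fold_models[[f]] <- structure(
      list(fold = f, feature_ids = features, zscore = zs,
           classifier = model, auc = auc,
           youden_threshold = yt$threshold,
           sensitivity = yt$sensitivity, specificity = yt$specificity,
           accuracy = acc, selection = sel,
           selection_fallback = selection_fallback),
      class = "fold_model")
    fold_summaries[[f]] <- perf_summary(te_scores, te_labels, yt$threshold,
                                        B = B,
                                        seed = derive_seed(seed, 300L + f),
                                        threshold_origin = "fold-youden")
  }
  mets <- vapply(fold_models, function(m)
    c(auc = m$auc, accuracy = m$accuracy, sensitivity = m$sensitivity,
      specificity = m$specificity, threshold = m$youden_threshold), numeric(5))
  mean_summary <- data.frame(metric = rownames(mets),
                             mean = rowMeans(mets),
                             sd = apply(mets, 1, sd),
                             row.names = NULL, stringsAsFactors = FALSE)
  structure(list(fold_models = fold_models,
                 fold_summaries = fold_summaries,
                 mean_summary = mean_summary, folds = folds, k = k,
                 seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds\n", x$k))
  print(x$mean_summary, row.names = FALSE)
  invisible(x)
}

#' Build the reciprocal-weighted fold-model ensemble
#'
#' Aggregates `k` fold-level linear models into a single scorer
#' `score(x) = sum_i w_i * model_i(x)` with `w_i = 1 / (k * threshold_i)`,
#' so that a sample scoring exactly each fold's Youden threshold scores
#' exactly 1: the ensemble decision rule is `score >= 1 -> class 1`.
#' Requires fold models with a linear continuous scorer (linear SVR or
#' perceptron coefficients); each fold model keeps its own feature subset
#' and Z-score parameters.
#'
#' @param fold_models list of fold models from [cross_validate()] (or
#'   hand-built records with `feature_ids`, `coefficients`, `intercept`,
#'   `youden_threshold` and `zscore`).
#' @param provenance free-text provenance tag.
#' @return an object of class `ensemble_model`.
#' @export
build_ensemble <- function(fold_models, provenance = "") {
  k <- length(fold_models)
  folds <- lapply(fold_models, function(m) {
    if (inherits(m, "fold_model")) {
      mm <- m$classifier$model
      if (is.null(mm$coefficients))
        stop("ensemble aggregation requires a linear scorer (svr-linear)")
      list(feature_ids = m$feature_ids,
           coefficients = unname(mm$coefficients),
           intercept = mm$intercept,
           youden_threshold = m$youden_threshold,
           zscore = list(means = unname(m$zscore$means),
                         sds = unname(m$zscore$sds)))
    } else {
      stopifnot(all(c("feature_ids", "coefficients", "intercept",
                      "youden_threshold", "zscore") %in% names(m)))
      m
    }
  })
  thresholds <- vapply(folds, `[[`, 0, "youden_threshold")
  if (any(!is.finite(thresholds) | thresholds <= 0))
    stop("non-positive or non-finite Youden threshold: score orientation violated")
  for (f in folds)
    if (length(f$coefficients) != length(f$feature_ids))
      stop("coefficient/feature length mismatch in a fold model")
  weights <- 1 / (k * thresholds)
  structure(list(folds = folds, weights = weights, decision_threshold = 1,
                 provenance = provenance),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %d fold models, %d distinct features, decision threshold >= %g\n",
              length(x$folds), length(ensemble_features(x)),
              x$decision_threshold))
  invisible(x)
}

#' Distinct features used by an ensemble
#'
#' @param model an [build_ensemble()] result.
#' @return character vector of the distinct feature IDs across fold models.
#' @export
ensemble_features <- function(model) {
  stopifnot(inherits(model, "ensemble_model"))
  unique(unlist(lapply(model$folds, `[[`, "feature_ids")))
}

#' Score samples with an ensemble
#'
#' Each fold model standardises its own feature subset with its fold's
#' Z-score parameters, applies its linear coefficients, and contributes
#' its reciprocal weight times that score.
#'
#' @param model an `ensemble_model`.
#' @param newdata a [feature_table()] or numeric matrix with feature IDs
#'   as column names.
#' @return numeric vector of ensemble scores (decision: `score >= 1`).
#' @export
predict_ensemble <- function(model, newdata) {
  stopifnot(inherits(model, "ensemble_model"))
  X <- if (inherits(newdata, "feature_table")) newdata$values else
    as.matrix(newdata)
  total <- numeric(nrow(X))
  for (i in seq_along(model$folds)) {
    f <- model$folds[[i]]
    miss <- setdiff(f$feature_ids, colnames(X))
    if (length(miss))
      stop("newdata lacks feature(s): ", paste(miss, collapse = ", "))
    Xi <- X[, f$feature_ids, drop = FALSE]
    Xi <- sweep(sweep(Xi, 2, f$zscore$means, "-"), 2, f$zscore$sds, "/")
    total <- total + model$weights[i] *
      (drop(Xi %*% f$coefficients) + f$intercept)
  }
  total
}

#' Recalibrate the ensemble decision threshold on a new cohort
#'
#' The training-normalised threshold (>= 1) need not maximise the Youden
#' index on a cohort acquired under a different protocol.  This recomputes
#' the Youden threshold on the new cohort's ensemble scores and reports
#' performance summaries at both thresholds.
#'
#' @param model an `ensemble_model`.
#' @param cohort a labelled [feature_table()].
#' @param B bootstrap replicates for the confidence intervals.
#' @param seed RNG seed.
#' @return list with `threshold` (recalibrated), `scores`,
#'   `summary_normalized`, `summary_recalibrated`, and `degenerate`
#'   (`TRUE` when the normalised threshold yields zero specificity).
#' @export
recalibrate_threshold <- function(model, cohort, B = 1000L, seed = 1L) {
  stopifnot(inherits(model, "ensemble_model"),
            inherits(cohort, "feature_table"))
  if (is.null(cohort$labels)) stop("cohort must be labelled")
  scores <- predict_ensemble(model, cohort)
  labels <- cohort$labels
  yt <- youden_threshold(scores, labels)
  s_norm <- perf_summary(scores, labels, model$decision_threshold, B, seed,
                         threshold_origin = "training-normalized")
  s_rec <- perf_summary(scores, labels, yt$threshold, B, seed + 10L,
                        threshold_origin = "recalibrated")
  degenerate <- s_norm$point[s_norm$metric == "specificity"] == 0
  if (degenerate)
    message("normalized threshold yields zero specificity on this cohort")
  list(threshold = yt$threshold, scores = scores,
       summary_normalized = s_norm, summary_recalibrated = s_rec,
       degenerate = degenerate)
}
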