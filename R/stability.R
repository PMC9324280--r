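#' Jaccard index between two feature sets
#'
#' `|a n b| / |a u b|`, defined as 1 when both sets are empty.
#'
#' @param a,b character vectors (feature-ID sets).
#' @return numeric scalar in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Bundle repeated selection runs
#'
#' @param sets list of feature-ID character vectors, one per resampling
#'   run (M >= 2).
#' @param pool the full feature pool (character vector of IDs, or its size
#'   `d` when only anonymous indices matter).
#' @param method free-text method tag.
#' @return an object of class `selection_runs`.
#' @export
selection_runs <- function(sets, pool, method = "") {
  if (length(sets) < 2) stop("need at least M = 2 runs")
  if (is.numeric(pool) && length(pool) == 1)
    pool <- paste0("f", seq_len(pool))
  pool <- as.character(pool)
  sets <- lapply(sets, function(s) unique(as.character(s)))
  bad <- vapply(sets, function(s) !all(s %in% pool), TRUE)
  if (any(bad)) stop("run ", which(bad)[1], " selects features outside the pool")
  structure(list(method = method, sets = sets, pool = pool),
            class = "selection_runs")
}

# M x d binary selection matrix of a selection_runs object.
selection_matrix <- function(runs) {
  Z <- matrix(0L, length(runs$sets), length(runs$pool),
              dimnames = list(NULL, runs$pool))
  for (i in seq_along(runs$sets)) Z[i, runs$sets[[i]]] <- 1L
  Z
}

as_selection_matrix <- function(runs) {
  if (inherits(runs, "selection_runs")) selection_matrix(runs)
  else {
    Z <- as.matrix(runs)
    storage.mode(Z) <- "integer"
    Z
  }
}

#' Mean pairwise Jaccard index over repeated runs
#'
#' Statistics over all `choose(M, 2)` unordered pairs of runs.
#'
#' @param runs a [selection_runs()] object (or a binary M x d matrix).
#' @return list with `mean`, `sd` and the vector of all pairwise `values`.
#' @export
mean_pairwise_jaccard <- function(runs) {
  Z <- as_selection_matrix(runs)
  M <- nrow(Z)
  if (M < 2) stop("need at least M = 2 runs")
  inter <- tcrossprod(Z)
  k <- rowSums(Z)
  un <- outer(k, k, "+") - inter
  J <- ifelse(un > 0, inter / un, 1)  # two empty sets agree perfectly
  vals <- J[upper.tri(J)]
  list(mean = mean(vals), sd = sd(vals), values = vals)
}

#' Nogueira stability score
#'
#' The variance-based stability estimator
#' \deqn{\Phi = 1 - \frac{\frac{1}{d}\sum_f s_f^2}
#'   {\frac{\bar k}{d}\left(1 - \frac{\bar k}{d}\right)}}
#' with \eqn{s_f^2 = \frac{M}{M-1}\hat p_f (1 - \hat p_f)}, where
#' \eqn{\hat p_f} is the selection frequency of feature `f` across the `M`
#' runs and \eqn{\bar k} the mean subset size.  Equals 1 for a perfectly
#' stable selector, is close to 0 for a selector drawing features at
#' random, and can be negative.
#'
#' @param runs a [selection_runs()] object or a binary M x d matrix.
#' @return numeric scalar (at most 1).
#' @export
nogueira_score <- function(runs) {
  Z <- as_selection_matrix(runs)
  M <- nrow(Z); d <- ncol(Z)
  if (M < 2) stop("need at least M = 2 runs")
  kbar <- mean(rowSums(Z))
  if (kbar == 0 || kbar == d)
    stop("stability undefined for trivial selectors (mean subset size 0 or d)")
  phat <- colMeans(Z)
  s2 <- M / (M - 1) * phat * (1 - phat)
  1 - mean(s2) / ((kbar / d) * (1 - kbar / d))
}

# Asymptotic variance of the Nogueira score estimator (delta-method
# estimator from the originating work); also returns the score.
nogueira_score_var <- function(runs) {
  Z <- as_selection_matrix(runs)
  M <- nrow(Z); d <- ncol(Z)
  stab <- nogueira_score(Z)
  phat <- colMeans(Z)
  ki <- rowSums(Z)
  kbar <- mean(ki)
  denom <- (kbar / d) * (1 - kbar / d)
  phi <- (1 / denom) * ((Z %*% phat) / d - ki * kbar / d^2 +
    (stab / 2) * (2 * ki * kbar / d^2 - ki / d - kbar / d + 1))
  phi <- as.numeric(phi)
  list(score = stab, var = (4 / M^2) * sum((phi - mean(phi))^2))
}

#' Significance test for a difference in Nogueira stability
#'
#' Compares the stability scores of two run sets over the same feature
#' pool: the difference of the two estimates divided by the square root of
#' the sum of their asymptotic variance estimates, referred to a standard
#' normal distribution (two-sided).
#'
#' @param runs_a,runs_b [selection_runs()] objects (or binary matrices)
#'   over the same pool.
#' @return list with `z`, `p`, and the two scores `phi_a`, `phi_b`.
#' @export
nogueira_test <- function(runs_a, runs_b) {
  if (inherits(runs_a, "selection_runs") &&
      inherits(runs_b, "selection_runs") &&
      !identical(runs_a$pool, runs_b$pool))
    stop("run sets must share the same feature pool")
  a <- nogueira_score_var(runs_a)
  b <- nogueira_score_var(runs_b)
  se <- sqrt(a$var + b$var)
  z <- if (se > 0) (a$score - b$score) / se else 0
  list(z = z, p = 2 * pnorm(-abs(z)), phi_a = a$score, phi_b = b$score)
}

#' Feature-selection stability experiment
#'
#' Draws `M` subsamples of the cohort (a fixed fraction of the samples,
#' without replacement; the same subsamples are shared across all compared
#' methods so the comparison is paired by design), re-runs the preliminary
#' filter inside each subsample, applies every selector to the filtered
#' features, and summarises the M selected sets per method with the mean
#' subset size, the mean pairwise Jaccard index and the Nogueira score.
#' Methods are compared pairwise with an unpaired t-test on the pairwise
#' Jaccard values (as conventionally reported; a paired variant is
#' included because the run pairs coincide across methods) and with the
#' asymptotic [nogueira_test()].
#'
#' @param pair a [replicate_pair()].
#' @param labels 0/1 labels (default: the primary table's).
#' @param methods character vector of built-in selector names (see
#'   [select_features()]) and/or a named list mixing names with custom
#'   selector functions `function(X, y) -> character IDs` (useful for
#'   mock selectors in tests).
#' @param M number of resampling runs (default 100).
#' @param fraction subsample fraction (default 0.8).
#' @param seed master RNG seed.
#' @param prefilter a [prefilter_config()].
#' @param cfg a [bbrent_config()] governing the built-in selectors.
#' @return a `stability_report`: list with `runs` (per-method
#'   [selection_runs()]), `summary` (data frame), `jac_tests` and
#'   `ns_tests` (pairwise comparison data frames).
#' @export
stability_experiment <- function(pair, labels = pair$primary$labels,
                                 methods = c("enet", "rent", "boosted-rent",
                                             "bagged-rent", "bb-rent"),
                                 M = 100L, fraction = 0.8, seed = 1L,
                                 prefilter = prefilter_config(),
                                 cfg = bbrent_config()) {
  stopifnot(inherits(pair, "replicate_pair"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  if (is.null(labels)) stop("labels are required")
  labels <- as.integer(labels)
  if (!is.list(methods)) {
    methods <- as.list(methods)
    names(methods) <- vapply(methods, identity, "")
  }
  if (is.null(names(methods)) || any(!nzchar(names(methods))))
    stop("methods must be named")
  n <- length(pair$primary$sample_ids)
  m <- max(2L, round(fraction * n))
  pool <- pair$primary$feature_ids
  # The penalty strength is resolved once, on the full cohort after the
  # preliminary filter, and reused across every resampling run and method:
  # the experiment then measures the stability of a *fixed* selector under
  # data perturbation rather than mixing in tuning jitter.
  shared_lambda <- cfg$enet$reg_strength
  if (identical(shared_lambda, "auto")) {
    full_rep <- run_prefilter(pair, labels, prefilter)
    full_keep <- prefilter_passing(full_rep)
    shared_lambda <- if (length(full_keep))
      resolve_lambda(pair$primary$values[, full_keep, drop = FALSE],
                     labels, cfg$enet, seed = derive_seed(seed, 499L))
    else 0.01
  }
  set.seed(derive_seed(seed, 31L))
  subsamples <- lapply(seq_len(M), function(r) {
    for (attempt in 1:25) {
      idx <- sample.int(n, m)
      if (length(unique(labels[idx])) == 2) return(idx)
    }
    idx
  })
  sets <- lapply(methods, function(...) vector("list", M))
  for (r in seq_len(M)) {
    idx <- subsamples[[r]]
    sub <- rp_subset(pair, samples = idx)
    rep_r <- run_prefilter(sub, labels[idx], prefilter)
    keep <- prefilter_passing(rep_r)
    X <- sub$primary$values[, keep, drop = FALSE]
    y <- labels[idx]
    lambda <- shared_lambda
    run_cfg <- cfg
    run_cfg$seed <- derive_seed(seed, 1000L + r)
    for (mm in names(methods)) {
      spec <- methods[[mm]]
      sel <- if (is.function(spec)) {
        as.character(spec(X, y))
      } else if (length(keep) == 0) {
        character(0)
      } else {
        select_features(X, y, method = spec, cfg = run_cfg,
                        lambda = lambda)$selected
      }
      sets[[mm]][[r]] <- sel
    }
  }
  runs <- lapply(names(methods), function(mm)
    selection_runs(sets[[mm]], pool, method = mm))
  names(runs) <- names(methods)
  summary_df <- do.call(rbind, lapply(names(runs), function(mm) {
    sizes <- lengths(runs[[mm]]$sets)
    jac <- mean_pairwise_jaccard(runs[[mm]])
    phi <- tryCatch(nogueira_score(runs[[mm]]), error = function(e) NA_real_)
    data.frame(method = mm, mean_size = mean(sizes), sd_size = sd(sizes),
               jac_mean = jac$mean, jac_sd = jac$sd, nogueira = phi,
               stringsAsFactors = FALSE)
  }))
  pairs <- if (length(runs) >= 2) utils::combn(names(runs), 2) else NULL
  jac_tests <- ns_tests <- NULL
  if (!is.null(pairs)) {
    jac_tests <- do.call(rbind, apply(pairs, 2, function(pr) {
      va <- mean_pairwise_jaccard(runs[[pr[1]]])$values
      vb <- mean_pairwise_jaccard(runs[[pr[2]]])$values
      const <- sd(va) == 0 && sd(vb) == 0
      data.frame(method_a = pr[1], method_b = pr[2],
                 p_unpaired = if (const) as.numeric(mean(va) == mean(vb))
                   else t.test(va, vb)$p.value,
                 p_paired = if (const) as.numeric(all(va == vb))
                   else t.test(va, vb, paired = TRUE)$p.value,
                 stringsAsFactors = FALSE)
    }))
    ns_tests <- do.call(rbind, apply(pairs, 2, function(pr) {
      tst <- tryCatch(nogueira_test(runs[[pr[1]]], runs[[pr[2]]]),
                      error = function(e) list(z = NA_real_, p = NA_real_))
      data.frame(method_a = pr[1], method_b = pr[2], z = tst$z, p = tst$p,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(runs = runs, summary = summary_df, jac_tests = jac_tests,
                 ns_tests = ns_tests, M = M, fraction = fraction,
                 seed = seed),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> M = %d runs, fraction = %g\n",
              x$M, x$fraction))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
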