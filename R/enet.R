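#' Elastic-net configuration
#'
#' Parameterisation matches the common penalised-likelihood form: the
#' penalty is `lambda * (l1_ratio * ||b||_1 + (1 - l1_ratio)/2 * ||b||_2^2)`
#' added to the mean (weighted) logistic negative log-likelihood.
#'
#' @param l1_ratio mixing parameter in `[0, 1]` (1 = lasso, 0 = ridge).
#' @param reg_strength penalty strength `lambda > 0`, or `"auto"` to pick
#'   it by internal stratified 5-fold cross-validation.
#' @param max_iter maximum IRLS iterations.
#' @param tol convergence tolerance on coefficient changes.
#' @return an object of class `enet_config`.
#' @export
enet_config <- function(l1_ratio = 0.5, reg_strength = "auto",
                        max_iter = 50L, tol = 1e-6) {
  if (l1_ratio < 0 || l1_ratio > 1) stop("l1_ratio must lie in [0, 1]")
  if (!identical(reg_strength, "auto")) {
    reg_strength <- as.numeric(reg_strength)
    if (!is.finite(reg_strength) || reg_strength <= 0)
      stop("reg_strength must be > 0 or \"auto\"")
  }
  structure(list(l1_ratio = l1_ratio, reg_strength = reg_strength,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "enet_config")
}

#' Fit an elastic-net penalised logistic model
#'
#' Minimises the elastic-net penalised mean logistic loss by iteratively
#' reweighted least squares with cyclic coordinate descent.  The caller is
#' expected to hand in standardised predictors; no internal scaling is
#' performed.  Deterministic given inputs and configuration.
#'
#' @param X numeric matrix of standardised predictors.
#' @param y 0/1 response.
#' @param cfg an [enet_config()]; `reg_strength` must be numeric here
#'   (resolve `"auto"` beforehand with [cv_reg_strength()]).
#' @param sample_weights optional non-negative per-sample weights
#'   (normalised internally to sum 1).
#' @return list with `coefficients` (named when `X` has column names),
#'   `intercept`, `converged` and `iterations`.  Non-convergence at
#'   `max_iter` triggers a warning and a `converged = FALSE` flag.
#' @export
fit_elastic_net <- function(X, y, cfg = enet_config(reg_strength = 0.01),
                            sample_weights = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be 0/1")
  if (identical(cfg$reg_strength, "auto"))
    stop("reg_strength is \"auto\"; resolve it with cv_reg_strength() first")
  if (is.null(sample_weights)) sample_weights <- rep(1, nrow(X))
  if (any(sample_weights < 0)) stop("sample_weights must be >= 0")
  fit <- enet_fit_cpp(X, y, as.numeric(sample_weights),
                      cfg$reg_strength, cfg$l1_ratio, cfg$max_iter, cfg$tol)
  if (!fit$converged)
    warning("elastic net did not converge within max_iter; result flagged")
  coef <- as.numeric(fit$beta)
  names(coef) <- colnames(X)
  list(coefficients = coef, intercept = fit$intercept,
       converged = fit$converged, iterations = fit$iterations)
}

# Penalised objective on the fit scale; used by tests against an
# independent convex optimiser and exported for that purpose.

#' Elastic-net penalised logistic objective
#'
#' The exact function [fit_elastic_net()] minimises; exposed so that the
#' solver can be validated against generic optimisers.
#'
#' @inheritParams fit_elastic_net
#' @param coefficients,intercept candidate solution.
#' @return scalar objective value.
#' @export
enet_objective <- function(X, y, coefficients, intercept, cfg,
                           sample_weights = NULL) {
  X <- as.matrix(X)
  if (is.null(sample_weights)) sample_weights <- rep(1, nrow(X))
  v <- sample_weights / sum(sample_weights)
  eta <- drop(X %*% coefficients) + intercept
  loss <- sum(v * (log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta))
  pen <- cfg$reg_strength * (cfg$l1_ratio * sum(abs(coefficients)) +
                             (1 - cfg$l1_ratio) / 2 * sum(coefficients^2))
  loss + pen
}

#' Choose the penalty strength by cross-validation
#'
#' Stratified k-fold cross-validation over a log-spaced grid descending
#' from the smallest lambda that zeroes every coefficient; the lambda with
#' the smallest mean held-out binomial deviance wins.  Chosen once per
#' selector invocation and reused across all repeated fits, which keeps
#' the ensemble selector tractable.
#'
#' @param X standardised predictor matrix.
#' @param y 0/1 response.
#' @param l1_ratio elastic-net mixing parameter.
#' @param nfolds folds (default 5).
#' @param nlambda grid size (default 30).
#' @param lambda_min_ratio smallest grid value relative to lambda_max.
#' @param seed RNG seed for the fold split.
#' @param rule `"1se"` (default) picks the strongest penalty whose mean
#'   deviance is within one standard error of the minimum — the usual
#'   parsimony convention, which favours sparse, stable selection;
#'   `"min"` picks the deviance-minimising penalty.
#' @return the selected lambda (numeric scalar).
#' @export
cv_reg_strength <- function(X, y, l1_ratio = 0.5, nfolds = 5L,
                            nlambda = 30L, lambda_min_ratio = 0.01,
                            seed = 1L, rule = c("1se", "min")) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  lmax <- max(abs(crossprod(X, y - mean(y)))) / n / max(l1_ratio, 1e-3)
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1
  grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                  length.out = nlambda))
  folds <- stratified_folds(y, nfolds, seed = seed)
  dev <- matrix(NA_real_, nfolds, nlambda)
  for (f in seq_len(nfolds)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 1) next
    for (l in seq_along(grid)) {
      fit <- enet_fit_cpp(X[tr, , drop = FALSE], y[tr],
                          rep(1, sum(tr)), grid[l], l1_ratio, 200L, 1e-6)
      eta <- drop(X[!tr, , drop = FALSE] %*% as.numeric(fit$beta)) +
        fit$intercept
      dev[f, l] <- mean(log1p(exp(-abs(eta))) + pmax(eta, 0) -
                          y[!tr] * eta)
    }
  }
  mdev <- colMeans(dev, na.rm = TRUE)
  best <- which.min(mdev)
  if (rule == "min") return(grid[best])
  se <- apply(dev, 2, sd, na.rm = TRUE) / sqrt(nfolds)
  # grid is descending in lambda: take the largest lambda within 1 SE
  grid[min(which(mdev <= mdev[best] + se[best]))]
}
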