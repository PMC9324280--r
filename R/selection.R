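#' RENT selection criteria
#'
#' A feature survives the repeated elastic net when, across the K repeated
#' fits, (i) its coefficient is non-zero in at least a fraction `tau1` of
#' runs, (ii) the majority coefficient sign occurs in at least a fraction
#' `tau2` of the non-zero runs, and (iii) a one-sample t-test rejects a
#' zero mean coefficient at level `tau3`.
#'
#' @param tau1 non-zero frequency cutoff in `[0, 1]` (default 0.9).
#' @param tau2 sign-stability cutoff in `[0, 1]` (default 0.9).
#' @param tau3 two-sided significance level for the t-test (default 0.05).
#' @param K number of repeated fits (default 200).
#' @param subsample_fraction fraction of samples drawn without replacement
#'   for each repeated fit (default 0.8).
#' @return an object of class `rent_criteria`.
#' @export
rent_criteria <- function(tau1 = 0.9, tau2 = 0.9, tau3 = 0.05, K = 200L,
                          subsample_fraction = 0.8) {
  if (tau1 < 0 || tau1 > 1 || tau2 < 0 || tau2 > 1)
    stop("tau1 and tau2 must lie in [0, 1]")
  if (tau3 <= 0 || tau3 >= 1) stop("tau3 must lie in (0, 1)")
  if (K < 2) stop("K must be at least 2")
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop("subsample_fraction must lie in (0, 1]")
  structure(list(tau1 = tau1, tau2 = tau2, tau3 = tau3, K = as.integer(K),
                 subsample_fraction = subsample_fraction),
            class = "rent_criteria")
}

#' BB-RENT configuration
#'
#' Hyperparameters of the bagged-boosted repeated elastic net: `N` weak
#' learners per boosted chain, `K` repeated fits inside each RENT, `Q`
#' bootstrap bags, and the nomination-frequency threshold `eta` (a feature
#' must be nominated in strictly more than `eta * Q` bags).  The full-scale
#' defaults are `N = 25`, `K = 200`, `Q = 150`, `eta = 0.5`; tests and
#' examples run at reduced scale.
#'
#' @param N maximum boosted learners per chain.
#' @param K repeated fits per RENT run.
#' @param Q bootstrap bags.
#' @param eta nomination-frequency threshold fraction in `(0, 1)`.
#' @param criteria a [rent_criteria()]; its `K` is kept in sync with `K`.
#' @param enet an [enet_config()].
#' @param seed RNG seed.
#' @return an object of class `bbrent_config`.
#' @export
bbrent_config <- function(N = 25L, K = 200L, Q = 150L, eta = 0.5,
                          criteria = rent_criteria(K = K),
                          enet = enet_config(), seed = 1L) {
  if (N < 1 || K < 1 || Q < 1) stop("N, K and Q must be >= 1")
  if (eta <= 0 || eta >= 1) stop("eta must lie in (0, 1)")
  criteria$K <- as.integer(K)
  structure(list(N = as.integer(N), K = as.integer(K), Q = as.integer(Q),
                 eta = eta, criteria = criteria, enet = enet,
                 seed = as.integer(seed)),
            class = "bbrent_config")
}

# Resolve reg_strength = "auto" by CV on the standardised full data.
resolve_lambda <- function(X, y, enet_cfg, seed = 1L) {
  if (!identical(enet_cfg$reg_strength, "auto")) return(enet_cfg$reg_strength)
  Xs <- scale(X)
  Xs[, !is.finite(colSums(Xs))] <- 0
  cv_reg_strength(Xs, y, l1_ratio = enet_cfg$l1_ratio, seed = seed)
}

#' Fit an AdaBoost-boosted chain of elastic nets
#'
#' Discrete two-class AdaBoost with elastic-net logistic weak learners:
#' each learner is fitted under the current sample weights, its thresholded
#' predictions give the weighted error `eps_m`, the boosting coefficient is
#' `0.5 * log((1 - eps_m) / eps_m)`, and the weights are multiplied by
#' `exp(+/- beta_m)` and renormalised.  The chain stops early when
#' `eps_m >= 0.5`, `eps_m == 0`, or `N` learners have been fitted.  If the
#' very first learner has `eps >= 0.5` the chain degenerates to that single
#' learner with unit weight and is flagged.
#'
#' @param X standardised predictor matrix.
#' @param y 0/1 response.
#' @param cfg an [enet_config()] with numeric `reg_strength`.
#' @param N maximum number of weak learners.
#' @return an object of class `boosted_enet` with `learners` (matrix of
#'   per-learner coefficients), `intercepts`, `boost_weights`, `errors`,
#'   `aggregated_coeffs` (boost-weight-weighted combination with weights
#'   normalised to sum 1), `aggregated_intercept` and `fallback`.
#' @export
fit_boosted_enet <- function(X, y, cfg = enet_config(reg_strength = 0.01),
                             N = 25L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (identical(cfg$reg_strength, "auto"))
    stop("reg_strength is \"auto\"; resolve it with cv_reg_strength() first")
  fit <- boosted_enet_cpp(X, y, cfg$reg_strength, cfg$l1_ratio,
                          as.integer(N), cfg$max_iter, cfg$tol)
  agg <- as.numeric(fit$aggregated_coeffs)
  names(agg) <- colnames(X)
  structure(list(learners = fit$learners, intercepts = fit$intercepts,
                 boost_weights = as.numeric(fit$boost_weights),
                 errors = as.numeric(fit$errors),
                 aggregated_coeffs = agg,
                 aggregated_intercept = fit$aggregated_intercept,
                 fallback = fit$fallback),
            class = "boosted_enet")
}

# Apply the three RENT criteria to a K x p matrix of coefficient vectors.
rent_apply_criteria <- function(coefmat, criteria) {
  K <- nrow(coefmat)
  nz <- coefmat != 0
  c1 <- colMeans(nz)
  npos <- colSums(coefmat > 0)
  nneg <- colSums(coefmat < 0)
  nnz <- npos + nneg
  c2 <- ifelse(nnz > 0, pmax(npos, nneg) / nnz, 1)
  m <- colMeans(coefmat)
  s <- apply(coefmat, 2, sd)
  tstat <- ifelse(s > 0, m / (s / sqrt(K)), ifelse(m == 0, 0, Inf))
  c3 <- 2 * pt(-abs(tstat), K - 1)
  c3[!is.finite(tstat)] <- 0
  selected <- c1 >= criteria$tau1 & c2 >= criteria$tau2 & c3 <= criteria$tau3
  list(c1 = c1, c2 = c2, c3 = c3, selected = selected)
}

new_selection_result <- function(selected, diagnostics, method) {
  structure(list(selected = selected, diagnostics = diagnostics,
                 method = method),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> method '%s': %d of %d features\n",
              x$method, length(x$selected), nrow(x$diagnostics)))
  if (length(x$selected)) cat(paste(" ", x$selected, collapse = "\n"), "\n")
  invisible(x)
}

#' Repeated elastic net (RENT) feature selection
#'
#' Draws `K` subsamples (without replacement, at the configured fraction),
#' fits an elastic net — or an AdaBoost-boosted chain of elastic nets when
#' `boosted = TRUE` — on each subsample's standardised predictors, and
#' keeps the features whose coefficients satisfy all three
#' [rent_criteria()].
#'
#' @param X predictor matrix (raw scale; each subsample is standardised
#'   internally).
#' @param y 0/1 response.
#' @param criteria a [rent_criteria()].
#' @param boosted use the boosted chain as the repeated learner.
#' @param enet_cfg an [enet_config()]; `"auto"` penalty strength is
#'   resolved once on the full data and reused across all K fits.
#' @param N maximum learners per boosted chain (ignored unless `boosted`).
#' @param seed RNG seed.
#' @return a `selection_result` with per-feature diagnostics `c1`
#'   (non-zero frequency), `c2` (sign stability) and `c3` (t-test p).
#' @export
rent_select <- function(X, y, criteria = rent_criteria(), boosted = FALSE,
                        enet_cfg = enet_config(), N = 25L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (criteria$K < 2) stop("K must be at least 2")
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("f", seq_len(ncol(X)))
  lambda <- resolve_lambda(X, y, enet_cfg, seed = seed)
  set.seed(derive_seed(seed, 11L))
  coefmat <- rent_coef_runs_cpp(X, y, lambda, enet_cfg$l1_ratio,
                                criteria$K, criteria$subsample_fraction,
                                boosted, as.integer(N),
                                enet_cfg$max_iter, enet_cfg$tol)
  cr <- rent_apply_criteria(coefmat, criteria)
  diagnostics <- data.frame(feature_id = ids, c1 = cr$c1, c2 = cr$c2,
                            c3 = cr$c3, stringsAsFactors = FALSE)
  new_selection_result(ids[cr$selected], diagnostics,
                       if (boosted) "boosted-rent" else "rent")
}

#' Bagged-boosted repeated elastic net (BB-RENT) feature selection
#'
#' The training data are bootstrapped `Q` times (with replacement, at the
#' original size); each bag is processed with the boosted RENT, yielding a
#' nominated feature set; features nominated in strictly more than
#' `eta * Q` bags are ultimately selected.  Setting `boosted = FALSE`
#' gives the bagged-RENT comparator.
#'
#' @param X predictor matrix.
#' @param y 0/1 response.
#' @param cfg a [bbrent_config()].
#' @param boosted whether each bag runs the boosted (default) or the plain
#'   RENT.
#' @return a `selection_result`; diagnostics carry the nomination count
#'   per feature plus the across-bag means of the RENT criteria.
#' @export
bb_rent <- function(X, y, cfg = bbrent_config(), boosted = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("f", seq_len(ncol(X)))
  n <- nrow(X)
  lambda <- resolve_lambda(X, y, cfg$enet, seed = cfg$seed)
  enet_cfg <- cfg$enet
  enet_cfg$reg_strength <- lambda
  set.seed(derive_seed(cfg$seed, 23L))
  counts <- numeric(ncol(X))
  c1s <- c2s <- c3s <- numeric(ncol(X))
  for (q in seq_len(cfg$Q)) {
    bag <- sample.int(n, n, replace = TRUE)
    if (length(unique(y[bag])) < 2) bag <- seq_len(n)  # degenerate bag guard
    coefmat <- rent_coef_runs_cpp(X[bag, , drop = FALSE], y[bag], lambda,
                                  enet_cfg$l1_ratio, cfg$criteria$K,
                                  cfg$criteria$subsample_fraction,
                                  boosted, cfg$N,
                                  enet_cfg$max_iter, enet_cfg$tol)
    cr <- rent_apply_criteria(coefmat, cfg$criteria)
    counts <- counts + cr$selected
    c1s <- c1s + cr$c1; c2s <- c2s + cr$c2; c3s <- c3s + cr$c3
  }
  selected <- counts > cfg$eta * cfg$Q  # strict: ties at eta*Q are excluded
  diagnostics <- data.frame(feature_id = ids, nomination_count = counts,
                            c1 = c1s / cfg$Q, c2 = c2s / cfg$Q,
                            c3 = c3s / cfg$Q, stringsAsFactors = FALSE)
  new_selection_result(ids[selected], diagnostics,
                       if (boosted) "bb-rent" else "bagged-rent")
}

#' Single elastic-net feature selection
#'
#' One elastic-net fit on the standardised full data (penalty strength by
#' internal cross-validation when `"auto"`); selects the features with
#' non-zero coefficients.
#'
#' @inheritParams rent_select
#' @return a `selection_result`.
#' @export
enet_select <- function(X, y, enet_cfg = enet_config(), seed = 1L) {
  X <- as.matrix(X)
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("f", seq_len(ncol(X)))
  lambda <- resolve_lambda(X, y, enet_cfg, seed = seed)
  cfg <- enet_cfg
  cfg$reg_strength <- lambda
  Xs <- scale(X)
  Xs[, !is.finite(colSums(Xs))] <- 0
  fit <- fit_elastic_net(Xs, y, cfg)
  nz <- fit$coefficients != 0
  diagnostics <- data.frame(feature_id = ids, coefficient = fit$coefficients,
                            stringsAsFactors = FALSE, row.names = NULL)
  new_selection_result(ids[nz], diagnostics, "enet")
}

#' Run one of the five selector variants
#'
#' Dispatcher over the five selection methods compared by the stability
#' experiment: a single elastic net, RENT, boosted RENT, bagged RENT and
#' BB-RENT.
#'
#' @param X predictor matrix with feature IDs as column names.
#' @param y 0/1 response.
#' @param method one of `"enet"`, `"rent"`, `"boosted-rent"`,
#'   `"bagged-rent"`, `"bb-rent"`.
#' @param cfg a [bbrent_config()] (supplies the criteria, the elastic-net
#'   configuration, `N`, `K`, `Q`, `eta` and the seed).
#' @param lambda optional pre-resolved penalty strength overriding the
#'   configuration (used to share one lambda across compared methods).
#' @return a `selection_result`.
#' @export
select_features <- function(X, y,
                            method = c("enet", "rent", "boosted-rent",
                                       "bagged-rent", "bb-rent"),
                            cfg = bbrent_config(), lambda = NULL) {
  method <- match.arg(method)
  enet_cfg <- cfg$enet
  if (!is.null(lambda)) enet_cfg$reg_strength <- lambda
  switch(method,
    "enet" = enet_select(X, y, enet_cfg, seed = cfg$seed),
    "rent" = rent_select(X, y, cfg$criteria, boosted = FALSE,
                         enet_cfg = enet_cfg, seed = cfg$seed),
    "boosted-rent" = rent_select(X, y, cfg$criteria, boosted = TRUE,
                                 enet_cfg = enet_cfg, N = cfg$N,
                                 seed = cfg$seed),
    "bagged-rent" = {
      cfg$enet <- enet_cfg
      bb_rent(X, y, cfg, boosted = FALSE)
    },
    "bb-rent" = {
      cfg$enet <- enet_cfg
      bb_rent(X, y, cfg, boosted = TRUE)
    })
}
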