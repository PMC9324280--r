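test_that("extreme regularisation shrinks every coefficient to zero", {
  d <- toy_design(1)
  fit <- fit_elastic_net(d$X, d$y, enet_config(0.5, reg_strength = 100))
  expect_true(all(fit$coefficients == 0))
  expect_equal(plogis(fit$intercept), mean(d$y), tolerance = 1e-6)
})

test_that("solver objective matches a generic convex optimiser", {
  # several toys, compared against Nelder-Mead on the identical penalised
  # loss; the solver must be at least as good to 1e-6
  cases <- list(list(seed = 1, l1 = 0.3, lam = 0.1),
                list(seed = 2, l1 = 1.0, lam = 0.05),
                list(seed = 3, l1 = 0.0, lam = 0.2),
                list(seed = 4, l1 = 0.7, lam = 0.02))
  for (cs in cases) {
    d <- toy_design(cs$seed, n = 8, p = 2)
    cfg <- enet_config(cs$l1, cs$lam, max_iter = 1000L, tol = 1e-10)
    fit <- fit_elastic_net(d$X, d$y, cfg)
    mine <- enet_objective(d$X, d$y, fit$coefficients, fit$intercept, cfg)
    oracle <- optim(rep(0, 3), function(par)
      enet_objective(d$X, d$y, par[1:2], par[3], cfg),
      method = "Nelder-Mead",
      control = list(maxit = 20000, reltol = 1e-14))$value
    expect_lt(mine - oracle, 1e-6)
  }
})

test_that("solver agrees with glmnet on the shared objective", {
  d <- toy_design(7, n = 150, p = 12,
                  beta = c(1.5, -1, 0.5, rep(0, 9)))
  cfg <- enet_config(0.5, 0.03, max_iter = 1000L, tol = 1e-9)
  fit <- fit_elastic_net(d$X, d$y, cfg)
  g <- glmnet::glmnet(d$X, d$y, family = "binomial", alpha = 0.5,
                      lambda = 0.03, standardize = FALSE, thresh = 1e-12)
  gb <- as.numeric(stats::coef(g))
  mine <- enet_objective(d$X, d$y, fit$coefficients, fit$intercept, cfg)
  theirs <- enet_objective(d$X, d$y, gb[-1], gb[1], cfg)
  expect_lt(abs(mine - theirs), 1e-7)
  expect_lt(max(abs(fit$coefficients - gb[-1])), 1e-4)
})

test_that("a separating feature gets the right coefficient sign", {
  set.seed(12)
  x <- c(rnorm(20, -2), rnorm(20, 2))
  X <- cbind(drop(scale(x)), drop(scale(rnorm(40))))
  colnames(X) <- c("sep", "noise")
  y <- rep(c(0, 1), each = 20)
  fit <- fit_elastic_net(X, y, enet_config(0.5, 0.01))
  expect_gt(fit$coefficients["sep"], 0)
  fit2 <- fit_elastic_net(-X, y, enet_config(0.5, 0.01))
  expect_lt(fit2$coefficients["sep"], 0)
})

test_that("weighted fits respect sample weights", {
  d <- toy_design(5, n = 60, p = 3)
  w <- ifelse(d$y == 1, 10, 1)
  fit <- fit_elastic_net(d$X, d$y, enet_config(0.5, 0.05), sample_weights = w)
  base <- fit_elastic_net(d$X, d$y, enet_config(0.5, 0.05))
  # up-weighting the positive class pushes the intercept up
  expect_gt(fit$intercept, base$intercept)
})

test_that("boosted chain obeys its stopping and identity rules", {
  # perfectly separable: first weak learner has zero error, chain length 1
  set.seed(3)
  x <- c(rnorm(15, -3), rnorm(15, 3))
  X <- cbind(f1 = scale(x))
  y <- rep(c(0, 1), each = 15)
  b <- fit_boosted_enet(X, y, enet_config(0.5, 0.01), N = 10)
  expect_equal(nrow(b$learners), 1)
  expect_false(b$fallback)

  # N = 1 reduces to the single elastic net
  d <- toy_design(9, n = 80, p = 4)
  b1 <- fit_boosted_enet(d$X, d$y, enet_config(0.5, 0.05), N = 1)
  single <- fit_elastic_net(d$X, d$y, enet_config(0.5, 0.05))
  expect_equal(unname(b1$aggregated_coeffs), unname(single$coefficients),
               tolerance = 1e-12)

  # hopeless labels: first learner has error >= 0.5, flagged fallback
  set.seed(4)
  Xn <- cbind(f1 = scale(rnorm(40)))
  yn <- rep(c(0, 1), 20)
  bf <- fit_boosted_enet(Xn, yn, enet_config(0.5, 10), N = 5)
  expect_true(bf$fallback)
  expect_equal(nrow(bf$learners), 1)
})

test_that("boosting concentrates on errors without degrading training fit", {
  set.seed(21)
  n <- 60
  X <- cbind(a = scale(rnorm(n)), b = scale(rnorm(n)))
  y <- as.numeric(X[, 1] + 0.5 * X[, 2] + rnorm(n, sd = 0.6) > 0)
  b <- fit_boosted_enet(X, y, enet_config(0.5, 0.08), N = 6)
  expect_gt(nrow(b$learners), 1)
  expect_true(all(b$errors < 0.5))
  # ensemble training error at full depth does not exceed the first
  # learner's own training error on the seeded toy
  score1 <- drop(X %*% b$learners[1, ]) + b$intercepts[1]
  err1 <- mean((score1 >= 0) != y)
  w <- b$boost_weights / sum(b$boost_weights)
  votes <- sapply(seq_len(nrow(b$learners)), function(m)
    ifelse(drop(X %*% b$learners[m, ]) + b$intercepts[m] >= 0, 1, -1))
  final <- as.numeric(votes %*% w > 0)
  expect_lte(mean(final != y), err1)
})

test_that("RENT criteria behave on trivial patterns", {
  cm <- rbind(c(0, 1, 1, -0.5), c(0, 2, 1, 0.5), c(0, 1.5, 1, -0.2),
              c(0, 1.2, 1, 0.1))
  cr <- bbrent:::rent_apply_criteria(cm, rent_criteria(K = 4))
  expect_false(cr$selected[1])  # all-zero: c1 = 0
  expect_true(cr$selected[2])   # always non-zero, same sign, big mean
  expect_equal(cr$c1, c(0, 1, 1, 1))
  expect_equal(cr$c2[4], 0.5)   # two positive, two negative
  expect_false(cr$selected[4])
})

test_that("RENT recovers a planted feature among nulls", {
  # scaled down from 100 seeds to 20; planted d = 1.5 among 50 nulls
  hits <- 0; null_sel <- 0
  for (s in 1:20) {
    co <- generate_cohort(synthetic_config(
      n_samples = 150, n_features = 51, n_informative = 1,
      effect_sizes = 1.5, block_structure = list(),
      replicate_noise_sd = 0, seed = 600 + s))
    X <- co$pair$primary$values
    res <- rent_select(X, co$labels, rent_criteria(K = 50), seed = s)
    hits <- hits + (co$truth$informative %in% res$selected)
    null_sel <- null_sel + length(setdiff(res$selected, co$truth$informative))
  }
  expect_gte(hits, 18)
  expect_lte(null_sel / 20, 2)
})

test_that("bagging layer: degenerate Q, strict eta ties, monotonicity", {
  co <- tiny_cohort(seed = 13, n = 100)
  X <- co$pair$primary$values
  cfg <- reduced_bbrent(seed = 2, K = 10L, Q = 1L)
  res <- bb_rent(X, co$labels, cfg)
  # Q = 1: selected iff nominated by the single bag (count 1 > 0.5)
  expect_setequal(res$selected,
                  res$diagnostics$feature_id[res$diagnostics$nomination_count == 1])

  cfg2 <- reduced_bbrent(seed = 2, K = 10L, Q = 10L)
  res2 <- bb_rent(X, co$labels, cfg2)
  counts <- res2$diagnostics$nomination_count
  # strict inequality: a count of exactly eta * Q never selects
  expect_false(any(counts[res2$diagnostics$feature_id %in% res2$selected] <=
                     cfg2$eta * cfg2$Q))
  # raising eta never grows the selected set
  sel_low <- res2$diagnostics$feature_id[counts > 0.3 * 10]
  sel_high <- res2$diagnostics$feature_id[counts > 0.8 * 10]
  expect_true(all(res2$selected %in% sel_low))
  expect_true(all(sel_high %in% res2$selected))
})

test_that("selectors are deterministic given seed, config and data", {
  co <- tiny_cohort(seed = 14, n = 80)
  X <- co$pair$primary$values
  cfg <- reduced_bbrent(seed = 31, K = 8L, Q = 5L, N = 3L)
  a <- bb_rent(X, co$labels, cfg)
  b <- bb_rent(X, co$labels, cfg)
  expect_identical(a$selected, b$selected)
  expect_identical(a$diagnostics, b$diagnostics)
  r1 <- rent_select(X, co$labels, rent_criteria(K = 10), seed = 5)
  r2 <- rent_select(X, co$labels, rent_criteria(K = 10), seed = 5)
  expect_identical(r1$diagnostics, r2$diagnostics)
})

test_that("all-noise data selects at most a stray feature", {
  # spec scale Q = 20, K = 30; seed count scaled down from 100 to 20
  sizes <- vapply(1:20, function(s) {
    co <- generate_cohort(synthetic_config(
      n_samples = 100, n_features = 30, n_informative = 0,
      effect_sizes = numeric(0), block_structure = list(),
      seed = 700 + s))
    length(bb_rent(co$pair$primary$values, co$labels,
                   reduced_bbrent(seed = s))$selected)
  }, 0)
  expect_gte(sum(sizes <= 1), 19)
})

test_that("the five selector variants run through the dispatcher", {
  co <- tiny_cohort(seed = 15, n = 80)
  X <- co$pair$primary$values
  cfg <- reduced_bbrent(seed = 3, K = 8L, Q = 5L, N = 3L)
  for (m in c("enet", "rent", "boosted-rent", "bagged-rent", "bb-rent")) {
    res <- select_features(X, co$labels, method = m, cfg = cfg)
    expect_s3_class(res, "selection_result")
    expect_identical(res$method, m)
    expect_true(all(res$selected %in% colnames(X)))
    expect_equal(nrow(res$diagnostics), ncol(X))
  }
})
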