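#' Configuration for the synthetic feature-table generator
#'
#' The generator emulates the statistical structure of a radiomic feature
#' table from a two-class imaging cohort: a few hundred features with
#' correlated blocks, a small planted informative subset (a couple of
#' strong "shape-like" effects plus weaker "texture-like" ones), a
#' replicate measurement with additive noise giving a controllable ICC,
#' and a covariate-shifted second cohort standing in for data from a
#' different scanner field strength.
#'
#' Defaults mirror the cohort the pipeline targets: 221 samples per class
#' (442 in total) and 422 features.  The signal profile is calibrated to
#' the selection behaviour observed on real radiomic tables: a small
#' stable core of strong, mutually independent "shape-like" features
#' (always selected), plus thin weak effects spread over highly
#' correlated "texture-like" blocks whose redundancy makes the elastic
#' net's choice of representative unstable — the main driver of
#' feature-selection instability this package is about.
#'
#' @param n_samples samples *per class*.
#' @param n_features total number of features (default 422).
#' @param n_informative number of planted informative features.
#' @param effect_sizes standardised mean differences (Cohen's d) of the
#'   informative features; recycled/truncated to `n_informative`.
#' @param block_structure list of `c(size, rho)` or `c(size, rho, effect)`
#'   triples describing correlated feature blocks realised after the
#'   independent informative features; `rho` in `[0, 1)` is the
#'   within-block correlation and `effect` (default 0) a standardised mean
#'   difference shared by every block member.  Weakly informative,
#'   mutually correlated blocks emulate redundant texture features, the
#'   main driver of feature-selection instability in radiomic tables.
#' @param replicate_noise_sd per-feature measurement-noise sd (scalar or
#'   length `n_features`); both delineations are independently noisy
#'   measurements of the same latent values, so a unit-variance latent
#'   feature has ICC `1 / (1 + sd^2)`.
#' @param shift numeric `c(scale, offset, noise_sd)` applied when
#'   generating the shifted second cohort.
#' @param skew if `TRUE`, values are exponentiated (log-normal on the
#'   latent scale) so the non-parametric branch of the univariate test is
#'   exercised; configured effect sizes then apply on the latent scale.
#' @param seed master seed; all sub-streams derive deterministically.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 221, n_features = 422,
                             n_informative = 3,
                             effect_sizes = c(1.2, 1.0, 0.7),
                             block_structure = c(
                               rep(list(c(30, 0.85, 0.25)), 2),
                               rep(list(c(30, 0.85, 0.20)), 2),
                               rep(list(c(30, 0.85, 0.15)), 2),
                               rep(list(c(30, 0.85, 0)), 2)),
                             replicate_noise_sd = 0.2,
                             shift = c(scale = 1.2, offset = 0.5, noise_sd = 0.3),
                             skew = FALSE, seed = 1) {
  if (n_samples < 2) stop("n_samples must be at least 2 per class")
  if (n_informative > n_features) stop("n_informative exceeds n_features")
  effect_sizes <- rep_len(as.numeric(effect_sizes),
                          max(n_informative, 1L))[seq_len(n_informative)]
  block_structure <- lapply(block_structure, function(b) {
    b <- as.numeric(b)
    if (length(b) == 2) b <- c(b, 0)
    if (length(b) != 3 || b[1] < 1 || b[2] < 0 || b[2] >= 1)
      stop("each block must be c(size >= 1, rho in [0, 1)[, effect])")
    b
  })
  if (n_informative + sum(vapply(block_structure, `[`, 0, 1)) > n_features)
    stop("informative features plus blocks exceed n_features")
  if (any(replicate_noise_sd < 0)) stop("replicate_noise_sd must be >= 0")
  if (length(shift) != 3) stop("shift must be c(scale, offset, noise_sd)")
  if (shift[3] < 0) stop("shift noise sd must be >= 0")
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_sizes = effect_sizes,
                 block_structure = block_structure,
                 replicate_noise_sd = replicate_noise_sd,
                 shift = setNames(as.numeric(shift),
                                  c("scale", "offset", "noise_sd")),
                 skew = isTRUE(skew), seed = as.integer(seed)),
            class = "synthetic_config")
}

# Feature IDs: informative features are tagged shape-like (d >= 1) or
# texture-like (d < 1); block members and free features get their own
# filter/class components so IDs look like real radiomic identifiers.
synthetic_feature_ids <- function(config) {
  ids <- character(config$n_features)
  k <- 0L
  if (config$n_informative > 0) {
    cls <- ifelse(config$effect_sizes >= 1, "shape", "texture")
    ids[seq_len(config$n_informative)] <-
      make_feature_id("synthetic", cls,
                      sprintf("Informative%02d", seq_len(config$n_informative)))
    k <- config$n_informative
  }
  for (b in seq_along(config$block_structure)) {
    sz <- config$block_structure[[b]][1]
    ids[k + seq_len(sz)] <-
      make_feature_id("synthetic", "texture",
                      sprintf("Block%02dMember%02d", b, seq_len(sz)))
    k <- k + sz
  }
  nfree <- config$n_features - k
  if (nfree > 0)
    ids[k + seq_len(nfree)] <-
      make_feature_id("synthetic", "firstorder",
                      sprintf("Noise%03d", seq_len(nfree)))
  ids
}

# One latent cohort draw (before skew transform): informative features are
# independent unit-variance normals with a per-class mean shift equal to
# the configured Cohen's d; block features share a common factor giving
# within-block correlation rho; remaining features are independent noise.
synthetic_draw <- function(config, n_per_class) {
  n <- 2L * n_per_class
  d <- config$n_features
  X <- matrix(rnorm(n * d), n, d)
  k <- config$n_informative
  for (b in config$block_structure) {
    sz <- b[1]; rho <- b[2]
    z <- rnorm(n)
    cols <- k + seq_len(sz)
    X[, cols] <- sqrt(rho) * z + sqrt(1 - rho) * X[, cols]
    k <- k + sz
  }
  labels <- rep(c(0L, 1L), each = n_per_class)
  if (config$n_informative > 0) {
    for (j in seq_len(config$n_informative))
      X[labels == 1L, j] <- X[labels == 1L, j] + config$effect_sizes[j]
  }
  k <- config$n_informative
  for (b in config$block_structure) {
    cols <- k + seq_len(b[1])
    if (b[3] != 0) X[labels == 1L, cols] <- X[labels == 1L, cols] + b[3]
    k <- k + b[1]
  }
  list(X = X, labels = labels)
}

#' Generate a synthetic two-class cohort with a replicate measurement
#'
#' Both tables are equally noisy measurements of the same latent feature
#' values: `primary = latent + e1`, `replicate = latent + e2` with
#' independent `e ~ N(0, replicate_noise_sd^2)` per feature, so the
#' implied ICC of a unit-variance latent feature is exactly
#' `1 / (1 + sd^2)`.  Configured effect sizes apply on the latent scale;
#' the observable standardised difference shrinks by the factor
#' `1 / sqrt(1 + sd^2)` (2% at the default sd of 0.2).
#'
#' @param config a [synthetic_config()].
#' @return a list with elements `pair` (a [replicate_pair()]; both tables
#'   carry the labels), `labels`, and `truth` (informative feature IDs and
#'   their configured effect sizes).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, 1L))
  draw <- synthetic_draw(config, config$n_samples)
  ids <- synthetic_feature_ids(config)
  noise_sd <- rep_len(config$replicate_noise_sd, config$n_features)
  n <- nrow(draw$X)
  P <- draw$X + matrix(rnorm(n * config$n_features), n) *
    rep(noise_sd, each = n)
  R <- draw$X + matrix(rnorm(n * config$n_features), n) *
    rep(noise_sd, each = n)
  draw$X <- P
  if (config$skew) {
    draw$X <- exp(draw$X)
    R <- exp(R)
  }
  sample_ids <- sprintf("S%04d", seq_len(n))
  primary <- feature_table(draw$X, sample_ids, ids, labels = draw$labels,
                           cohort_tag = "synthetic-primary")
  replicate <- feature_table(R, sample_ids, ids, labels = draw$labels,
                             cohort_tag = "synthetic-replicate")
  weak <- character(0)
  k <- config$n_informative
  for (b in config$block_structure) {
    if (b[3] != 0) weak <- c(weak, ids[k + seq_len(b[1])])
    k <- k + b[1]
  }
  truth <- list(informative = ids[seq_len(config$n_informative)],
                effect_sizes = config$effect_sizes,
                weak_informative = weak)
  list(pair = replicate_pair(primary, replicate), labels = draw$labels,
       truth = truth)
}

#' Generate a covariate-shifted second cohort
#'
#' Draws a fresh cohort with the same feature IDs and generative class
#' effects as [generate_cohort()] would, then applies the configured
#' affine shift plus extra measurement noise: `scale * x + offset +
#' N(0, noise_sd^2)`.  This emulates testing on data acquired under a
#' different protocol (e.g. a different scanner field strength).
#'
#' @param config a [synthetic_config()].
#' @param base_seed seed for the shifted draw; defaults to a sub-stream of
#'   `config$seed` distinct from the primary cohort's.
#' @return a labelled [feature_table()].
#' @export
generate_shifted_cohort <- function(config, base_seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(base_seed)) base_seed <- derive_seed(config$seed, 2L)
  set.seed(base_seed)
  draw <- synthetic_draw(config, config$n_samples)
  s <- config$shift
  n <- nrow(draw$X)
  noise_sd <- rep_len(config$replicate_noise_sd, config$n_features)
  meas <- draw$X + matrix(rnorm(n * config$n_features), n) *
    rep(noise_sd, each = n)
  X <- s[["scale"]] * meas + s[["offset"]] +
    matrix(rnorm(n * config$n_features, sd = s[["noise_sd"]]), n)
  if (config$skew) X <- exp(X)
  feature_table(X, sprintf("T%04d", seq_len(n)),
                synthetic_feature_ids(config), labels = draw$labels,
                cohort_tag = "synthetic-shifted")
}
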