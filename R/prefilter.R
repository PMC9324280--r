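#' Configuration for preliminary feature filtering
#'
#' Stage one of feature selection keeps a feature only if (i) it is not
#' (near-)constant, (ii) it is robust to re-delineation, i.e. the ICC
#' between the two replicate measurements is at least `icc_min` with the
#' associated F-test p-value at most `icc_p_max`, and (iii) it shows a
#' univariate association with the class label at `univariate_p_max`.
#' Exclusion thresholds are applied as printed: a feature is *excluded*
#' when ICC < `icc_min` or p > the cap, so boundary values are kept.
#'
#' @param icc_min minimum ICC (default 0.9).
#' @param icc_p_max maximum ICC F-test p-value (default 0.05).
#' @param univariate_p_max maximum univariate test p-value (default 0.05).
#' @param normality_alpha Shapiro-Wilk level deciding between the t-test
#'   and the Mann-Whitney U-test (default 0.05).
#' @param variance_min variance threshold; the default 0 drops only
#'   constant features.
#' @param icc_form `"agreement"` (two-way mixed-effects, single
#'   measurement, absolute agreement; the recommended form for
#'   intra-observer reliability) or `"consistency"`.
#' @param p_adjust multiplicity correction for the univariate p-values
#'   passed to [stats::p.adjust()]; `"none"` (the default) applies the raw
#'   per-feature threshold.
#' @return an object of class `prefilter_config`.
#' @export
prefilter_config <- function(icc_min = 0.9, icc_p_max = 0.05,
                             univariate_p_max = 0.05,
                             normality_alpha = 0.05, variance_min = 0,
                             icc_form = c("agreement", "consistency"),
                             p_adjust = "none") {
  for (v in c(icc_min, icc_p_max, univariate_p_max, normality_alpha))
    if (v < 0 || v > 1) stop("prefilter thresholds must lie in [0, 1]")
  if (variance_min < 0) stop("variance_min must be >= 0")
  structure(list(icc_min = icc_min, icc_p_max = icc_p_max,
                 univariate_p_max = univariate_p_max,
                 normality_alpha = normality_alpha,
                 variance_min = variance_min,
                 icc_form = match.arg(icc_form),
                 p_adjust = p_adjust),
            class = "prefilter_config")
}

#' Variance filter
#'
#' @param table a [feature_table()].
#' @param variance_min a feature passes iff its sample variance is
#'   strictly greater than this.
#' @return character vector of passing feature IDs.
#' @export
variance_filter <- function(table, variance_min = 0) {
  stopifnot(inherits(table, "feature_table"))
  v <- apply(table$values, 2, var)
  table$feature_ids[v > variance_min]
}

#' Intraclass correlation between two replicate measurements
#'
#' Two-way mixed-effects, single-measurement ICC from the two-way ANOVA
#' mean squares of an n subjects x 2 raters layout.  The default
#' absolute-agreement form is
#' \deqn{ICC = (MS_R - MS_E) / (MS_R + MS_E + (2/n)(MS_C - MS_E))}
#' and the p-value comes from the F-test of no subject effect,
#' `F = MS_R / MS_E` on `(n - 1, n - 1)` degrees of freedom.
#'
#' @param x,y numeric vectors of paired measurements (length >= 3).
#' @param form `"agreement"` or `"consistency"`.
#' @return list with `icc` and `p`.
#' @export
icc_agreement <- function(x, y, form = c("agreement", "consistency")) {
  form <- match.arg(form)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired samples")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  res <- icc_matrix(cbind(x), cbind(y), form)
  if (is.na(res$icc[1]))
    stop("zero total variance: uninformative feature; run variance_filter first")
  list(icc = unname(res$icc[1]), p = unname(res$p[1]))
}

# Vectorised ICC over the columns of two aligned matrices.  Returns NA for
# columns with zero total variance.  k = 2 raters throughout.
icc_matrix <- function(X, Y, form = "agreement") {
  n <- nrow(X); k <- 2
  subj_mean <- (X + Y) / 2                  # n x p
  rater_mean <- rbind(colMeans(X), colMeans(Y))  # 2 x p
  grand <- colMeans(subj_mean)              # p
  ssr <- k * colSums(sweep(subj_mean, 2, grand)^2)        # subjects
  ssc <- n * colSums(sweep(rater_mean, 2, grand)^2)       # raters
  sst <- colSums(sweep(X, 2, grand)^2) + colSums(sweep(Y, 2, grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- pmax(sse / ((n - 1) * (k - 1)), 0)
  icc <- if (form == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  fstat <- msr / mse
  p <- pf(fstat, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  degenerate <- sst <= 1e-12 * pmax(abs(grand)^2, 1)
  icc[degenerate] <- NA_real_
  p[degenerate] <- NA_real_
  list(icc = icc, p = p)
}

#' Univariate two-group association test
#'
#' Uses a Shapiro-Wilk normality gate in each class at `normality_alpha`:
#' when both classes look normal, a two-sample Student t-test; otherwise a
#' Mann-Whitney U-test with normal approximation and tie correction.
#'
#' @param values numeric feature vector.
#' @param labels 0/1 class labels.
#' @param normality_alpha level of the normality gate.
#' @return list with `p` and `test_used` (`"t"` or `"mann-whitney"`).
#' @export
univariate_test <- function(values, labels, normality_alpha = 0.05) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  g0 <- values[labels == 0L]
  g1 <- values[labels == 1L]
  if (length(g0) < 3 || length(g1) < 3)
    stop("both classes must be present with at least 3 samples each")
  normal <- function(g) {
    if (length(unique(g)) < 3) return(FALSE)
    if (length(g) > 5000) g <- g[seq(1, length(g), length.out = 5000)]
    shapiro.test(g)$p.value > normality_alpha
  }
  if (normal(g0) && normal(g1)) {
    p <- t.test(g0, g1, var.equal = TRUE)$p.value
    list(p = p, test_used = "t")
  } else {
    p <- suppressWarnings(
      wilcox.test(g0, g1, exact = FALSE, correct = TRUE)$p.value)
    list(p = p, test_used = "mann-whitney")
  }
}

#' Run the full preliminary filter
#'
#' Applies the variance filter on the primary table, the ICC gate across
#' the replicate pair, and the univariate association test on the primary
#' table.  The overall pass flag is the pure conjunction of the three
#' gates, so the evaluation order is immaterial; every feature receives a
#' full diagnostic row regardless of where it fails.
#'
#' @param pair a [replicate_pair()].
#' @param labels 0/1 labels aligned with the pair's samples (defaults to
#'   the primary table's labels).
#' @param config a [prefilter_config()].
#' @return a `prefilter_report`: a data frame with one row per feature and
#'   columns `feature_id`, `variance`, `variance_pass`, `icc`, `icc_p`,
#'   `test_used`, `univariate_p`, `overall_pass`.
#' @export
run_prefilter <- function(pair, labels = pair$primary$labels,
                          config = prefilter_config()) {
  stopifnot(inherits(pair, "replicate_pair"),
            inherits(config, "prefilter_config"))
  if (is.null(labels)) stop("labels are required for the univariate test")
  labels <- as.integer(labels)
  X <- pair$primary$values
  ids <- pair$primary$feature_ids
  v <- apply(X, 2, var)
  variance_pass <- v > config$variance_min
  icc <- icc_matrix(X, pair$replicate$values, config$icc_form)
  uni <- lapply(seq_along(ids), function(j) {
    if (v[j] <= 0) return(list(p = NA_real_, test_used = NA_character_))
    univariate_test(X[, j], labels, config$normality_alpha)
  })
  up <- vapply(uni, `[[`, 0, "p")
  up_adj <- if (identical(config$p_adjust, "none")) up else
    stats::p.adjust(up, method = config$p_adjust)
  icc_pass <- !is.na(icc$icc) & icc$icc >= config$icc_min &
    icc$p <= config$icc_p_max
  uni_pass <- !is.na(up_adj) & up_adj <= config$univariate_p_max
  report <- data.frame(
    feature_id = ids, variance = unname(v),
    variance_pass = unname(variance_pass),
    icc = unname(icc$icc), icc_p = unname(icc$p),
    test_used = vapply(uni, `[[`, "", "test_used"),
    univariate_p = unname(up_adj),
    overall_pass = unname(variance_pass & icc_pass & uni_pass),
    stringsAsFactors = FALSE)
  class(report) <- c("prefilter_report", "data.frame")
  report
}

#' Feature IDs passing a prefilter report
#'
#' @param report a [run_prefilter()] result.
#' @return character vector of passing feature IDs.
#' @export
prefilter_passing <- function(report) {
  report$feature_id[report$overall_pass]
}
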