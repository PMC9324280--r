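#' Fit Z-score normalisation parameters
#'
#' @param X numeric matrix (samples x features).
#' @return an object of class `zscore_params` with per-feature `means` and
#'   `sds` (sample standard deviation, strictly positive).
#' @export
zscore_fit <- function(X) {
  X <- as.matrix(X)
  means <- colMeans(X)
  sds <- apply(X, 2, sd)
  if (any(sds <= 0 | !is.finite(sds))) {
    bad <- colnames(X)[sds <= 0 | !is.finite(sds)]
    if (is.null(bad)) bad <- which(sds <= 0 | !is.finite(sds))
    stop("zero-variance feature(s): ", paste(bad, collapse = ", "),
         "; run variance_filter() first")
  }
  structure(list(means = means, sds = sds), class = "zscore_params")
}

#' Apply Z-score normalisation
#'
#' @param X numeric matrix with the same columns (in order) the parameters
#'   were fitted on.
#' @param params a [zscore_fit()] result.
#' @return the standardised matrix.
#' @export
zscore_apply <- function(X, params) {
  stopifnot(inherits(params, "zscore_params"))
  X <- as.matrix(X)
  if (ncol(X) != length(params$means))
    stop("column count does not match fitted z-score parameters")
  sweep(sweep(X, 2, params$means, "-"), 2, params$sds, "/")
}
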