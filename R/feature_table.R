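#' Construct a feature table
#'
#' The universal currency of the pipeline: a samples x features matrix of
#' real-valued radiomic features together with sample identifiers, feature
#' identifiers, an optional binary label vector (1 = positive class, e.g.
#' carcinoma; 0 = negative class, e.g. benign hyperplasia) and a free-text
#' cohort tag.
#'
#' @param values numeric matrix, one row per sample, one column per feature.
#' @param sample_ids character vector of unique sample identifiers.
#' @param feature_ids character vector of unique feature identifiers.
#'   Radiomic feature identifiers conventionally take the form
#'   `"imaging-filter|feature-class|feature-name"`, see [make_feature_id()].
#' @param labels optional integer/numeric vector of 0/1 class labels aligned
#'   with `sample_ids`.
#' @param cohort_tag free-text tag (e.g. `"train3T"`).
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, sample_ids = rownames(values),
                          feature_ids = colnames(values), labels = NULL,
                          cohort_tag = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values))
    stop("length(sample_ids) must equal nrow(values)")
  if (length(feature_ids) != ncol(values))
    stop("length(feature_ids) must equal ncol(values)")
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicate sample IDs: ", paste(dup, collapse = ", "))
  dup <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup))
    stop("duplicate feature IDs: ", paste(dup, collapse = ", "))
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("missing or non-finite value at sample '%s', feature '%s'",
                 sample_ids[bad[1]], feature_ids[bad[2]]))
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != length(sample_ids))
      stop("labels must align with sample_ids")
    if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
      stop("labels must contain only 0 and 1")
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 feature_ids = feature_ids, labels = labels,
                 cohort_tag = as.character(cohort_tag)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features%s%s\n",
              nrow(x$values), ncol(x$values),
              if (!is.null(x$labels))
                sprintf(", labels (%d positive)", sum(x$labels)) else "",
              if (nzchar(x$cohort_tag))
                sprintf(", cohort '%s'", x$cohort_tag) else ""))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Subset a feature table by samples and/or features
#'
#' @param x a `feature_table`.
#' @param samples sample indices or IDs (default all).
#' @param features feature indices or IDs (default all).
#' @return a `feature_table`.
#' @export
ft_subset <- function(x, samples = NULL, features = NULL) {
  stopifnot(inherits(x, "feature_table"))
  si <- if (is.null(samples)) seq_along(x$sample_ids) else samples
  fi <- if (is.null(features)) seq_along(x$feature_ids) else features
  if (is.character(si)) si <- match(si, x$sample_ids)
  if (is.character(fi)) fi <- match(fi, x$feature_ids)
  if (anyNA(si)) stop("unknown sample ID in subset")
  if (anyNA(fi)) stop("unknown feature ID in subset")
  feature_table(x$values[si, fi, drop = FALSE],
                x$sample_ids[si], x$feature_ids[fi],
                labels = if (!is.null(x$labels)) x$labels[si],
                cohort_tag = x$cohort_tag)
}

#' Compose a radiomic feature identifier
#'
#' Radiomic features are conventionally identified by the imaging filter,
#' the feature class and the feature name joined by `"|"`, e.g.
#' `"original|shape|SurfaceVolumeRatio"`.
#'
#' @param filter,class,name components of the identifier.
#' @return character vector of identifiers.
#' @export
make_feature_id <- function(filter, class, name) {
  paste(filter, class, name, sep = "|")
}

#' Read a feature table from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row of feature IDs
#' and the sample ID in the first column.  Missing or non-numeric cells are
#' a hard error (the loader rejects rather than imputes).
#'
#' @param path file path.
#' @param label_column name of the 0/1 label column, or `NULL` if the table
#'   is unlabelled.
#' @param cohort_tag free-text tag stored on the result.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, label_column = NULL, cohort_tag = "") {
  df <- read.csv(path, check.names = FALSE, colClasses = "character",
                 fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop("feature table CSV needs a sample-ID column plus features")
  sample_ids <- df[[1]]
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicate sample IDs in ", path, ": ", paste(dup, collapse = ", "))
  labels <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(df))
      stop("label column '", label_column, "' not found in ", path)
    labels <- suppressWarnings(as.numeric(df[[label_column]]))
    df[[label_column]] <- NULL
  }
  feature_ids <- names(df)[-1]
  values <- matrix(NA_real_, nrow(df), length(feature_ids))
  for (j in seq_along(feature_ids)) {
    col <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(col) & !is.na(df[[j + 1]]) | is.na(df[[j + 1]]))
    if (length(bad))
      stop(sprintf("non-numeric or missing cell at sample '%s', feature '%s' in %s",
                   sample_ids[bad[1]], feature_ids[j], path))
    values[, j] <- col
  }
  feature_table(values, sample_ids, feature_ids, labels = labels,
                cohort_tag = cohort_tag)
}

#' Write a feature table to CSV
#'
#' Inverse of [read_feature_table()]: values are written as full-precision
#' decimal text so that a read/write round trip is the identity to better
#' than 1e-12.
#'
#' @param x a `feature_table`.
#' @param path output file path.
#' @param label_column name under which to store labels (only used when the
#'   table carries labels).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, label_column = "label") {
  stopifnot(inherits(x, "feature_table"))
  df <- data.frame(sample_id = x$sample_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(x$labels)) df[[label_column]] <- x$labels
  vals <- as.data.frame(x$values, check.names = FALSE)
  rownames(vals) <- NULL
  df <- cbind(df, vals)
  write.csv(df, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Pair a primary and a replicate feature table
#'
#' The replicate table comes from a repeated delineation of the same
#' lesions: identical sample and feature IDs in identical order, so that
#' per-feature agreement (ICC) can be assessed.
#'
#' @param primary,replicate `feature_table`s with identical IDs.
#' @return an object of class `replicate_pair`.
#' @export
replicate_pair <- function(primary, replicate) {
  stopifnot(inherits(primary, "feature_table"),
            inherits(replicate, "feature_table"))
  if (!identical(primary$sample_ids, replicate$sample_ids))
    stop("primary and replicate sample IDs differ")
  if (!identical(primary$feature_ids, replicate$feature_ids))
    stop("primary and replicate feature IDs differ")
  structure(list(primary = primary, replicate = replicate),
            class = "replicate_pair")
}

#' @export
print.replicate_pair <- function(x, ...) {
  cat(sprintf("<replicate_pair> %d samples x %d features\n",
              nrow(x$primary$values), ncol(x$primary$values)))
  invisible(x)
}

#' Subset both tables of a replicate pair
#'
#' @inheritParams ft_subset
#' @param x a `replicate_pair`.
#' @return a `replicate_pair`.
#' @export
rp_subset <- function(x, samples = NULL, features = NULL) {
  stopifnot(inherits(x, "replicate_pair"))
  replicate_pair(ft_subset(x$primary, samples, features),
                 ft_subset(x$replicate, samples, features))
}
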