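ENSEMBLE_SCHEMA_VERSION <- "1.0"

#' Serialize an ensemble model to JSON
#'
#' Writes a human-diffable JSON record with an explicit schema version.
#' Numbers are written as full-precision decimal text so a round trip
#' preserves coefficients, intercepts, thresholds and weights exactly.
#'
#' @param model an [build_ensemble()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
serialize_ensemble <- function(model, path) {
  stopifnot(inherits(model, "ensemble_model"))
  payload <- list(
    schema_version = ENSEMBLE_SCHEMA_VERSION,
    type = "ensemble_model",
    decision_threshold = model$decision_threshold,
    provenance = model$provenance,
    weights = as.numeric(model$weights),
    folds = lapply(model$folds, function(f) list(
      feature_ids = as.list(f$feature_ids),
      coefficients = as.numeric(f$coefficients),
      intercept = f$intercept,
      youden_threshold = f$youden_threshold,
      zscore = list(means = as.numeric(f$zscore$means),
                    sds = as.numeric(f$zscore$sds)))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Deserialize an ensemble model from JSON
#'
#' @param path a file written by [serialize_ensemble()].
#' @return an `ensemble_model`.
#' @export
deserialize_ensemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (field in c("schema_version", "decision_threshold", "weights", "folds"))
    if (is.null(obj[[field]]))
      stop("ensemble model file is missing field '", field, "'")
  if (!identical(obj$schema_version, ENSEMBLE_SCHEMA_VERSION))
    stop("unsupported ensemble schema version: ", obj$schema_version)
  folds <- lapply(seq_along(obj$folds), function(i) {
    f <- obj$folds[[i]]
    for (field in c("feature_ids", "coefficients", "intercept",
                    "youden_threshold", "zscore"))
      if (is.null(f[[field]]))
        stop(sprintf("fold %d is missing field '%s'", i, field))
    for (field in c("means", "sds"))
      if (is.null(f$zscore[[field]]))
        stop(sprintf("fold %d zscore is missing field '%s'", i, field))
    list(feature_ids = vapply(f$feature_ids, as.character, ""),
         coefficients = vapply(f$coefficients, as.numeric, 0),
         intercept = as.numeric(f$intercept),
         youden_threshold = as.numeric(f$youden_threshold),
         zscore = list(means = vapply(f$zscore$means, as.numeric, 0),
                       sds = vapply(f$zscore$sds, as.numeric, 0)))
  })
  model <- structure(list(folds = folds,
                          weights = vapply(obj$weights, as.numeric, 0),
                          decision_threshold = as.numeric(obj$decision_threshold),
                          provenance = if (is.null(obj$provenance)) ""
                            else obj$provenance),
                     class = "ensemble_model")
  model
}

#' Load the packaged nasopharyngeal-carcinoma ensemble fixture
#'
#' A published five-fold linear-SVR ensemble for discriminating early
#' nasopharyngeal carcinoma from benign hyperplasia on T2-weighted
#' fat-suppressed MRI, distributed with the package as a worked example
#' and serialisation fixture: 17 distinct radiomic features across the
#' five fold models, per-fold intercepts, and reciprocal ensemble weights
#' normalising the decision threshold to 1.  The original per-feature
#' standardisation constants are not distributed, so the fixture carries
#' placeholder Z-score parameters (mean 0, sd 1): scores on real feature
#' values are therefore not reproducible from this fixture, but all
#' structural and arithmetic properties of the ensemble are.
#'
#' @return an `ensemble_model`.
#' @export
npc_ensemble_fixture <- function() {
  deserialize_ensemble(system.file("extdata", "npc_ensemble_model.json",
                                   package = "bbrent", mustWork = TRUE))
}
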