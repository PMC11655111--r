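## Tabular export interfaces: per-epoch feature tables as CSV with a
## JSON sidecar schema, and the feature-selection artefacts (explained
## variance, retained features, dendrogram) in portable formats.

#' Write a feature table as CSV with a JSON schema sidecar
#'
#' One row per epoch (subject_id, epoch, start_s, label, then one column
#' per feature, in registry order); the sidecar records the registry id
#' and feature order.
#'
#' @param features a \linkS4class{PSGFeatureSet}.
#' @param path output CSV path; the sidecar is written to
#'   \code{paste0(path, ".schema.json")}.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(features, path) {
  stopifnot(is(features, "PSGFeatureSet"))
  cd <- SummarizedExperiment::colData(features)
  tab <- cbind(data.frame(subject_id = cd$subject_id, epoch = cd$epoch,
                          start_s = cd$start_s, label = cd$label),
               as.data.frame(featureMatrix(features)))
  utils::write.csv(tab, path, row.names = FALSE)
  schema <- list(
    registry_id = S4Vectors::metadata(features)$registry_id,
    features = rownames(features),
    signals = as.character(SummarizedExperiment::rowData(features)$signal),
    n_epochs = ncol(features))
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write feature-selection artefacts
#'
#' Emits the explained-variance table (CSV), the retained-feature list
#' (JSON) and the class dendrogram (Newick) into a directory.
#'
#' @param selection a \linkS4class{PCASelectionResult}.
#' @param dendrogram a \linkS4class{ClassDendrogram}, or NULL to skip.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeSelectionOutputs <- function(selection, dendrogram = NULL, dir) {
  stopifnot(is(selection, "PCASelectionResult"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(
    data.frame(component = seq_along(selection@explained),
               explained = selection@explained,
               cumulative = selection@cumulative),
    file.path(dir, "explained_variance.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_pcs_used = selection@nPCsUsed,
         retained = selection@retained),
    file.path(dir, "retained_features.json"), auto_unbox = TRUE,
    pretty = TRUE)
  if (!is.null(dendrogram))
    writeLines(dendrogramNewick(dendrogram),
               file.path(dir, "class_dendrogram.nwk"))
  invisible(dir)
}

#' Write a per-family metrics report as CSV
#'
#' @param reports named list of \linkS4class{MetricsReport} (as returned
#'   in \code{evaluateCase()$reports}).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeMetricsReport <- function(reports, path) {
  rows <- do.call(rbind, lapply(names(reports), function(f) {
    s <- metricsSummary(reports[[f]])
    cbind(family = f, s)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
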