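#' Accessors for psgApnea classes
#'
#' Small accessor family: channel series, planted events, hypnogram and
#' detachment intervals of a \linkS4class{PSGRecording}; the epoch index of
#' an \linkS4class{EpochSet}; definitions of a \linkS4class{FeatureRegistry};
#' slots of selection results and metric reports.
#'
#' @param x,object an object of the documented class.
#' @param name channel name for \code{psgChannel}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("psgChannel", function(x, name) standardGeneric("psgChannel"))
#' @rdname accessors
#' @export
setGeneric("psgEvents", function(x) standardGeneric("psgEvents"))
#' @rdname accessors
#' @export
setGeneric("hypnogram", function(x) standardGeneric("hypnogram"))
#' @rdname accessors
#' @export
setGeneric("detachments", function(x) standardGeneric("detachments"))
#' @rdname accessors
#' @export
setGeneric("epochIndex", function(x) standardGeneric("epochIndex"))
#' @rdname accessors
#' @export
setGeneric("registryDefs", function(x) standardGeneric("registryDefs"))
#' @rdname accessors
#' @export
setGeneric("retainedFeatures", function(x) standardGeneric("retainedFeatures"))
#' @rdname accessors
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))
#' @rdname accessors
#' @export
setGeneric("metricsSummary", function(x) standardGeneric("metricsSummary"))

#' @rdname accessors
#' @export
setMethod("psgChannel", "PSGRecording", function(x, name) {
  if (!name %in% names(x@channels))
    stop("no channel '", name, "' in recording ", x@subject_id)
  x@channels[[name]]
})
#' @rdname accessors
#' @export
setMethod("psgEvents", "PSGRecording", function(x) x@events)
#' @rdname accessors
#' @export
setMethod("hypnogram", "PSGRecording", function(x) x@hypnogram)
#' @rdname accessors
#' @export
setMethod("detachments", "PSGRecording", function(x) x@detachments)
#' @rdname accessors
#' @export
setMethod("epochIndex", "EpochSet", function(x) x@index)
#' @rdname accessors
#' @export
setMethod("registryDefs", "FeatureRegistry", function(x) x@defs)
#' @rdname accessors
#' @export
setMethod("retainedFeatures", "PCASelectionResult", function(x) x@retained)
#' @rdname accessors
#' @export
setMethod("explainedVariance", "PCASelectionResult", function(x) x@explained)
#' @rdname accessors
#' @export
setMethod("metricsSummary", "MetricsReport", function(x) x@summary)

setMethod("show", "PSGRecording", function(object) {
  n <- length(object@channels[[1]])
  cat("PSGRecording '", object@subject_id, "': ",
      sprintf("%.2f h", n / object@fs / 3600), " at ", object@fs, " Hz, ",
      length(object@channels), " channels, ", nrow(object@events),
      " events (", paste(names(table(object@events$class)), collapse = "/"),
      "), ", sum(object@hypnogram), " wake epochs\n", sep = "")
})

setMethod("show", "EpochSet", function(object) {
  idx <- object@index
  cat("EpochSet: ", nrow(idx), " epochs of 30 s (",
      sum(idx$excluded), " excluded)\n", sep = "")
  if (any(!is.na(idx$label))) {
    tb <- table(idx$label[!idx$excluded])
    cat("  labels:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  }
})

setMethod("show", "FeatureRegistry", function(object) {
  cat("FeatureRegistry '", object@registry_id, "': ", nrow(object@defs),
      " features\n  by signal: ", sep = "")
  tb <- table(object@defs$signal)
  cat(paste(names(tb), tb, sep = "=", collapse = " "), "\n")
})

setMethod("show", "PCASelectionResult", function(object) {
  cat("PCASelectionResult: ", ncol(object@loadings), " components, ",
      object@nPCsUsed, " used (cumulative variance ",
      sprintf("%.1f%%", 100 * object@cumulative[object@nPCsUsed]), "), ",
      length(object@retained), " features retained\n", sep = "")
})

setMethod("show", "ClassDendrogram", function(object) {
  cat("ClassDendrogram over {",
      paste(object@hclust$labels, collapse = ", "), "}",
      if (!is.na(object@wilks)) sprintf("; Wilks' lambda = %.4g", object@wilks),
      "\n", sep = "")
})

setMethod("show", "MetricsReport", function(object) {
  s <- object@summary
  cat("MetricsReport over ", nrow(object@per_repeat), " repeats:\n", sep = "")
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-5s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
})
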