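## Cohort-level driver: generate each subject's night, segment, exclude,
## label and extract features, discarding the raw signals subject by
## subject so arbitrarily large cohorts fit in memory.

#' Generate a synthetic cohort and extract its feature table
#'
#' Draws \code{n_subjects} profiles, simulates one night each, prepares
#' labelled epochs and extracts the registry features, column-binding the
#' per-subject results into one \linkS4class{PSGFeatureSet}. Raw signals
#' are released after each subject.
#'
#' @param n_subjects number of subjects.
#' @param registry registry id or \linkS4class{FeatureRegistry}.
#' @param duration_h night length per subject (hours).
#' @param event_rate_per_h planted events per hour.
#' @param class_mix event class weights (see \code{\link{scheduleEvents}}).
#' @param wake_fraction fraction of wake epochs.
#' @param detach_rate sensor detachments per hour.
#' @param effect_size event physiology strength (0--1).
#' @param seed cohort seed.
#' @return a \linkS4class{PSGFeatureSet} spanning all subjects.
#' @examples
#' \donttest{
#' fs <- cohortFeatures(3, duration_h = 0.5, seed = 1)
#' table(epochLabels(fs))
#' }
#' @export
cohortFeatures <- function(n_subjects, registry = "subset_b_detection",
                           duration_h = 4, event_rate_per_h = 15,
                           class_mix = defaultClassMix(),
                           wake_fraction = 0.15, detach_rate = 0.2,
                           effect_size = 1, seed = 1L) {
  profiles <- cohortProfiles(n_subjects, seed = seed)
  if (is.character(registry)) registry <- featureRegistry(registry)
  parts <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    rec <- generateRecording(profiles[[i]], duration_h = duration_h,
                             event_rate_per_h = event_rate_per_h,
                             class_mix = class_mix,
                             wake_fraction = wake_fraction,
                             detach_rate = detach_rate,
                             effect_size = effect_size)
    parts[[i]] <- extractFeatures(prepareEpochs(rec), registry)
    rm(rec)
  }
  out <- do.call(SummarizedExperiment::cbind, parts)
  new("PSGFeatureSet", out)
}
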