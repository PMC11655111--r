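#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.PSG_FS <- 100L                # sampling rate (Hz) of every channel
.EPOCH_S <- 30L                # scoring epoch length (s)
.PSG_CHANNELS <- c("thoracic", "spo2", "audio", "eog_l", "eog_r",
                   "ecg", "position")
.EVENT_CLASSES <- c("HYP", "OSA", "CSA", "MSA")
.EPOCH_CLASSES <- c("NORMAL", "HYP", "OSA", "CSA", "MSA")
## tie-break severity used when two events overlap an epoch equally
.SEVERITY_ORDER <- c(CSA = 4L, MSA = 3L, OSA = 2L, HYP = 1L)
.POSITION_CODES <- 0:4         # supine, left, right, prone, upright

#' Subject profile for the synthetic PSG generator
#'
#' Physiological baselines of one simulated sleeper. Identical profile and
#' seed always regenerate an identical recording.
#'
#' @slot subject_id single character identifier.
#' @slot baseline_spo2 resting oxygen saturation, percent, in [94, 99].
#' @slot resp_rate respiratory rate in Hz, in [0.15, 0.35].
#' @slot heart_rate resting heart rate in beats/min, in [50, 90].
#' @slot snore_propensity scaling of obstructive snoring loudness, in [0, 1].
#' @slot seed integer root seed, expanded into per-channel streams.
#' @exportClass SubjectProfile
setClass("SubjectProfile",
  representation(subject_id = "character", baseline_spo2 = "numeric",
                 resp_rate = "numeric", heart_rate = "numeric",
                 snore_propensity = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@subject_id) != 1L) msg <- c(msg, "subject_id must be length 1")
    if (object@baseline_spo2 < 94 || object@baseline_spo2 > 99)
      msg <- c(msg, "baseline_spo2 outside [94, 99]")
    if (object@resp_rate < 0.15 || object@resp_rate > 0.35)
      msg <- c(msg, "resp_rate outside [0.15, 0.35] Hz")
    if (object@heart_rate < 50 || object@heart_rate > 90)
      msg <- c(msg, "heart_rate outside [50, 90] bpm")
    if (object@snore_propensity < 0 || object@snore_propensity > 1)
      msg <- c(msg, "snore_propensity outside [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' One night of annotated multi-channel polysomnography
#'
#' All channels are sampled at 100 Hz, band-limited below 30 Hz (except
#' oximetry, which keeps its DC level, and the integer position code) and
#' quantized to a 16-bit grid over the channel's physical range. Events are
#' the planted (or scored) apneic events; the hypnogram flags wake at the
#' 30-s epoch grid; detachment intervals mark sensor dropouts.
#'
#' @slot subject_id character scalar.
#' @slot fs sampling rate, always 100 Hz.
#' @slot channels named list of equal-length numeric vectors.
#' @slot events data.frame with columns class, onset, duration (seconds).
#' @slot hypnogram logical vector, TRUE = wake, one entry per 30-s epoch.
#' @slot detachments data.frame with columns start, end (seconds).
#' @exportClass PSGRecording
setClass("PSGRecording",
  representation(subject_id = "character", fs = "integer",
                 channels = "list", events = "data.frame",
                 hypnogram = "logical", detachments = "data.frame"),
  validity = function(object) {
    msg <- character(0)
    if (object@fs != .PSG_FS) msg <- c(msg, "fs must be 100 Hz")
    lens <- lengths(object@channels)
    if (length(unique(lens)) > 1L) msg <- c(msg, "channels differ in length")
    if (!all(.PSG_CHANNELS %in% names(object@channels)))
      msg <- c(msg, "missing required channels")
    ev <- object@events
    if (nrow(ev)) {
      if (!all(ev$class %in% .EVENT_CLASSES)) msg <- c(msg, "unknown event class")
      if (any(ev$duration < 10 | ev$duration > 120))
        msg <- c(msg, "event durations outside [10, 120] s")
      dur_s <- lens[1] / object@fs
      if (any(ev$onset + ev$duration > dur_s + 1e-9))
        msg <- c(msg, "event extends past recording end")
      o <- order(ev$onset)
      if (nrow(ev) > 1L &&
          any(ev$onset[o][-1] < (ev$onset + ev$duration)[o][-nrow(ev)]))
        msg <- c(msg, "events overlap")
    }
    if (length(msg)) msg else TRUE
  })

#' Segmented 30-s epochs of one recording
#'
#' Thin view over a \linkS4class{PSGRecording}: an index table (one row per
#' non-overlapping 30-s window anchored at t = 0) plus the parent recording,
#' from which channel slices are extracted on demand.
#'
#' @slot recording the parent \linkS4class{PSGRecording}.
#' @slot index data.frame with columns epoch (1-based), start_s, label
#'   (NA until labelled / for excluded epochs), excluded, reason.
#' @exportClass EpochSet
setClass("EpochSet",
  representation(recording = "PSGRecording", index = "data.frame"),
  validity = function(object) {
    idx <- object@index
    need <- c("epoch", "start_s", "label", "excluded", "reason")
    if (!all(need %in% names(idx))) return("index lacks required columns")
    if (nrow(idx) && any(diff(idx$start_s) != .EPOCH_S))
      return("epochs not contiguous on the 30-s grid")
    if (any(idx$excluded & !is.na(idx$label)))
      return("excluded epochs must carry no label")
    TRUE
  })

#' Named feature registry
#'
#' An ordered bank of per-epoch feature definitions. The two fixed
#' registries \code{subset_b_detection} (32 features) and
#' \code{subset_iii_distinction} (44 features) reproduce the published
#' detection and distinction subsets; \code{full_bank} is their union.
#'
#' @slot registry_id one of subset_b_detection, subset_iii_distinction,
#'   full_bank.
#' @slot defs data.frame with columns name, signal, category.
#' @exportClass FeatureRegistry
setClass("FeatureRegistry",
  representation(registry_id = "character", defs = "data.frame"),
  validity = function(object) {
    if (anyDuplicated(object@defs$name)) return("feature names not unique")
    if (!all(c("name", "signal", "category") %in% names(object@defs)))
      return("defs lacks required columns")
    TRUE
  })

#' Per-epoch feature table
#'
#' A \linkS4class{SummarizedExperiment} with features as rows (rowData:
#' signal, category) and epochs as columns (colData: subject_id, epoch,
#' start_s, label). The single assay \code{values} holds the extracted
#' feature values; \code{imputed} marks values that were flagged by the
#' extractor (e.g. too few ECG beats) and later imputed.
#'
#' @exportClass PSGFeatureSet
setClass("PSGFeatureSet", contains = "SummarizedExperiment")

#' Loading-based PCA feature-selection result
#'
#' @slot loadings feature x component orthonormal weight matrix.
#' @slot explained per-component fractions of total variance (sums to 1).
#' @slot cumulative running sums of \code{explained}.
#' @slot retained ordered names of the retained features.
#' @slot nPCsUsed number of leading components inspected.
#' @exportClass PCASelectionResult
setClass("PCASelectionResult",
  representation(loadings = "matrix", explained = "numeric",
                 cumulative = "numeric", retained = "character",
                 nPCsUsed = "integer"),
  validity = function(object) {
    if (abs(sum(object@explained) - 1) > 1e-8)
      return("explained variance fractions must sum to 1")
    if (!all(object@retained %in% rownames(object@loadings)))
      return("retained features not a subset of the input features")
    TRUE
  })

#' Class-mean dendrogram from a multivariate group analysis
#'
#' Complete-linkage agglomeration of the event classes using Mahalanobis
#' distances between class mean vectors under the pooled within-class
#' covariance (the group-mean structure a MANOVA exposes).
#'
#' @slot hclust the \code{stats::hclust} merge tree.
#' @slot distances symmetric class-by-class Mahalanobis distance matrix.
#' @slot wilks Wilks' lambda of the one-way MANOVA (NA if not computable).
#' @exportClass ClassDendrogram
setClass("ClassDendrogram",
  representation(hclust = "ANY", distances = "matrix", wilks = "numeric"),
  validity = function(object) {
    if (!inherits(object@hclust, "hclust")) return("hclust slot must be an hclust")
    TRUE
  })

#' Dichotomous case-study configuration
#'
#' Case i: apnea (OSA/CSA/MSA) vs NORMAL+HYP. Case ii: apnea vs NORMAL with
#' HYP epochs dropped. Case iii: OSA/MSA vs CSA with NORMAL/HYP dropped.
#'
#' @slot case_id "i", "ii" or "iii".
#' @slot positive_classes,negative_classes epoch labels on each side.
#' @slot registry_id feature registry the case uses.
#' @slot cap largest-class cap factor for distinction balancing.
#' @slot seed integer seed for balancing draws.
#' @exportClass CaseConfig
setClass("CaseConfig",
  representation(case_id = "character", positive_classes = "character",
                 negative_classes = "character", registry_id = "character",
                 cap = "numeric", seed = "integer"))

#' Subject-wise train/test split
#'
#' @slot train_subjects,test_subjects disjoint subject id sets whose union
#'   is the cohort.
#' @slot fraction training fraction (0.7 by convention).
#' @exportClass SplitPlan
setClass("SplitPlan",
  representation(train_subjects = "character", test_subjects = "character",
                 fraction = "numeric"),
  validity = function(object) {
    if (length(intersect(object@train_subjects, object@test_subjects)))
      return("train and test subjects overlap")
    TRUE
  })

#' Classifier family and tuning budget
#'
#' @slot family decision_tree, discriminant, naive_bayes, svm or knn.
#' @slot search_space named list of hyperparameter ranges (family default
#'   when empty).
#' @slot budget number of hyperparameter evaluations.
#' @slot cv_folds subject-grouped cross-validation folds.
#' @slot seed integer seed for the search.
#' @exportClass ModelSpec
setClass("ModelSpec",
  representation(family = "character", search_space = "list",
                 budget = "integer", cv_folds = "integer", seed = "integer"),
  validity = function(object) {
    if (!object@family %in% c("decision_tree", "discriminant", "naive_bayes",
                              "svm", "knn"))
      return("unknown model family")
    if (object@budget < 1L) return("budget must be >= 1")
    if (object@cv_folds < 2L) return("cv_folds must be >= 2")
    TRUE
  })

#' Repeated-evaluation metrics report
#'
#' @slot summary data.frame with one row per metric (sens, spec, ppv, npv,
#'   acc) and columns mean, sd over repeats.
#' @slot per_repeat data.frame of per-repeat metric values and confusion
#'   totals (tp, fn, tn, fp).
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(summary = "data.frame", per_repeat = "data.frame"),
  validity = function(object) {
    m <- object@summary$mean
    m <- m[!is.na(m)]
    if (length(m) && (any(m < 0) || any(m > 1)))
      return("metric means must lie in [0, 1]")
    TRUE
  })
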