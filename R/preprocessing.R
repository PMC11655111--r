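## Segmentation of a recording into the standard 30-s scoring epochs,
## exclusion of wake / sensor-detachment epochs, and event-to-epoch
## labelling.

#' Segment a recording into non-overlapping 30-s epochs
#'
#' Epochs are anchored at t = 0 and contiguous; a trailing window shorter
#' than 30 s is dropped. Labels start unset and no epoch is excluded.
#'
#' @param recording a \linkS4class{PSGRecording}.
#' @return an \linkS4class{EpochSet}.
#' @examples
#' rec <- generateRecording(subjectProfile("s01", seed = 3), duration_h = 0.5)
#' segmentEpochs(rec)
#' @export
segmentEpochs <- function(recording) {
  stopifnot(is(recording, "PSGRecording"))
  lens <- lengths(recording@channels)
  if (length(unique(lens)) > 1L) stop("channels differ in length")
  n_epochs <- floor(lens[[1]] / (recording@fs * .EPOCH_S))
  idx <- data.frame(epoch = seq_len(n_epochs),
                    start_s = (seq_len(n_epochs) - 1) * .EPOCH_S,
                    label = NA_character_, excluded = FALSE,
                    reason = "none", stringsAsFactors = FALSE)
  new("EpochSet", recording = recording, index = idx)
}

#' Extract one epoch's samples for one channel
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param epoch 1-based epoch number.
#' @param channel channel name.
#' @return numeric vector of exactly 3000 samples.
#' @export
epochSlice <- function(epochs, epoch, channel) {
  stopifnot(is(epochs, "EpochSet"))
  fs <- epochs@recording@fs
  i0 <- epochs@index$start_s[epoch] * fs
  psgChannel(epochs@recording, channel)[(i0 + 1L):(i0 + fs * .EPOCH_S)]
}

#' Exclude wake and sensor-detachment epochs
#'
#' An epoch is excluded when its hypnogram flag is wake, or when it
#' overlaps any detachment interval by at least 1 s. Excluded epochs carry
#' no label.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param hypnogram logical wake flags on the epoch grid (defaults to the
#'   recording's own hypnogram).
#' @param detachment_intervals data.frame with columns start, end in
#'   seconds (defaults to the recording's own annotations).
#' @return the \linkS4class{EpochSet} with updated exclusion flags.
#' @export
excludeEpochs <- function(epochs, hypnogram = NULL,
                          detachment_intervals = NULL) {
  stopifnot(is(epochs, "EpochSet"))
  idx <- epochs@index
  if (is.null(hypnogram)) hypnogram <- epochs@recording@hypnogram
  if (is.null(detachment_intervals))
    detachment_intervals <- epochs@recording@detachments
  if (length(hypnogram) < nrow(idx))
    stop("hypnogram shorter than the epoch grid")
  for (k in seq_len(nrow(idx))) {
    s0 <- idx$start_s[k]; s1 <- s0 + .EPOCH_S
    reason <- "none"
    if (isTRUE(hypnogram[k])) reason <- "wake"
    else if (nrow(detachment_intervals)) {
      ov <- pmin(s1, detachment_intervals$end) -
        pmax(s0, detachment_intervals$start)
      if (any(ov >= 1)) reason <- "detachment"
    }
    if (reason != "none") {
      idx$excluded[k] <- TRUE
      idx$reason[k] <- reason
      idx$label[k] <- NA_character_
    }
  }
  initialize(epochs, index = idx)
}

#' Label epochs from event annotations
#'
#' An epoch takes the class of the event with the largest temporal overlap
#' with its window, provided that overlap is at least 5 s (half the
#' minimum clinical event duration); otherwise it is NORMAL. Exact-overlap
#' ties break by severity CSA > MSA > OSA > HYP. Excluded epochs stay
#' unlabelled.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param events event table (class, onset, duration); defaults to the
#'   recording's planted events.
#' @param min_overlap_s minimum overlap for an event to label an epoch.
#' @return the \linkS4class{EpochSet} with labels filled in.
#' @export
labelEpochs <- function(epochs, events = NULL, min_overlap_s = 5) {
  stopifnot(is(epochs, "EpochSet"))
  if (is.null(events)) events <- epochs@recording@events
  idx <- epochs@index
  for (k in seq_len(nrow(idx))) {
    if (idx$excluded[k]) next
    s0 <- idx$start_s[k]; s1 <- s0 + .EPOCH_S
    lab <- "NORMAL"
    if (nrow(events)) {
      ov <- pmin(s1, events$onset + events$duration) - pmax(s0, events$onset)
      ok <- which(ov >= min_overlap_s)
      if (length(ok)) {
        sev <- .SEVERITY_ORDER[events$class[ok]]
        best <- ok[order(-ov[ok], -sev)][1]
        lab <- events$class[best]
      }
    }
    idx$label[k] <- lab
  }
  initialize(epochs, index = idx)
}

#' Segment, exclude and label in one call
#'
#' @param recording a \linkS4class{PSGRecording}.
#' @return a labelled \linkS4class{EpochSet}.
#' @export
prepareEpochs <- function(recording)
  labelEpochs(excludeEpochs(segmentEpochs(recording)))
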