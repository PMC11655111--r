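# Shared fixtures, generated once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

allClassMix <- function() c(HYP = 0.35, OSA = 0.40, CSA = 0.10, MSA = 0.15)

# one 0.5-h recording with a few events of every class
fixRecording <- function() fixture("rec", function()
  generateRecording(subjectProfile("fx01", seed = 301), duration_h = 0.5,
                    event_rate_per_h = 20, class_mix = allClassMix(),
                    wake_fraction = 0.1, detach_rate = 1))

# small labelled cohort feature set (detection registry)
fixCohort <- function() fixture("cohort", function()
  cohortFeatures(6, "subset_b_detection", duration_h = 0.75,
                 event_rate_per_h = 15, class_mix = allClassMix(),
                 seed = 302))

# hand-built recording with prescribed channel length and event table,
# bypassing the generator (all channels flat apart from markers)
makeRecording <- function(n_samples, events = NULL, hypnogram = NULL,
                          detachments = NULL) {
  if (is.null(events))
    events <- data.frame(class = character(0), onset = numeric(0),
                         duration = numeric(0))
  n_ep <- floor(n_samples / 3000)
  if (is.null(hypnogram)) hypnogram <- logical(n_ep)
  if (is.null(detachments))
    detachments <- data.frame(start = numeric(0), end = numeric(0))
  ch <- lapply(seq_len(7), function(i) rep(0, n_samples))
  names(ch) <- c("thoracic", "spo2", "audio", "eog_l", "eog_r", "ecg",
                 "position")
  new("PSGRecording", subject_id = "manual", fs = 100L, channels = ch,
      events = events, hypnogram = hypnogram, detachments = detachments)
}

# labelled epoch table (data.frame) with prescribed class counts
makeEpochTable <- function(counts, n_subjects = 4, seed = 1) {
  withr::with_seed(seed, {
    lab <- rep(names(counts), counts)
    data.frame(label = sample(lab),
               subject = sample(sprintf("s%02d", seq_len(n_subjects)),
                                length(lab), replace = TRUE),
               feat = rnorm(length(lab)))
  })
}
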