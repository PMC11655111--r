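## Minimal EDF+ (continuous) writer and reader for PSG recordings: seven
## 16-bit signal channels at 100 Hz in 1-s data records plus one
## "EDF Annotations" channel carrying the event list (class, onset,
## duration), the hypnogram wake flags and the detachment intervals as
## time-stamped annotation lists (TALs). The writer's physical/digital
## scaling matches the generator's 16-bit midtread grid, so a write/read
## round trip is lossless.

.edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

## physical ranges per channel; position is stored 1:1 (integer codes)
.edfRanges <- function() {
  r <- .CHANNEL_RANGE
  r$position <- c(-32768, 32767)
  r
}

#' Write a recording as EDF+
#'
#' @param recording a \linkS4class{PSGRecording}.
#' @param path output file path (.edf).
#' @param csv_path optional path for a companion CSV annotation table
#'   (subject_id, class, onset_s, duration_s).
#' @return \code{path}, invisibly.
#' @export
writeEDF <- function(recording, path, csv_path = NULL) {
  stopifnot(is(recording, "PSGRecording"))
  fs <- recording@fs
  chans <- .PSG_CHANNELS
  n <- length(recording@channels[[1]])
  n_rec <- floor(n / fs)
  rng <- .edfRanges()

  ## ---- annotation strings per 1-s record ----
  a14 <- rawToChar(as.raw(20)); a15 <- rawToChar(as.raw(21))
  ann <- rep("", n_rec)
  add <- function(rec, s) if (rec >= 1 && rec <= n_rec)
    ann[rec] <<- paste0(ann[rec], s)
  ev <- recording@events
  for (i in seq_len(nrow(ev)))
    add(floor(ev$onset[i]) + 1L,
        sprintf("+%.2f%s%.2f%s%s%s", ev$onset[i], a15, ev$duration[i],
                a14, ev$class[i], a14))
  for (k in which(recording@hypnogram))
    add((k - 1L) * .EPOCH_S + 1L,
        sprintf("+%d%s%d%shypno_wake%s", (k - 1L) * .EPOCH_S, a15,
                .EPOCH_S, a14, a14))
  det <- recording@detachments
  for (i in seq_len(nrow(det)))
    add(floor(det$start[i]) + 1L,
        sprintf("+%.2f%s%.2f%sdetachment%s", det$start[i], a15,
                det$end[i] - det$start[i], a14, a14))
  ann <- paste0(sprintf("+%d%s%s", seq_len(n_rec) - 1L, a14, a14), ann)
  ann_samp <- max(16L, ceiling((max(nchar(ann)) + 2L) / 2L))

  ## ---- headers ----
  ns <- length(chans) + 1L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(.edfPad(x, w), con, eos = NULL)
  wr("0", 8)
  wr(recording@subject_id, 80)
  wr(paste("Startdate 01-JAN-2000", recording@subject_id), 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256L * (ns + 1L), 8)
  wr("EDF+C", 44)
  wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  labels <- c(thoracic = "Thor RIP", spo2 = "SpO2", audio = "Sound level",
              eog_l = "EOG E1", eog_r = "EOG E2", ecg = "ECG",
              position = "Body position")
  dims <- c(thoracic = "au", spo2 = "%", audio = "au", eog_l = "uV",
            eog_r = "uV", ecg = "mV", position = "code")
  for (ch in chans) wr(labels[[ch]], 16); wr("EDF Annotations", 16)
  for (i in seq_len(ns)) wr("", 80)                     # transducer
  for (ch in chans) wr(dims[[ch]], 8); wr("", 8)
  for (ch in chans) wr(rng[[ch]][1], 8); wr(-1, 8)      # physical min
  for (ch in chans) wr(rng[[ch]][2], 8); wr(1, 8)       # physical max
  for (i in seq_len(ns)) wr(-32768L, 8)                 # digital min
  for (i in seq_len(ns)) wr(32767L, 8)                  # digital max
  for (ch in chans) wr("BP 0.05-30Hz", 80); wr("", 80)  # prefiltering
  for (ch in chans) wr(fs, 8); wr(ann_samp, 8)
  for (i in seq_len(ns)) wr("", 32)

  ## ---- data records ----
  dig <- lapply(chans, function(ch) {
    x <- recording@channels[[ch]]
    lo <- rng[[ch]][1]; hi <- rng[[ch]][2]
    as.integer(pmin(32767, pmax(-32768,
      round((x - lo) / (hi - lo) * 65535) - 32768L)))
  })
  names(dig) <- chans
  for (r in seq_len(n_rec)) {
    sel <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in chans)
      writeBin(dig[[ch]][sel], con, size = 2L, endian = "little")
    bytes <- c(charToRaw(ann[r]), raw(2L * ann_samp))
    writeBin(bytes[seq_len(2L * ann_samp)], con)
  }
  if (!is.null(csv_path)) {
    tab <- cbind(subject_id = recording@subject_id,
                 ev[, c("class", "onset", "duration")])
    names(tab) <- c("subject_id", "class", "onset_s", "duration_s")
    utils::write.csv(tab, csv_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read an EDF+ recording written by \code{\link{writeEDF}}
#'
#' Parses the signal headers and the annotation channel (events,
#' hypnogram wake flags, detachment intervals) back into a
#' \linkS4class{PSGRecording}. Channel order and labels must follow the
#' package's schema; arbitrary external EDF files with the same channel
#' set and annotation texts are accepted.
#'
#' @param path an .edf file.
#' @return a \linkS4class{PSGRecording}.
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)
  subject_id <- rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  lab <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  nsamp <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)

  ann_i <- which(lab == "EDF Annotations")
  sig_i <- setdiff(seq_len(ns), ann_i)
  store <- lapply(seq_len(ns), function(i)
    vector("list", n_rec))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = nsamp[i], size = 2L,
                   endian = "little", signed = TRUE)
      store[[i]][[r]] <- v
    }
  }
  schema <- c("Thor RIP" = "thoracic", "SpO2" = "spo2",
              "Sound level" = "audio", "EOG E1" = "eog_l",
              "EOG E2" = "eog_r", "ECG" = "ecg",
              "Body position" = "position")
  channels <- list()
  for (i in sig_i) {
    x <- unlist(store[[i]])
    phys <- (x - dmin[i]) / (dmax[i] - dmin[i]) * (pmax_[i] - pmin_[i]) +
      pmin_[i]
    channels[[schema[[lab[i]]]]] <- phys
  }
  ## ---- annotations ----
  a14 <- rawToChar(as.raw(20)); a15 <- rawToChar(as.raw(21))
  events <- data.frame(class = character(0), onset = numeric(0),
                       duration = numeric(0))
  wake_onsets <- numeric(0)
  det <- data.frame(start = numeric(0), end = numeric(0))
  for (r in seq_len(n_rec)) {
    bytes <- writeBin(as.integer(store[[ann_i]][[r]]), raw(),
                      size = 2L, endian = "little")
    txt <- rawToChar(bytes[bytes != as.raw(0)], multiple = FALSE)
    ## token-stream parse: "+onset\x15dur" tokens are followed by their
    ## annotation text in the next \x14-separated token
    toks <- strsplit(txt, a14, fixed = TRUE)[[1]]
    k <- 1L
    while (k <= length(toks)) {
      if (grepl(a15, toks[k], fixed = TRUE)) {
        od <- strsplit(toks[k], a15, fixed = TRUE)[[1]]
        onset <- as.numeric(od[1]); dur <- as.numeric(od[2])
        text <- if (k + 1L <= length(toks)) toks[k + 1L] else ""
        if (text %in% .EVENT_CLASSES)
          events <- rbind(events, data.frame(class = text, onset = onset,
                                             duration = dur))
        else if (text == "hypno_wake") wake_onsets <- c(wake_onsets, onset)
        else if (text == "detachment")
          det <- rbind(det, data.frame(start = onset, end = onset + dur))
        k <- k + 2L
      } else k <- k + 1L
    }
  }
  n_epochs <- floor(n_rec * rec_dur / .EPOCH_S)
  hyp <- logical(n_epochs)
  hyp[round(wake_onsets / .EPOCH_S) + 1L] <- TRUE
  events <- events[order(events$onset), ]
  rownames(events) <- NULL
  new("PSGRecording", subject_id = subject_id, fs = .PSG_FS,
      channels = channels, events = events, hypnogram = hyp,
      detachments = det)
}
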