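## Seeded generator of annotated multi-channel PSG nights with planted
## hypopnea (HYP), obstructive (OSA), central (CSA) and mixed (MSA)
## apneic events. Channel physiology follows the clinical picture:
## absent respiratory effort in CSA, preserved-but-obstructed effort and
## loud snoring in OSA, a central-then-obstructive morphology in MSA,
## partial airflow reduction in HYP, with proportional lagged SpO2
## desaturations, cyclic heart-rate variation, and post-event arousal
## activity in the EOGs.

.defaultClassMix <- local({
  apnea <- c(OSA = 84, CSA = 0.4, MSA = 15) / sum(c(84, 0.4, 15))
  m <- c(HYP = 0.45, 0.55 * apnea)
  names(m) <- c("HYP", "OSA", "CSA", "MSA")
  m / sum(m)
})

## physical ranges used for 16-bit quantization, by channel
.CHANNEL_RANGE <- list(thoracic = c(-5, 5), spo2 = c(0, 100),
                       audio = c(-5, 5), eog_l = c(-300, 300),
                       eog_r = c(-300, 300), ecg = c(-2.5, 2.5),
                       position = c(0, 4))

#' Default apneic event class mix
#'
#' Hypopnea share of 0.45 with the apnea remainder split in the reported
#' clinical ratios OSA:MSA:CSA = 84:15:0.4.
#' @return named numeric vector summing to 1 over HYP, OSA, CSA, MSA.
#' @export
defaultClassMix <- function() .defaultClassMix

#' Construct a subject profile
#'
#' @param subject_id character identifier.
#' @param baseline_spo2 resting saturation (\%), in [94, 99].
#' @param resp_rate respiratory rate (Hz), in [0.15, 0.35].
#' @param heart_rate resting heart rate (bpm), in [50, 90].
#' @param snore_propensity snoring loudness scaling, in [0, 1].
#' @param seed integer root seed; identical profile + seed regenerate an
#'   identical recording.
#' @return a \linkS4class{SubjectProfile}.
#' @examples
#' subjectProfile("s01", seed = 7)
#' @export
subjectProfile <- function(subject_id, baseline_spo2 = 96.5,
                           resp_rate = 0.25, heart_rate = 65,
                           snore_propensity = 0.5, seed = 1L) {
  new("SubjectProfile", subject_id = as.character(subject_id),
      baseline_spo2 = baseline_spo2, resp_rate = resp_rate,
      heart_rate = heart_rate, snore_propensity = snore_propensity,
      seed = as.integer(seed))
}

#' Draw a cohort of subject profiles
#'
#' Baselines are drawn uniformly within their physiological ranges; each
#' subject receives an independent root seed derived from \code{seed}.
#'
#' @param n number of subjects.
#' @param seed cohort seed.
#' @return list of \linkS4class{SubjectProfile}.
#' @export
cohortProfiles <- function(n, seed = 1L) {
  withSeed(substreamSeed(seed, "cohort-profiles"), {
    lapply(seq_len(n), function(i)
      subjectProfile(sprintf("s%03d", i),
                     baseline_spo2 = runif(1, 94.5, 98.5),
                     resp_rate = runif(1, 0.18, 0.30),
                     heart_rate = runif(1, 55, 85),
                     snore_propensity = runif(1, 0.2, 1),
                     seed = substreamSeed(seed, sprintf("subject-%03d", i))))
  })
}

#' Schedule apneic events over a night
#'
#' Event count is Poisson with the requested hourly rate; durations follow
#' a truncated log-normal with median 28 s (about 60\% of mass in the
#' typical 20--40 s range) clipped to the clinical 10--120 s window;
#' onsets are placed uniformly with at least 15 s between events; classes
#' are drawn i.i.d. from \code{class_mix}.
#'
#' @param duration_s recording length in seconds.
#' @param event_rate_per_h expected events per hour (>= 0).
#' @param class_mix named non-negative weights over HYP/OSA/CSA/MSA
#'   summing to 1 (tolerance 1e-6).
#' @param seed integer seed (NULL = current RNG stream).
#' @return data.frame with columns class, onset, duration, sorted by onset.
#' @examples
#' scheduleEvents(3600, 20, c(OSA = 1, HYP = 0, CSA = 0, MSA = 0), seed = 7)
#' @export
scheduleEvents <- function(duration_s, event_rate_per_h,
                           class_mix = defaultClassMix(), seed = NULL) {
  stopifnot(event_rate_per_h >= 0, duration_s > 0)
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-6)
    stop("class_mix entries must be non-negative and sum to 1")
  empty <- data.frame(class = character(0), onset = numeric(0),
                      duration = numeric(0))
  if (event_rate_per_h == 0) return(empty)
  withSeed(seed, {
    n <- rpois(1, event_rate_per_h * duration_s / 3600)
    if (n == 0) return(empty)
    dur <- numeric(0)
    while (length(dur) < n) {           # truncated log-normal durations
      d <- rlnorm(n, meanlog = log(28), sdlog = 0.41)
      dur <- c(dur, d[d >= 10 & d <= 120])
    }
    dur <- dur[seq_len(n)]
    cls <- sample(names(class_mix), n, replace = TRUE, prob = class_mix)
    onset <- numeric(0); keepd <- numeric(0); keepc <- character(0)
    for (i in seq_len(n)) {
      if (dur[i] >= duration_s) next
      for (try in seq_len(200)) {
        o <- runif(1, 0, duration_s - dur[i])
        ok <- !length(onset) ||
          all(o + dur[i] + 15 <= onset | onset + keepd + 15 <= o)
        if (ok) { onset <- c(onset, o); keepd <- c(keepd, dur[i])
                  keepc <- c(keepc, cls[i]); break }
      }
    }
    o <- order(onset)
    data.frame(class = keepc[o], onset = onset[o], duration = keepd[o])
  })
}

## smooth unit-sd noise at the 100 Hz grid, built from 1 Hz white noise
## averaged over `smooth_s` seconds and linearly interpolated
.slowNoise <- function(duration_s, smooth_s, n_out) {
  m <- max(4L, ceiling(duration_s) + smooth_s)
  w <- as.numeric(stats::filter(rnorm(m), rep(1 / smooth_s, smooth_s),
                                sides = 2))
  w[is.na(w)] <- 0
  s <- sd(w); if (s > 0) w <- w / s
  approx(seq_len(m) - 1, w, xout = seq(0, duration_s, length.out = n_out),
         rule = 2)$y
}

## deterministic per-event seed, keyed by the event's identity (not its
## list position) so removing one event never perturbs another
.eventSeed <- function(seed, tag, ev)
  substreamSeed(seed, sprintf("%s|%s|%.0f|%.0f", tag, ev$class,
                              ev$onset * 1000, ev$duration * 1000))

## raised-cosine ramp helper: gain envelope `g` per event with 1-s
## transitions placed just outside [onset, onset+duration]
.applyGainWindow <- function(g, t, onset, end, value) {
  fs <- 1 / (t[2] - t[1])
  i0 <- max(1L, floor((onset - 1) * fs) + 1L)
  i1 <- min(length(t), ceiling((end + 1) * fs))
  tt <- t[i0:i1]
  w <- rep(1, length(tt))
  inside <- tt >= onset & tt <= end
  w[inside] <- 0
  rin <- tt >= onset - 1 & tt < onset
  w[rin] <- (1 + cos(pi * (tt[rin] - (onset - 1)))) / 2
  rout <- tt > end & tt <= end + 1
  w[rout] <- (1 - cos(pi * (tt[rout] - end))) / 2
  seg <- if (is.function(value)) value(tt) else value
  g[i0:i1] <- g[i0:i1] * (w + (1 - w) * seg)
  g
}

#' Synthesize the thoracic respiratory-effort channel
#'
#' Quasi-sinusoidal effort at the subject's respiratory rate with slow
#' multiplicative amplitude variability. During CSA the envelope collapses
#' below 10\% of baseline; during OSA it is preserved or increased with a
#' crescendo and phase irregularity; HYP attenuates to 30--70\%; MSA is
#' central over its first 40--60\% and obstructive afterwards.
#'
#' @param events event table from \code{\link{scheduleEvents}}.
#' @param profile a \linkS4class{SubjectProfile}.
#' @param duration_s recording length (s).
#' @param effect_size scales every event's deviation from baseline
#'   physiology (1 = full clinical effect, 0 = no event signature).
#' @return numeric vector of length \code{duration_s * 100}.
#' @export
synthThoracic <- function(events, profile, duration_s, effect_size = 1) {
  fs <- .PSG_FS
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  seed <- profile@seed
  phi0 <- withSeed(substreamSeed(seed, "resp-phase"), runif(1, 0, 2 * pi))
  amp <- withSeed(substreamSeed(seed, "thoracic-amp"),
                  pmax(0.5, 1 + 0.12 * .slowNoise(duration_s, 30L, n)))
  noise <- withSeed(substreamSeed(seed, "thoracic-noise"), rnorm(n, sd = 0.03))
  g <- rep(1, n)
  psi <- numeric(n)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    end <- ev$onset + ev$duration
    es <- .eventSeed(seed, "thoracic", ev)
    draws <- withSeed(es, runif(4))
    obstructive <- function(tt, o, d, ph) {
      u <- pmin(1, pmax(0, (tt - o) / d))
      pmax(0.9, 1 + 0.15 + 0.35 * u + 0.3 * sin(2 * pi * 0.1 * (tt - o) + ph))
    }
    gfun <- switch(ev$class,
      CSA = function(tt) rep(0.05, length(tt)),
      HYP = local({ gh <- 0.4 + 0.3 * draws[1]
                    function(tt) rep(gh, length(tt)) }),
      OSA = local({ ph <- 2 * pi * draws[2]; o <- ev$onset; d <- ev$duration
                    function(tt) obstructive(tt, o, d, ph) }),
      MSA = local({ uc <- 0.4 + 0.2 * draws[3]; ph <- 2 * pi * draws[2]
                    o <- ev$onset; d <- ev$duration
                    function(tt) {
                      gg <- obstructive(tt, o + uc * d, d * (1 - uc), ph)
                      central <- tt < o + uc * d
                      gg[central] <- 0.05
                      # 1-s internal ramp at the central->obstructive switch
                      sw <- tt >= o + uc * d & tt < o + uc * d + 1
                      a <- (tt[sw] - (o + uc * d))
                      gg[sw] <- 0.05 + (gg[sw] - 0.05) * (1 - cos(pi * a)) / 2
                      gg
                    } }))
    gev <- function(tt) 1 + effect_size * (gfun(tt) - 1)
    g <- .applyGainWindow(g, t, ev$onset, end, gev)
    if (ev$class %in% c("OSA", "MSA")) {  # local phase irregularity
      idx <- idxWindow(ev$onset, end, n)
      if (length(idx)) {
        tau <- t[idx] - ev$onset
        taper <- sin(pi * tau / ev$duration)^2
        psi[idx] <- psi[idx] + 2.5 * effect_size *
          sin(2 * pi * 0.25 * tau + 2 * pi * draws[4]) * taper
      }
    }
  }
  amp * g * sin(2 * pi * profile@resp_rate * t + phi0 + psi) + noise
}

#' Synthesize the pulse-oximetry (SpO2) channel
#'
#' Baseline saturation with slow noise of about 0.25\% SD. Each event
#' produces a desaturation delayed 10--20 s after onset with depth
#' \code{3 + 4 * (1 - residual airflow)} percent (apneas deeper than
#' hypopneas), exponential resaturation with a 15 s time constant, and a
#' response strictly confined to [onset, onset + duration + 60 s]. Values
#' are clipped to [70, 100].
#'
#' @inheritParams synthThoracic
#' @return numeric vector of saturations (\%).
#' @export
synthSpo2 <- function(events, profile, duration_s, effect_size = 1) {
  fs <- .PSG_FS
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  seed <- profile@seed
  x <- profile@baseline_spo2 +
    withSeed(substreamSeed(seed, "spo2-noise"),
             0.25 * .slowNoise(duration_s, 8L, n))
  raf <- c(HYP = NA, OSA = 0, CSA = 0, MSA = 0)  # residual airflow
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    end <- ev$onset + ev$duration
    es <- .eventSeed(seed, "spo2", ev)
    draws <- withSeed(es, runif(2))
    ## hypopnea desaturations sit near the 3% scoring threshold; full
    ## apneas (no residual airflow) reach the maximal 7% depth
    r <- if (ev$class == "HYP") 0.6 + 0.3 * draws[2] else raf[[ev$class]]
    depth <- effect_size * (3 + 4 * (1 - r))
    lag <- 10 + 10 * draws[1]
    t0 <- ev$onset + lag                 # desaturation onset
    t1 <- t0 + 8                         # fast fall to the nadir
    t2 <- max(t1, end + 10)              # nadir plateau to past event end
    wend <- end + 60
    idx <- idxWindow(ev$onset, wend, n)
    if (!length(idx)) next
    tt <- t[idx]
    resp <- numeric(length(tt))
    fall <- tt > t0 & tt <= t1
    resp[fall] <- -depth * (tt[fall] - t0) / (t1 - t0)
    plat <- tt > t1 & tt <= t2
    resp[plat] <- -depth
    rec <- tt > t2
    resp[rec] <- -depth * exp(-(tt[rec] - t2) / 15)
    # confine strictly to the window: cosine-taper the last 5 s to zero
    tl <- tt > wend - 5
    resp[tl] <- resp[tl] * (1 + cos(pi * (tt[tl] - (wend - 5)) / 5)) / 2
    x[idx] <- x[idx] + resp
  }
  pmin(pmax(x, 70), 100)
}

#' Synthesize the ancillary channels
#'
#' Audio: respiration-gated band-limited noise, amplified during
#' obstructive events in proportion to the subject's snore propensity and
#' silenced during central events. ECG: a template pulse train whose RR
#' interval lengthens toward event termination and shortens for about 15 s
#' afterwards (cyclic variation well above 10\% of the baseline RR),
#' implemented as a local time warp so the response is strictly confined
#' to each event's neighbourhood. EOGs: 1/f-like background with a
#' 13--30 Hz arousal burst in the 10 s after each event ends. Position: a
#' piecewise-constant integer code (0 supine, 1 left, 2 right, 3 prone,
#' 4 upright) with 0--4 changes per night.
#'
#' @inheritParams synthThoracic
#' @return named list with elements audio, eog_l, eog_r, ecg, position.
#' @export
synthAncillary <- function(events, profile, duration_s, effect_size = 1) {
  fs <- .PSG_FS
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  seed <- profile@seed
  phi0 <- withSeed(substreamSeed(seed, "resp-phase"), runif(1, 0, 2 * pi))

  ## ---- audio ----
  ## a 100 Hz channel band-limited below 30 Hz cannot carry raw snore
  ## acoustics; like the oximetry trace, the recorded audio channel is a
  ## sound-level signal: non-negative breath bursts gated at the
  ## respiratory rate, scaled up (snoring) during obstructive events and
  ## collapsed during central ones
  resp_env <- 0.04 + 0.45 * pmax(0, sin(2 * pi * profile@resp_rate * t + phi0))^2
  g <- rep(1, n)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    end <- ev$onset + ev$duration
    snore <- 1.5 + 2.5 * profile@snore_propensity
    lvl <- switch(ev$class, CSA = 0.05, HYP = 0.7, OSA = snore, MSA = NA)
    if (ev$class == "MSA") {
      uc <- withSeed(.eventSeed(seed, "thoracic", ev), runif(4))[3]
      uc <- 0.4 + 0.2 * uc                  # same switch point as thoracic
      o <- ev$onset; d <- ev$duration
      gfun <- function(tt) {
        v <- rep(1 + effect_size * (snore - 1), length(tt))
        v[tt < o + uc * d] <- 1 + effect_size * (0.05 - 1)
        v
      }
      g <- .applyGainWindow(g, t, ev$onset, end, gfun)
    } else {
      g <- .applyGainWindow(g, t, ev$onset, end, 1 + effect_size * (lvl - 1))
    }
  }
  ## multiplicative level noise is itself band-limited (flat to ~10 Hz,
  ## fast roll-off) so the channel respects the <30 Hz acquisition band
  audio <- withSeed(substreamSeed(seed, "audio-noise"), {
    wob <- shapedNoise(n, fs, function(f) 1 / sqrt(1 + (f / 10)^8))
    (resp_env * pmax(0.1, 1 + 0.3 * wob) + 0.01 * abs(wob)) * g
  })

  ## ---- ECG ----
  rr0 <- 60 / profile@heart_rate
  ecg <- withSeed(substreamSeed(seed, "ecg"), {
    m <- ceiling(duration_s / rr0 * 1.4) + 8L
    wob <- as.numeric(stats::filter(rnorm(m), 0.97, "recursive"))
    wob <- 0.03 * wob * sqrt(1 - 0.97^2)
    beats <- cumsum(rr0 * (1 + wob + 0.01 * rnorm(m))) + runif(1, 0, rr0)
    beats <- beats[beats < duration_s - 0.5]
    imp <- numeric(n)
    imp[pmin(n, round(beats * fs) + 1L)] <- 1 + 0.05 * rnorm(length(beats))
    tk <- seq(-0.2, 0.45, by = 1 / fs)
    template <- exp(-(tk / 0.012)^2 / 2) - 0.15 * exp(-((tk - 0.04) / 0.02)^2 / 2) +
      0.22 * exp(-((tk - 0.28) / 0.05)^2 / 2)
    # FFT convolution, aligned so each impulse lands on the R peak
    nf <- stats::nextn(n + length(template), c(2, 3, 5))
    y <- Re(fft(fft(c(imp, numeric(nf - n))) *
               fft(c(template, numeric(nf - length(template)))),
               inverse = TRUE)) / nf
    y <- y[which.max(template) + 0:(n - 1L)]
    y + 0.01 * rnorm(n)
  })
  if (nrow(events) && effect_size > 0) {
    shift_rate <- numeric(n)                 # d(sigma)/dt of the time warp
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      end <- ev$onset + ev$duration
      ## autonomic response scales with severity: full apneas provoke a
      ## stronger cyclic bradycardia/tachycardia than hypopneas
      se <- (if (ev$class == "HYP") 0.04 else 0.12) * effect_size
      lb <- min(ev$duration, 25)
      brady <- idxWindow(end - lb, end - 0.01, n)
      shift_rate[brady] <- shift_rate[brady] + se
      tachy <- idxWindow(end, end + 15 - 0.01, n)
      shift_rate[tachy] <- shift_rate[tachy] - se * lb / 15
    }
    sigma <- cumsum(shift_rate) / fs
    warp <- which(abs(sigma) > 1e-9)
    if (length(warp)) {
      tau <- t[warp] - sigma[warp]
      ecg[warp] <- approx(t, ecg, xout = pmin(pmax(tau, 0), t[n]))$y
    }
  }

  ## ---- EOGs ----
  pink <- function(tag) withSeed(substreamSeed(seed, tag),
    30 * shapedNoise(n, fs, function(f) 1 / sqrt(pmax(f, 0.1))))
  eog_l <- pink("eog-l"); eog_r <- pink("eog-r")
  if (nrow(events) && effect_size > 0) {
    bp <- signal::butter(2, c(13, 30) / (fs / 2), type = "pass")
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      end <- ev$onset + ev$duration
      idx <- idxWindow(end, end + 10 - 0.01, n)
      if (length(idx) < 200L) next
      taper <- sin(pi * seq_along(idx) / length(idx))^2
      amp <- if (ev$class == "HYP") 10 else 28   # arousal ~ severity
      for (ch in c("eog-arousal-l", "eog-arousal-r")) {
        burst <- withSeed(.eventSeed(seed, ch, ev),
                          as.numeric(signal::filtfilt(bp, rnorm(length(idx)))))
        burst <- amp * effect_size * burst / max(sd(burst), 1e-12) * taper
        if (ch == "eog-arousal-l") eog_l[idx] <- eog_l[idx] + burst
        else eog_r[idx] <- eog_r[idx] + burst
      }
    }
  }

  ## ---- body position ----
  position <- withSeed(substreamSeed(seed, "position"), {
    k <- sample(0:4, 1)
    times <- sort(runif(k, 0, duration_s))
    codes <- integer(k + 1L)
    codes[1] <- sample(.POSITION_CODES, 1)
    for (j in seq_len(k))
      codes[j + 1L] <- sample(setdiff(.POSITION_CODES, codes[j]), 1)
    pos <- numeric(n)
    bounds <- c(0, times, duration_s)
    for (j in seq_len(k + 1L))
      pos[t >= bounds[j] & t < bounds[j + 1L] + 1] <- codes[j]
    pos
  })

  list(audio = audio, eog_l = eog_l, eog_r = eog_r, ecg = ecg,
       position = position)
}

#' Generate one annotated synthetic PSG recording
#'
#' Composes the channel synthesizers, emulates the acquisition chain
#' (zero-phase Butterworth band limiting below 30 Hz -- oximetry keeps its
#' DC level, the position code is untouched -- followed by 16-bit midtread
#' quantization over each channel's physical range), flags
#' \code{wake_fraction} of the 30-s epochs that contain no planted event
#' as wake, and draws sensor-detachment annotation intervals.
#'
#' @param profile a \linkS4class{SubjectProfile}.
#' @param duration_h night length in hours, in [0.5, 12].
#' @param event_rate_per_h expected planted events per hour.
#' @param class_mix event class weights, see \code{\link{scheduleEvents}}.
#' @param wake_fraction fraction of epochs flagged wake, in [0, 0.5].
#' @param detach_rate expected sensor detachments per hour.
#' @param effect_size event physiology strength (0 = events leave no
#'   trace on any channel, 1 = full clinical effect).
#' @return a \linkS4class{PSGRecording}.
#' @examples
#' rec <- generateRecording(subjectProfile("s01", seed = 3), duration_h = 0.5)
#' rec
#' @export
generateRecording <- function(profile, duration_h = 8,
                              event_rate_per_h = 15,
                              class_mix = defaultClassMix(),
                              wake_fraction = 0.15, detach_rate = 0.2,
                              effect_size = 1) {
  if (duration_h < 0.5 || duration_h > 12)
    stop("duration_h must lie in [0.5, 12]")
  if (wake_fraction < 0 || wake_fraction > 0.5)
    stop("wake_fraction must lie in [0, 0.5]")
  duration_s <- round(duration_h * 3600)
  seed <- profile@seed
  events <- scheduleEvents(duration_s, event_rate_per_h, class_mix,
                           seed = substreamSeed(seed, "events"))
  anc <- synthAncillary(events, profile, duration_s, effect_size)
  raw <- c(list(thoracic = synthThoracic(events, profile, duration_s,
                                         effect_size),
                spo2 = synthSpo2(events, profile, duration_s, effect_size)),
           anc)
  channels <- lapply(names(raw), function(ch) {
    x <- raw[[ch]]
    if (ch == "position") return(round(x))   # integer codes, stored as-is
    x <- bandLimit(x, .PSG_FS,
                   highpass = !(ch %in% c("spo2", "audio")))
    rg <- .CHANNEL_RANGE[[ch]]
    quantize16(x, rg[1], rg[2])
  })
  names(channels) <- names(raw)

  n_epochs <- floor(duration_s / .EPOCH_S)
  wake <- logical(n_epochs)
  starts <- (seq_len(n_epochs) - 1) * .EPOCH_S
  eventfree <- vapply(starts, function(s0)
    !nrow(events) || all(events$onset >= s0 + .EPOCH_S |
                         events$onset + events$duration <= s0),
    logical(1))
  n_wake <- round(wake_fraction * n_epochs)
  ## apneic events commonly terminate in an arousal or awakening, so the
  ## scorer's wake epochs concentrate just after events: half the wake
  ## budget is drawn from event-free epochs that start within 60 s of an
  ## event's end, the rest uniformly from the remaining event-free epochs
  wake_pick <- withSeed(substreamSeed(seed, "hypnogram"), {
    pool <- which(eventfree)
    post <- if (nrow(events)) pool[vapply(starts[pool], function(s0)
      any(events$onset + events$duration <= s0 &
          events$onset + events$duration > s0 - 60), logical(1))]
    else integer(0)
    a <- sample(post, min(length(post), round(n_wake / 2)))
    b <- sample(setdiff(pool, a), min(n_wake - length(a),
                                      length(setdiff(pool, a))))
    c(a, b)
  })
  wake[wake_pick] <- TRUE

  det <- withSeed(substreamSeed(seed, "detach"), {
    k <- rpois(1, detach_rate * duration_h)
    out <- data.frame(start = numeric(0), end = numeric(0))
    for (j in seq_len(k)) {
      d <- runif(1, 20, 90)
      for (try in seq_len(20)) {
        s0 <- runif(1, 0, duration_s - d)
        clear <- !nrow(events) ||
          all(events$onset >= s0 + d | events$onset + events$duration <= s0)
        if (clear || try == 20L) {
          out <- rbind(out, data.frame(start = s0, end = s0 + d)); break
        }
      }
    }
    out
  })

  new("PSGRecording", subject_id = profile@subject_id, fs = .PSG_FS,
      channels = channels, events = events, hypnogram = wake,
      detachments = det)
}
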