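## Per-epoch feature bank: time-domain statistics, prominence-based peak
## descriptors, Welch spectral summaries, spectral Renyi entropy,
## approximate entropy, oximetry desaturation/hypoxic-burden measures,
## instantaneous spectral entropy of the audio, EOG rhythm powers, ECG
## wavelet statistics and RR-interval summaries — organised as named
## registries so the fixed 32-feature detection subset and 44-feature
## distinction subset are constructible by name.

#' Time-domain statistics of an epoch
#'
#' @param x numeric samples of one epoch.
#' @param fs sampling rate (Hz), used for the AUC time grid.
#' @return named list: mean, std (n-1 denominator), median, iqr
#'   (linear-interpolation quantiles), skewness (0 for constant input),
#'   auc (trapezoidal integral of |x| in signal-units * s).
#' @examples
#' timeStats(c(1, 2, 3, 4), fs = 1)
#' @export
timeStats <- function(x, fs = 100) {
  stopifnot(length(x) > 0)
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  list(mean = mean(x), std = if (length(x) > 1) sd(x) else 0,
       median = median(x), iqr = q[2] - q[1],
       skewness = sampleSkewness(x),
       auc = trapezInt((seq_along(x) - 1) / fs, abs(x)))
}

#' Peak descriptors of an epoch
#'
#' Peaks are local maxima with topographic prominence of at least 10\% of
#' the epoch's range and at least 1 s apart. Peak heights (PH) are
#' measured from the epoch median; inter-peak distances (IPD) are in
#' seconds. With fewer than two peaks the IPD statistics are 0 and the
#' result is flagged.
#'
#' @param x numeric epoch samples.
#' @param fs sampling rate (Hz).
#' @return named list: n_peaks, min_ph, mean_ph, std_ph, sum_ph,
#'   mean_ipd, skew_ipd, flagged.
#' @export
peakStats <- function(x, fs = 100) {
  rng <- diff(range(x))
  pk <- if (rng > 0) findPeaksProm(x, minProm = 0.1 * rng,
                                   minDistSamples = as.integer(fs))
        else integer(0)
  med <- median(x)
  if (!length(pk))
    return(list(n_peaks = 0, min_ph = 0, mean_ph = 0, std_ph = 0,
                sum_ph = 0, mean_ipd = 0, skew_ipd = 0, flagged = TRUE))
  ph <- x[pk] - med
  ipd <- diff(pk) / fs
  few <- length(pk) < 2L
  list(n_peaks = length(pk), min_ph = min(ph), mean_ph = mean(ph),
       std_ph = if (length(ph) > 1) sd(ph) else 0, sum_ph = sum(ph),
       mean_ipd = if (few) 0 else mean(ipd),
       skew_ipd = if (few) 0 else sampleSkewness(ipd),
       flagged = few)
}

#' Welch spectral summaries over a band
#'
#' Welch periodogram (4-s Hann segments, 50\% overlap); the mean frequency
#' is the PSD-weighted centroid over the band, the median frequency splits
#' the band power in half, and the band power integrates the PSD
#' (signal-units^2).
#'
#' @param x numeric epoch samples.
#' @param fs sampling rate (Hz).
#' @param band two-element frequency band (Hz) within [0, fs/2].
#' @param nper Welch segment length in samples; the default 4-s segment
#'   suits the faster channels, while the thoracic respiration band
#'   (0.05--1 Hz) is evaluated with 16-s segments for usable resolution.
#' @return named list: mean_freq, median_freq, peak_freq, band_power.
#' @export
spectralStats <- function(x, fs = 100, band = c(0, fs / 2), nper = 4L * fs) {
  stopifnot(band[1] >= 0, band[2] <= fs / 2, band[1] < band[2])
  .spectralFromPSD(welchPSD(x, fs, nper), band)
}

## spectral summaries from a precomputed Welch PSD (cached per epoch by
## the extractor so each channel is transformed once)
.spectralFromPSD <- function(W, band) {
  sel <- W$freq >= band[1] & W$freq <= band[2]
  f <- W$freq[sel]; p <- W$psd[sel]
  df <- W$freq[2] - W$freq[1]
  tot <- sum(p)
  if (tot <= 0)
    return(list(mean_freq = 0, median_freq = 0, peak_freq = 0,
                band_power = 0))
  cum <- cumsum(p)
  list(mean_freq = sum(f * p) / tot,
       median_freq = f[which(cum >= tot / 2)[1]],
       peak_freq = f[which.max(p)],
       band_power = tot * df)
}

#' Order-2 Renyi entropy of the spectral distribution
#'
#' The Welch PSD of the epoch is normalized to a probability distribution
#' over frequency bins; the collision entropy -log(sum(p^2)) is returned
#' (natural log). A zero-power series gives 0 by convention.
#'
#' @param x numeric epoch samples.
#' @param fs sampling rate (Hz).
#' @param order entropy order (only 2 supported).
#' @return non-negative scalar.
#' @export
renyiEntropy <- function(x, fs = 100, order = 2) {
  stopifnot(order == 2, length(x) > 0)
  .renyiFromPSD(welchPSD(x, fs))
}

.renyiFromPSD <- function(W) {
  p <- W$psd
  s <- sum(p)
  if (s <= 0) return(0)
  p <- p / s
  -log(sum(p^2))
}

#' Approximate entropy ApEn(m, r)
#'
#' Standard Pincus formulation with self-matches included: the tolerance
#' is \code{r_frac} times the sample SD of \code{x}. A constant series
#' returns 0.
#'
#' @param x numeric series (for oximetry, the 1 Hz series over the current
#'   plus up to three preceding epochs, see \code{\link{extractFeatures}}).
#' @param m embedding dimension.
#' @param r_frac tolerance as a fraction of SD (0.15 or 0.25 in the bank).
#' @return non-negative scalar.
#' @export
approximateEntropy <- function(x, m = 2L, r_frac = 0.25) {
  n <- length(x)
  s <- if (n > 1) sd(x) else 0
  if (s == 0 || n < m + 2L) return(0)
  r <- r_frac * s
  phi <- function(mm) {
    nm <- n - mm + 1L
    D <- matrix(0, nm, nm)
    for (k in 0:(mm - 1L)) {
      v <- x[(1L + k):(nm + k)]
      D <- pmax(D, abs(outer(v, v, "-")))
    }
    mean(log(rowSums(D <= r) / nm))
  }
  phi(m) - phi(m + 1L)
}

#' Oximetry desaturation and hypoxic-burden features
#'
#' @param x SpO2 epoch samples in percent saturation.
#' @param fs sampling rate (Hz).
#' @param window_s delta-index window length (12 s by the usual
#'   convention).
#' @return named list: std, range, min, p95, p5, m2 (second central
#'   moment), delta_index (mean absolute difference between consecutive
#'   \code{window_s}-second window means), tsa95 (fraction of the epoch
#'   below 95\% saturation).
#' @export
spo2Features <- function(x, fs = 100, window_s = 12) {
  w <- as.integer(window_s * fs)
  starts <- seq(1L, length(x), by = w)
  means <- vapply(starts, function(s)
    mean(x[s:min(length(x), s + w - 1L)]), numeric(1))
  list(std = if (length(x) > 1) sd(x) else 0,
       range = diff(range(x)), min = min(x),
       p95 = quantile(x, 0.95, names = FALSE, type = 7),
       p5 = quantile(x, 0.05, names = FALSE, type = 7),
       m2 = mean((x - mean(x))^2),
       delta_index = if (length(means) > 1) mean(abs(diff(means))) else 0,
       tsa95 = mean(x < 95))
}

#' Instantaneous spectral entropy (ISE) of the audio channel
#'
#' The ISE series is the Shannon entropy (natural log) of each 1-s
#' spectrogram column's normalized periodogram; a silent column scores 0.
#'
#' @param audio numeric epoch samples.
#' @param fs sampling rate (Hz).
#' @return named list: ise_range (max - min of the ISE series),
#'   time_outside (fraction of columns with ISE outside the epoch's
#'   mean +/- 2 SD), ise (the per-second series).
#' @export
iseFeatures <- function(audio, fs = 100) {
  ncol <- floor(length(audio) / fs)
  ise <- vapply(seq_len(ncol), function(j) {
    seg <- audio[((j - 1L) * fs + 1L):(j * fs)]
    p <- Mod(fft(seg)[1:(fs %/% 2 + 1L)])^2
    s <- sum(p)
    if (s <= 0) return(0)
    p <- p / s
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
  m <- mean(ise); s <- if (ncol > 1) sd(ise) else 0
  list(ise_range = diff(range(ise)),
       time_outside = if (s > 0) mean(ise < m - 2 * s | ise > m + 2 * s)
                      else 0,
       ise = ise)
}

#' EOG delta and beta rhythm powers
#'
#' Band powers via \code{\link{spectralStats}} with delta = [0.5, 4] Hz
#' and beta = [13, 30] Hz.
#'
#' @param eog_l,eog_r left/right EOG epoch samples.
#' @param fs sampling rate (Hz).
#' @return named list: delta_l, delta_r, beta_r.
#' @export
eogRhythmPower <- function(eog_l, eog_r, fs = 100) {
  list(delta_l = spectralStats(eog_l, fs, c(0.5, 4))$band_power,
       delta_r = spectralStats(eog_r, fs, c(0.5, 4))$band_power,
       beta_r = spectralStats(eog_r, fs, c(13, 30))$band_power)
}

#' ECG discrete-wavelet statistics
#'
#' Five-level Daubechies-4 decomposition with periodization; returns the
#' IQRs of detail levels 3--5, the variances of detail levels 1--3, and
#' the standard deviation and MAD (mean absolute deviation from the
#' median) of every detail level — 16 values.
#'
#' @param ecg numeric epoch samples.
#' @param fs sampling rate (Hz, unused beyond documentation).
#' @return named list of 16 statistics.
#' @export
ecgDwtFeatures <- function(ecg, fs = 100) {
  dw <- dwtDb4(ecg, 5L)
  out <- list()
  for (l in 3:5) {
    q <- quantile(dw[[paste0("d", l)]], c(0.25, 0.75), names = FALSE, type = 7)
    out[[paste0("dwt_iqr_d", l)]] <- q[2] - q[1]
  }
  for (l in 1:3) out[[paste0("dwt_var_d", l)]] <- var(dw[[paste0("d", l)]])
  for (l in 1:5) out[[paste0("dwt_std_d", l)]] <- sd(dw[[paste0("d", l)]])
  for (l in 1:5) {
    d <- dw[[paste0("d", l)]]
    out[[paste0("dwt_mad_d", l)]] <- mean(abs(d - median(d)))
  }
  out
}

#' Detail-level energies of the audio wavelet decomposition
#'
#' @param x numeric epoch samples.
#' @param levels detail levels whose energies (sums of squared
#'   coefficients) are returned.
#' @return named list of energies.
#' @export
dwtDetailEnergy <- function(x, levels = c(3L, 4L)) {
  dw <- dwtDb4(x, max(levels))
  out <- list()
  for (l in levels)
    out[[paste0("dwt_energy_d", l)]] <- sum(dw[[paste0("d", l)]]^2)
  out
}

#' RR-interval summaries from the ECG
#'
#' Beats are located by derivative-energy thresholding (squared first
#' difference, 150 ms moving average, adaptive threshold) with a 250 ms
#' refractory period. With fewer than two detected beats the values are
#' NA and flagged (imputed downstream with training-split medians).
#'
#' @param ecg numeric epoch samples.
#' @param fs sampling rate (Hz).
#' @return named list: mean_rr, median_rr (seconds), flagged.
#' @export
rrFeatures <- function(ecg, fs = 100) {
  d <- diff(ecg)
  e <- as.numeric(stats::filter(d^2, rep(1 / 15, 15), sides = 2))
  e[is.na(e)] <- 0
  thr <- 0.2 * quantile(e, 0.995, names = FALSE)
  if (thr <= 0)
    return(list(mean_rr = NA_real_, median_rr = NA_real_, flagged = TRUE))
  above <- which(e >= thr)
  if (!length(above))
    return(list(mean_rr = NA_real_, median_rr = NA_real_, flagged = TRUE))
  gaps <- which(diff(above) > 0.25 * fs)
  runs <- cbind(c(1L, gaps + 1L), c(gaps, length(above)))
  beats <- apply(runs, 1, function(rg) {
    seg <- above[rg[1]:rg[2]]
    seg[which.max(e[seg])]
  }) / fs
  if (length(beats) < 2L)
    return(list(mean_rr = NA_real_, median_rr = NA_real_, flagged = TRUE))
  rr <- diff(beats)
  list(mean_rr = mean(rr), median_rr = median(rr), flagged = FALSE)
}

## ---------------------------------------------------------------------
## registries

.registryTable <- function(id) {
  df <- function(name, signal, category)
    data.frame(name = name, signal = signal, category = category,
               stringsAsFactors = FALSE)
  thor_time11 <- df(paste0("thor_", c("mean", "std", "median", "iqr",
                                      "n_peaks", "min_ph", "mean_ph",
                                      "std_ph", "sum_ph", "mean_ipd", "auc")),
                    "thoracic", "time")
  thor_freq <- df(paste0("thor_", c("mean_freq", "median_freq", "peak_freq",
                                    "band_power")), "thoracic", "frequency")
  thor_renyi <- df("thor_renyi", "thoracic", "complexity")
  spo2_common <- rbind(
    df(paste0("spo2_", c("std", "range", "min")), "spo2", "time"),
    df("spo2_p5", "spo2", "time"),
    df("spo2_delta_index", "spo2", "time"),
    df("spo2_tsa95", "spo2", "hypoxic_burden"),
    df(c("spo2_apen025", "spo2_apen015"), "spo2", "complexity"))
  detection <- rbind(
    thor_time11, thor_freq, thor_renyi,
    df("spo2_p95", "spo2", "time"), spo2_common,
    df(c("audio_mean", "audio_median"), "audio", "time"),
    df(c("audio_ise_range", "audio_ise_outside"), "audio", "frequency"),
    df(c("eog_delta_l", "eog_delta_r", "eog_beta_r"), "eog", "frequency"))
  ## fixed ordering: keep spo2 rows contiguous
  detection <- detection[order(match(detection$signal,
                                     c("thoracic", "spo2", "audio", "eog"))), ]
  distinction <- rbind(
    df(paste0("ecg_", c(paste0("dwt_iqr_d", 3:5), paste0("dwt_var_d", 1:3),
                        paste0("dwt_std_d", 1:5), paste0("dwt_mad_d", 1:5))),
       "ecg", "frequency"),
    df(c("ecg_mean_rr", "ecg_median_rr"), "ecg", "rr"),
    df(paste0("thor_", c("std", "iqr", "n_peaks", "min_ph", "mean_ph",
                         "std_ph", "sum_ph", "mean_ipd", "skew_ipd", "auc")),
       "thoracic", "time"),
    df(c("thor_mean_freq", "thor_band_power"), "thoracic", "frequency"),
    df("spo2_m2", "spo2", "time"), spo2_common,
    df(c("audio_dwt_energy_d3", "audio_dwt_energy_d4"), "audio", "frequency"),
    df(c("audio_ise_range", "audio_renyi"), "audio", "complexity"),
    df("position_code", "position", "position"))
  distinction <- distinction[order(match(distinction$signal,
                                         c("ecg", "thoracic", "spo2",
                                           "audio", "position"))), ]
  switch(id,
    subset_b_detection = detection,
    subset_iii_distinction = distinction,
    full_bank = {
      u <- rbind(detection, distinction)
      u[!duplicated(u$name), ]
    },
    stop("unknown registry id: ", id))
}

#' Fixed feature registries
#'
#' \code{subset_b_detection} is the 32-feature detection subset (thoracic
#' 16, SpO2 9, audio 4, EOG 3); \code{subset_iii_distinction} is the
#' 44-feature distinction subset (ECG 18, thoracic 12, SpO2 9, audio 4,
#' position 1); \code{full_bank} is their union.
#'
#' @param registry_id one of \code{"subset_b_detection"},
#'   \code{"subset_iii_distinction"}, \code{"full_bank"}.
#' @return a \linkS4class{FeatureRegistry}.
#' @examples
#' featureRegistry("subset_b_detection")
#' @export
featureRegistry <- function(registry_id = c("subset_b_detection",
                                            "subset_iii_distinction",
                                            "full_bank")) {
  registry_id <- match.arg(registry_id)
  tab <- .registryTable(registry_id)
  rownames(tab) <- NULL
  new("FeatureRegistry", registry_id = registry_id, defs = tab)
}

## compute all registry features for one epoch; spo2_context is the 1-Hz
## oximetry series of the current plus up to three preceding epochs
.computeEpochFeatures <- function(slices, names_wanted, spo2_context, fs) {
  v <- numeric(0); fl <- character(0)
  want <- function(prefix) any(startsWith(names_wanted, prefix))
  add <- function(vals) v <<- c(v, unlist(vals))

  if (want("thor_")) {
    x <- slices$thoracic
    ts <- timeStats(x, fs); ps <- peakStats(x, fs)
    Wt <- welchPSD(x, fs, nper = 16L * fs)   # resolution for respiration
    ss <- .spectralFromPSD(Wt, band = c(0.05, 1))
    add(list(thor_mean = ts$mean, thor_std = ts$std, thor_median = ts$median,
             thor_iqr = ts$iqr, thor_skew = ts$skewness, thor_auc = ts$auc,
             thor_n_peaks = ps$n_peaks, thor_min_ph = ps$min_ph,
             thor_mean_ph = ps$mean_ph, thor_std_ph = ps$std_ph,
             thor_sum_ph = ps$sum_ph, thor_mean_ipd = ps$mean_ipd,
             thor_skew_ipd = ps$skew_ipd,
             thor_mean_freq = ss$mean_freq, thor_median_freq = ss$median_freq,
             thor_peak_freq = ss$peak_freq, thor_band_power = ss$band_power,
             thor_renyi = .renyiFromPSD(Wt)))
  }
  if (want("spo2_")) {
    sf <- spo2Features(slices$spo2, fs)
    add(list(spo2_std = sf$std, spo2_range = sf$range, spo2_min = sf$min,
             spo2_p95 = sf$p95, spo2_p5 = sf$p5, spo2_m2 = sf$m2,
             spo2_delta_index = sf$delta_index, spo2_tsa95 = sf$tsa95,
             spo2_apen025 = approximateEntropy(spo2_context, 2L, 0.25),
             spo2_apen015 = approximateEntropy(spo2_context, 2L, 0.15)))
  }
  if (want("audio_")) {
    a <- slices$audio
    ise <- iseFeatures(a, fs)
    add(list(audio_mean = mean(a), audio_median = median(a),
             audio_ise_range = ise$ise_range,
             audio_ise_outside = ise$time_outside,
             audio_renyi = renyiEntropy(a, fs)))
    if (any(startsWith(names_wanted, "audio_dwt")))
      add(dwtDetailEnergy(a, c(3L, 4L))[c("dwt_energy_d3", "dwt_energy_d4")] |>
            stats::setNames(c("audio_dwt_energy_d3", "audio_dwt_energy_d4")))
  }
  if (want("eog_")) {
    Wl <- welchPSD(slices$eog_l, fs); Wr <- welchPSD(slices$eog_r, fs)
    add(list(eog_delta_l = .spectralFromPSD(Wl, c(0.5, 4))$band_power,
             eog_delta_r = .spectralFromPSD(Wr, c(0.5, 4))$band_power,
             eog_beta_r = .spectralFromPSD(Wr, c(13, 30))$band_power))
  }
  if (want("ecg_")) {
    if (any(startsWith(names_wanted, "ecg_dwt"))) {
      dwf <- ecgDwtFeatures(slices$ecg, fs)
      add(stats::setNames(dwf, paste0("ecg_", names(dwf))))
    }
    if (any(names_wanted %in% c("ecg_mean_rr", "ecg_median_rr"))) {
      rr <- rrFeatures(slices$ecg, fs)
      if (rr$flagged) fl <- c(fl, "ecg_mean_rr", "ecg_median_rr")
      add(list(ecg_mean_rr = rr$mean_rr, ecg_median_rr = rr$median_rr))
    }
  }
  if ("position_code" %in% names_wanted) {
    tb <- table(round(slices$position))
    add(list(position_code = as.numeric(names(tb)[which.max(tb)])))
  }
  list(values = v[names_wanted], flagged = fl)
}

#' Extract registry features for every retained epoch
#'
#' Computes the registry's features for each non-excluded epoch of a
#' labelled \linkS4class{EpochSet}. Oximetry approximate entropy is
#' evaluated on the 1 Hz SpO2 series over a sliding context of the current
#' plus three preceding epochs (120 samples), attributed to the current
#' epoch. A missing channel required by the registry is a hard error
#' naming the first affected feature.
#'
#' @param epochs a labelled \linkS4class{EpochSet}.
#' @param registry a \linkS4class{FeatureRegistry} or registry id string.
#' @return a \linkS4class{PSGFeatureSet} (features x epochs) with assays
#'   \code{values} and \code{flagged}, rowData from the registry and
#'   colData subject_id, epoch, start_s, label.
#' @examples
#' rec <- generateRecording(subjectProfile("s01", seed = 3), duration_h = 0.5)
#' fs <- extractFeatures(prepareEpochs(rec), "subset_b_detection")
#' fs
#' @export
extractFeatures <- function(epochs, registry = "subset_b_detection") {
  stopifnot(is(epochs, "EpochSet"))
  if (is.character(registry)) registry <- featureRegistry(registry)
  defs <- registry@defs
  rec <- epochs@recording
  sig2chan <- c(thoracic = "thoracic", spo2 = "spo2", audio = "audio",
                ecg = "ecg", position = "position")
  for (i in seq_len(nrow(defs))) {
    ch <- switch(defs$signal[i], eog = c("eog_l", "eog_r"),
                 sig2chan[[defs$signal[i]]])
    if (!all(ch %in% names(rec@channels)))
      stop("channel '", paste(setdiff(ch, names(rec@channels)),
                              collapse = ","),
           "' required by feature '", defs$name[i], "' is missing")
  }
  idx <- epochs@index
  keep <- which(!idx$excluded)
  fs <- rec@fs
  spo2 <- psgChannel(rec, "spo2")
  spo2_1hz <- colMeans(matrix(spo2[seq_len(floor(length(spo2) / fs) * fs)],
                              nrow = fs))
  vals <- matrix(NA_real_, nrow(defs), length(keep),
                 dimnames = list(defs$name, NULL))
  flags <- matrix(FALSE, nrow(defs), length(keep),
                  dimnames = list(defs$name, NULL))
  need_chans <- unique(unlist(lapply(defs$signal, function(s)
    switch(s, eog = c("eog_l", "eog_r"), sig2chan[[s]]))))
  for (j in seq_along(keep)) {
    k <- keep[j]
    i0 <- idx$start_s[k] * fs
    slices <- lapply(need_chans, function(ch)
      rec@channels[[ch]][(i0 + 1L):(i0 + fs * .EPOCH_S)])
    names(slices) <- need_chans
    ctx0 <- max(0L, idx$start_s[k] - 3L * .EPOCH_S)
    ctx <- spo2_1hz[(ctx0 + 1L):min(length(spo2_1hz),
                                    idx$start_s[k] + .EPOCH_S)]
    out <- .computeEpochFeatures(slices, defs$name, ctx, fs)
    vals[, j] <- out$values
    if (length(out$flagged)) flags[out$flagged, j] <- TRUE
  }
  cd <- S4Vectors::DataFrame(subject_id = rec@subject_id,
                             epoch = idx$epoch[keep],
                             start_s = idx$start_s[keep],
                             label = idx$label[keep])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = vals, flagged = flags),
    rowData = S4Vectors::DataFrame(signal = defs$signal,
                                   category = defs$category,
                                   row.names = defs$name),
    colData = cd)
  S4Vectors::metadata(se)$registry_id <- registry@registry_id
  new("PSGFeatureSet", se)
}

#' Feature matrix and labels of a feature set
#'
#' Convenience accessors: \code{featureMatrix} returns the epochs x
#' features numeric matrix (transposed assay), \code{epochLabels} the
#' label vector, \code{epochSubjects} the subject ids.
#'
#' @param x a \linkS4class{PSGFeatureSet}.
#' @return matrix or character vector.
#' @export
featureMatrix <- function(x) t(SummarizedExperiment::assay(x, "values"))

#' @rdname featureMatrix
#' @export
epochLabels <- function(x) SummarizedExperiment::colData(x)$label

#' @rdname featureMatrix
#' @export
epochSubjects <- function(x) SummarizedExperiment::colData(x)$subject_id
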