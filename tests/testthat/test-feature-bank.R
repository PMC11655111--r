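fs100 <- 100
t30 <- (0:2999) / fs100

test_that("time statistics match closed forms", {
  ts <- timeStats(c(1, 2, 3, 4), fs = 1)
  expect_equal(ts$mean, 2.5)
  expect_equal(ts$median, 2.5)
  expect_equal(ts$iqr, 1.5)
  expect_equal(ts$std, sd(1:4))

  cs <- timeStats(rep(7, 100))
  expect_equal(cs$std, 0)
  expect_equal(cs$skewness, 0)

  # mean of |sin| is 2/pi, so the 30-s trapezoidal AUC is 30 * 2/pi
  auc <- timeStats(sin(2 * pi * 0.25 * t30))$auc
  expect_equal(auc, 30 * 2 / pi, tolerance = 5e-3)
})

test_that("peak descriptors count breaths on a clean respiratory tone", {
  ps <- peakStats(sin(2 * pi * 0.25 * t30))
  expect_equal(ps$n_peaks, 8)            # maxima at t = 1, 5, ..., 29 s
  expect_equal(ps$mean_ipd, 4, tolerance = 1e-6)
  expect_equal(ps$std_ph, 0, tolerance = 1e-9)

  expect_equal(peakStats(rep(1, 3000))$n_peaks, 0)

  two <- rep(0, 1000)
  two[c(300, 700)] <- 1                  # two identical isolated peaks
  expect_equal(peakStats(two)$n_peaks, 2)
  expect_equal(peakStats(two)$std_ph, 0)
})

test_that("Welch spectral summaries locate tones and conserve power", {
  tone <- spectralStats(sin(2 * pi * 0.3 * t30), band = c(0, 50))
  expect_lte(abs(tone$peak_freq - 0.3), 0.25)      # within one bin
  expect_equal(tone$band_power, 0.5, tolerance = 0.02)

  mf <- vapply(1:50, function(s) {
    withr::with_seed(s, spectralStats(rnorm(3000), band = c(0, 50))$mean_freq)
  }, numeric(1))
  expect_equal(mean(mf), 25, tolerance = 1)        # flat-PSD centroid
})

test_that("spectral Renyi entropy separates broadband from tonal epochs", {
  expect_equal(renyiEntropy(rep(0, 3000)), 0)
  # degenerate single-bin and uniform spectral distributions
  expect_equal(psgApnea:::.renyiFromPSD(list(psd = c(0, 5, 0))), 0)
  expect_equal(psgApnea:::.renyiFromPSD(list(psd = rep(2, 64))), log(64))

  tone <- sin(2 * pi * 0.3 * t30)
  for (s in 1:20)
    expect_gt(withr::with_seed(s, renyiEntropy(rnorm(3000))),
              renyiEntropy(tone))
})

test_that("approximate entropy follows the Pincus definition", {
  expect_equal(approximateEntropy(rep(3, 120)), 0)

  x <- withr::with_seed(4, rnorm(120))
  r <- 0.25 * sd(x)
  expect_equal(approximateEntropy(x, 2L, 0.25), oracleApEn(x, 2L, r),
               tolerance = 1e-9)

  per <- rep(c(0, 1, 0, -1), 30) * sd(x)   # period-4 deterministic
  expect_gt(approximateEntropy(x, 2L, 0.25),
            approximateEntropy(per, 2L, 0.25) + 0.3)
})

test_that("oximetry features quantify desaturation burden", {
  cst <- spo2Features(rep(97, 3000))
  expect_equal(cst$delta_index, 0)
  expect_equal(cst$tsa95, 0)
  expect_equal(cst$m2, 0)

  half <- c(rep(96, 1500), rep(93, 1500))
  expect_equal(spo2Features(half)$tsa95, 0.5)

  step <- c(rep(97, 1500), rep(93, 1500))
  expect_equal(spo2Features(step)$delta_index,
               oracleDeltaIndex(step, 100), tolerance = 1e-12)
  expect_equal(spo2Features(step)$range, 4)
  expect_equal(spo2Features(step)$m2, mean((step - mean(step))^2))
})

test_that("instantaneous spectral entropy flags nonstationary audio", {
  expect_equal(iseFeatures(rep(0, 3000))$ise_range, 0)

  outs <- vapply(1:40, function(s)
    withr::with_seed(s, iseFeatures(rnorm(3000))$time_outside), numeric(1))
  expect_lte(mean(outs), 0.1)

  for (s in 1:20) {
    stat <- withr::with_seed(s, iseFeatures(rnorm(3000))$ise_range)
    mixed <- withr::with_seed(s, iseFeatures(
      c(sin(2 * pi * 5 * t30[1:1500]), rnorm(1500)))$ise_range)
    expect_gt(mixed, stat)
  }
})

test_that("EOG rhythm powers respect band membership", {
  s2 <- sin(2 * pi * 2 * t30); s20 <- sin(2 * pi * 20 * t30)
  ep <- eogRhythmPower(s2, s2)
  expect_equal(ep$delta_r, 0.5, tolerance = 0.02)
  expect_lt(ep$beta_r, 1e-3)
  expect_equal(eogRhythmPower(s20, s20)$beta_r, 0.5, tolerance = 0.02)
  z <- eogRhythmPower(rep(0, 3000), rep(0, 3000))
  expect_equal(unlist(z), c(delta_l = 0, delta_r = 0, beta_r = 0))
})

test_that("wavelet statistics are zero, homogeneous and oracle-exact", {
  z <- ecgDwtFeatures(rep(0, 3000))
  expect_true(all(unlist(z) == 0))

  x <- withr::with_seed(8, rnorm(3000))
  f1 <- unlist(ecgDwtFeatures(x)); f3 <- unlist(ecgDwtFeatures(3 * x))
  stdish <- grep("iqr|std|mad", names(f1))
  expect_equal(f3[stdish], 3 * f1[stdish], tolerance = 1e-9)
  varish <- grep("var", names(f1))
  expect_equal(f3[varish], 9 * f1[varish], tolerance = 1e-9)

  # direct-summation oracle, including the odd-length level (750 -> 375)
  dw <- psgApnea:::dwtDb4(x, 5L)
  or <- oracleDwt(x, 5L, psgApnea:::.db4lo, psgApnea:::.db4hi)
  for (l in 1:5)
    expect_equal(dw[[paste0("d", l)]], or[[paste0("d", l)]],
                 tolerance = 1e-9)
})

test_that("RR summaries recover the programmed heart rate", {
  # clean template train at exactly 60 bpm: detector within 10 ms
  tt <- (0:29999) / 100
  clean <- rowSums(sapply(seq(0.5, 299, by = 1), function(b)
    exp(-((tt - b) / 0.012)^2 / 2)))
  rrc <- rrFeatures(clean[1:3000])
  expect_false(rrc$flagged)
  expect_equal(rrc$mean_rr, 1, tolerance = 0.01)

  # generator output: programmed rate within its slow 3% HR variability
  noev <- data.frame(class = character(0), onset = numeric(0),
                     duration = numeric(0))
  for (bpm in c(60, 75)) {
    p <- subjectProfile("rr", heart_rate = bpm, seed = 77)
    ecg <- synthAncillary(noev, p, 300)$ecg
    rr <- rrFeatures(ecg[3000:30000])
    expect_false(rr$flagged)
    expect_equal(rr$mean_rr, 60 / bpm, tolerance = 0.04 * 60 / bpm)
    expect_equal(rr$mean_rr, rr$median_rr, tolerance = 0.05 * rr$mean_rr)
  }
  expect_true(rrFeatures(rep(0, 3000))$flagged)
})

test_that("DC offsets leave scale-free features untouched", {
  x <- withr::with_seed(9, rnorm(3000))
  a <- timeStats(x); b <- timeStats(x + 50)
  expect_equal(a$std, b$std); expect_equal(a$iqr, b$iqr)
  expect_equal(a$skewness, b$skewness, tolerance = 1e-9)

  pa <- peakStats(x); pb <- peakStats(x + 50)   # PH from the median
  expect_equal(pa$n_peaks, pb$n_peaks)
  expect_equal(pa$mean_ph, pb$mean_ph, tolerance = 1e-9)

  expect_equal(approximateEntropy(x), approximateEntropy(x + 50),
               tolerance = 1e-12)

  da <- unlist(ecgDwtFeatures(x)); db <- unlist(ecgDwtFeatures(x + 50))
  expect_equal(da, db, tolerance = 1e-6)        # details kill constants
})

test_that("extraction follows the registry and is deterministic", {
  ep <- prepareEpochs(fixRecording())
  f32 <- extractFeatures(ep, "subset_b_detection")
  expect_equal(nrow(f32), 32L)
  expect_identical(rownames(f32), registryDefs(
    featureRegistry("subset_b_detection"))$name)

  f44 <- extractFeatures(ep, "subset_iii_distinction")
  expect_equal(nrow(f44), 44L)

  again <- extractFeatures(ep, "subset_b_detection")
  expect_identical(SummarizedExperiment::assay(f32, "values"),
                   SummarizedExperiment::assay(again, "values"))

  broken <- fixRecording()
  broken@channels$audio <- NULL
  expect_error(extractFeatures(prepareEpochs(broken), "subset_b_detection"),
               "audio")
})

test_that("event epochs shift the expected features in the expected direction", {
  fs <- fixCohort()
  v <- featureMatrix(fs); lab <- epochLabels(fs)
  stopifnot(sum(lab == "CSA") >= 10, sum(lab == "NORMAL") >= 50)
  pl <- function(f, cls) v[lab == cls, f]
  # central apneas suppress thoracic respiratory power
  expect_lt(t.test(pl("thor_band_power", "CSA"),
                   pl("thor_band_power", "NORMAL"),
                   alternative = "less")$p.value, 0.01)
  # apneic epochs desaturate: higher hypoxic burden, lower minimum
  for (cls in c("OSA", "CSA", "MSA")) {
    expect_lt(t.test(pl("spo2_tsa95", cls), pl("spo2_tsa95", "NORMAL"),
                     alternative = "greater")$p.value, 0.05)
    expect_lt(t.test(pl("spo2_min", cls), pl("spo2_min", "NORMAL"),
                     alternative = "less")$p.value, 0.01)
  }
})
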