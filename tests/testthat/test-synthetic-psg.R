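test_that("event scheduling respects rate, durations, gaps and determinism", {
  expect_equal(nrow(scheduleEvents(3600, 0, seed = 1)), 0L)
  expect_error(scheduleEvents(3600, 10, c(OSA = 0.8, HYP = 0.1)),
               "sum to 1")

  mix <- c(OSA = 1, HYP = 0, CSA = 0, MSA = 0)
  counts <- vapply(1:100, function(s)
    nrow(scheduleEvents(3600, 20, mix, seed = s)), numeric(1))
  # total of 100 draws at rate 20/h ~ Poisson(2000); 95% interval
  expect_gt(sum(counts), 2000 - 1.96 * sqrt(2000))
  expect_lt(sum(counts), 2000 + 1.96 * sqrt(2000))

  ev <- scheduleEvents(3600, 20, mix, seed = 7)
  expect_true(all(ev$class == "OSA"))
  expect_true(all(ev$duration >= 10 & ev$duration <= 120))
  if (nrow(ev) > 1)  # >= 15 s between consecutive events
    expect_true(all(ev$onset[-1] - (ev$onset + ev$duration)[-nrow(ev)] >= 15))
  expect_identical(ev, scheduleEvents(3600, 20, mix, seed = 7))
})

test_that("event durations concentrate in the typical 20-40 s range", {
  ev <- scheduleEvents(20 * 3600, 30, seed = 5)
  frac <- mean(ev$duration >= 20 & ev$duration <= 40)
  expect_gt(frac, 0.5)
  expect_lt(frac, 0.7)
})

prof <- subjectProfile("t1", resp_rate = 0.25, heart_rate = 60, seed = 42)

test_that("thoracic effort collapses in CSA, persists in OSA", {
  none <- synthThoracic(data.frame(class = character(0), onset = numeric(0),
                                   duration = numeric(0)), prof, 600)
  # envelope stability: coefficient of variation of 10-s RMS windows
  rms <- sqrt(colMeans(matrix(none^2, nrow = 1000)))
  expect_lt(sd(rms) / mean(rms), 0.3)

  rmsRatio <- function(cls) {
    ev <- data.frame(class = cls, onset = 120, duration = 40)
    x <- synthThoracic(ev, prof, 300)
    inn <- x[(120 * 100 + 300):(160 * 100 - 300)]
    out <- x[1:(100 * 100)]
    sqrt(mean(inn^2)) / sqrt(mean(out^2))
  }
  expect_lt(rmsRatio("CSA"), 0.1)
  expect_gt(rmsRatio("OSA"), 0.7)
  hyp <- rmsRatio("HYP")
  expect_gt(hyp, 0.25); expect_lt(hyp, 0.8)
})

test_that("mixed apnea is central first, obstructive second", {
  ev <- data.frame(class = "MSA", onset = 100, duration = 60)
  x <- synthThoracic(ev, prof, 300)
  first <- x[(100 * 100):(120 * 100)]   # within the central 40-60%
  last <- x[(145 * 100):(160 * 100)]
  expect_lt(sqrt(mean(first^2)) / sqrt(mean(last^2)), 0.2)
})

test_that("SpO2 baseline is stable and desaturations are lagged and deep", {
  noev <- data.frame(class = character(0), onset = numeric(0),
                     duration = numeric(0))
  x0 <- synthSpo2(noev, prof, 1200)
  expect_gte(min(x0), prof@baseline_spo2 - 1.5)

  ev <- data.frame(class = "OSA", onset = 600, duration = 30)
  x1 <- synthSpo2(ev, prof, 1200)
  tmin <- (which.min(x1) - 1) / 100
  expect_gte(tmin, 610); expect_lte(tmin, 680)
  expect_lte(min(x1), prof@baseline_spo2 - 3)

  # locality: identical outside [onset, onset + duration + 60]
  outside <- c(seq_len(600 * 100 - 1), (690 * 100 + 1):(1200 * 100))
  expect_identical(x0[outside], x1[outside])
})

test_that("desaturation depth orders full apneas above hypopneas", {
  depth <- function(cls, seed) {
    p <- subjectProfile("d1", seed = seed)
    ev <- data.frame(class = cls, onset = 60, duration = 30)
    p@baseline_spo2 - min(synthSpo2(ev, p, 240))
  }
  d <- sapply(c(OSA = "OSA", CSA = "CSA", MSA = "MSA", HYP = "HYP"),
              function(cl) mean(vapply(1:40, function(s)
                depth(cl, s), numeric(1))))
  expect_gt(d["OSA"], d["HYP"] + 1)
  expect_gt(d["CSA"], d["HYP"] + 1)
  expect_gt(d["MSA"], d["HYP"] + 1)
  expect_lt(max(d[1:3]) - min(d[1:3]), 0.5)   # apneas alike
})

test_that("ancillary channels carry the event physiology", {
  ev <- data.frame(class = "CSA", onset = 120, duration = 40)
  anc <- synthAncillary(ev, prof, 400)
  blockRms <- sqrt(colMeans(matrix(anc$audio[1:(400 * 100)]^2, nrow = 100)))
  inn <- sqrt(mean(anc$audio[(121 * 100):(159 * 100)]^2))
  expect_lt(inn, 0.2 * median(blockRms))

  # RR lengthens before termination, shortens after
  term <- 160
  rrpre <- rrFeatures(anc$ecg[((term - 20) * 100):(term * 100)])
  rrpost <- rrFeatures(anc$ecg[(term * 100):((term + 10) * 100)])
  expect_false(rrpre$flagged); expect_false(rrpost$flagged)
  expect_lt(rrpost$mean_rr, rrpre$mean_rr)

  expect_true(all(anc$position %in% 0:4))
})

test_that("recordings have the documented shape, grid and determinism", {
  rec <- fixRecording()
  expect_equal(length(psgChannel(rec, "thoracic")), 180000L)
  expect_equal(length(hypnogram(rec)), 60L)

  rec2 <- generateRecording(subjectProfile("fx01", seed = 301),
                            duration_h = 0.5, event_rate_per_h = 20,
                            class_mix = allClassMix(),
                            wake_fraction = 0.1, detach_rate = 1)
  expect_identical(rec@channels, rec2@channels)
  expect_identical(psgEvents(rec), psgEvents(rec2))

  # 16-bit midtread grid over the physical range
  x <- psgChannel(rec, "eog_l")
  q <- 600 / (2^16 - 1)
  expect_lt(max(abs((x + 300) / q - round((x + 300) / q))), 1e-6)

  expect_error(generateRecording(subjectProfile("z", seed = 1),
                                 duration_h = 0.2), "duration_h")
  expect_error(generateRecording(subjectProfile("z", seed = 1),
                                 wake_fraction = 0.9), "wake_fraction")
})

test_that("wake flags hit the requested fraction on event-free epochs", {
  rec <- generateRecording(subjectProfile("w1", seed = 9), duration_h = 1,
                           event_rate_per_h = 5, wake_fraction = 0.2)
  expect_lte(abs(sum(hypnogram(rec)) - 24), 1)
  ev <- psgEvents(rec)
  for (k in which(hypnogram(rec))) {
    s0 <- (k - 1) * 30
    expect_true(!nrow(ev) ||
                all(ev$onset >= s0 + 30 | ev$onset + ev$duration <= s0))
  }
})

test_that("output channels keep >99% of their power below 30 Hz", {
  rec <- fixRecording()
  for (ch in c("thoracic", "spo2", "audio", "eog_l", "eog_r", "ecg")) {
    x <- psgChannel(rec, ch)
    x <- x - mean(x)
    W <- psgApnea:::welchPSD(x, 100, nper = 2000)
    expect_gt(sum(W$psd[W$freq < 30]) / sum(W$psd), 0.99)
  }
})
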