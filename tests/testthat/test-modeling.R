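# two-subject-per-blob separable toy problem used across model tests
toyData <- function(n = 200, gap = 4, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n, 0), n / 2, 2),
               matrix(rnorm(n, gap), n / 2, 2))
    colnames(x) <- c("u", "v")
    list(x = x,
         y = factor(rep(c("neg", "pos"), each = n / 2)),
         subj = sprintf("s%02d", rep(1:10, length.out = n)))
  })
}

test_that("confusion metrics follow the printed formulas", {
  m <- computeMetrics(9, 1, 8, 2)
  expect_equal(m$sens, 0.9)
  expect_equal(m$spec, 0.8)
  expect_equal(m$ppv, 9 / 11)
  expect_equal(m$npv, 8 / 9)
  expect_equal(m$acc, 17 / 20)

  perfect <- computeMetrics(7, 0, 13, 0)
  expect_true(all(unlist(perfect) == 1))

  nopos <- computeMetrics(0, 0, 5, 5)
  expect_true(is.na(nopos$sens))   # undefined, flagged, never zero
  expect_equal(nopos$spec, 0.5)

  expect_error(computeMetrics(0, 0, 0, 0), "zero")
})

test_that("random search is deterministic and finds separable optima", {
  td <- toyData()
  sp <- modelSpec("svm", budget = 8L, seed = 11L)
  f1 <- tuneAndTrain(sp, td$x, td$y, td$subj)
  f2 <- tuneAndTrain(sp, td$x, td$y, td$subj)
  expect_identical(f1$config, f2$config)
  expect_gte(f1$cv_accuracy, 0.99)
  expect_equal(mean(f1$predict(td$x) == td$y), 1, tolerance = 0.01)

  kn <- tuneAndTrain(modelSpec("knn", search_space = list(k = c(1L, 5L)),
                               budget = 6L, seed = 12L), td$x, td$y, td$subj)
  expect_gte(mean(kn$predict(td$x) == td$y), 0.95)

  expect_error(tuneAndTrain(sp, td$x, factor(rep("a", nrow(td$x)))),
               "single-class")
})

test_that("every family trains and predicts on clean structure", {
  td <- toyData(n = 160)
  for (fam in c("decision_tree", "discriminant", "naive_bayes", "knn")) {
    fit <- tuneAndTrain(modelSpec(fam, budget = 4L, seed = 21L),
                        td$x, td$y, td$subj)
    expect_gte(mean(fit$predict(td$x) == td$y), 0.9)
  }
})

test_that("balanced evaluation satisfies the prevalence-0.5 identity", {
  ev <- evaluateCase(fixCohort(), caseConfig("i"),
                     list(svm = modelSpec("svm",
                                          search_space = list(kernel = "linear"),
                                          budget = 2L)),
                     repeats = 2L, seed = 31)
  pr <- ev$reports$svm@per_repeat
  expect_true(all(pr$tp + pr$fn == pr$tn + pr$fp))
  expect_equal(pr$acc, (pr$sens + pr$spec) / 2, tolerance = 1e-9)
  expect_s4_class(ev$reports$svm, "MetricsReport")
  expect_true(ev$best_family %in% names(ev$reports))
})

test_that("the distinction case runs end to end on cohort data", {
  fs44 <- fixture("cohort44", function()
    cohortFeatures(6, "subset_iii_distinction", duration_h = 0.75,
                   event_rate_per_h = 15, class_mix = allClassMix(),
                   seed = 302))
  ev <- evaluateCase(fs44, caseConfig("iii"),
                     list(tree = modelSpec("decision_tree", budget = 3L)),
                     repeats = 2L, seed = 33)
  s <- metricsSummary(ev$reports$tree)
  expect_true(all(s$mean[!is.na(s$mean)] >= 0 & s$mean[!is.na(s$mean)] <= 1))
  # every repeat keeps the positives (OSA+MSA) against CSA only
  expect_gt(s$mean[s$metric == "acc"], 0.5)
})

test_that("label shuffling collapses performance to chance", {
  ev <- evaluateCase(fixCohort(), caseConfig("i"),
                     list(svm = modelSpec("svm",
                                          search_space = list(kernel = "linear",
                                                              log10_cost = c(-2, 0)),
                                          budget = 2L)),
                     repeats = 3L, seed = 35, shuffle_labels = TRUE)
  acc <- ev$reports$svm@summary
  expect_lt(abs(acc$mean[acc$metric == "acc"] - 0.5), 0.12)
})
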