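test_that("case configurations encode the three dichotomies", {
  ci <- caseConfig("i")
  expect_setequal(ci@positive_classes, c("OSA", "CSA", "MSA"))
  expect_setequal(ci@negative_classes, c("NORMAL", "HYP"))
  expect_equal(ci@registry_id, "subset_b_detection")

  cii <- caseConfig("ii")
  expect_equal(cii@negative_classes, "NORMAL")

  ciii <- caseConfig("iii")
  expect_setequal(ciii@positive_classes, c("OSA", "MSA"))
  expect_equal(ciii@negative_classes, "CSA")
  expect_equal(ciii@registry_id, "subset_iii_distinction")
})

test_that("subject splits are disjoint, sized and deterministic", {
  ids <- sprintf("s%02d", 1:10)
  sp <- subjectSplit(ids, 0.7, seed = 3)
  expect_length(sp@train_subjects, 7L)
  expect_length(sp@test_subjects, 3L)
  expect_length(intersect(sp@train_subjects, sp@test_subjects), 0L)
  expect_setequal(c(sp@train_subjects, sp@test_subjects), ids)
  expect_identical(sp@train_subjects,
                   subjectSplit(ids, 0.7, seed = 3)@train_subjects)
  expect_error(subjectSplit("only_one"), "2 subjects")
})

test_that("detection balancing equalizes the class counts", {
  tab <- makeEpochTable(c(OSA = 60, MSA = 25, CSA = 15, NORMAL = 400,
                          HYP = 100))
  bal <- balanceDetection(tab, caseConfig("i"), seed = 5)
  expect_equal(sum(bal$positive), 100L)
  expect_equal(sum(!bal$positive), 100L)
  expect_true(all(bal$label[bal$positive] %in% c("OSA", "MSA", "CSA")))

  # case ii ignores HYP rows entirely
  bal2 <- balanceDetection(tab, caseConfig("ii"), seed = 5)
  expect_false("HYP" %in% bal2$label)

  # equal counts stay unchanged
  eq <- makeEpochTable(c(OSA = 50, NORMAL = 50))
  bal3 <- balanceDetection(eq, caseConfig("ii"), seed = 1)
  expect_equal(nrow(bal3), 100L)

  # minority negatives flip the subsampling direction
  few <- makeEpochTable(c(OSA = 80, NORMAL = 30))
  expect_message(bal4 <- balanceDetection(few, caseConfig("ii"), seed = 1),
                 "fewer negatives")
  expect_equal(sum(bal4$positive), 30L)
  expect_equal(sum(!bal4$positive), 30L)
})

test_that("distinction balancing keeps MSA and caps the ratios", {
  tab <- makeEpochTable(c(MSA = 50, OSA = 500, CSA = 100, NORMAL = 10))
  bal <- balanceDistinction(tab, cap = 5, seed = 2)
  cnt <- table(bal$label)
  expect_equal(unname(cnt["MSA"]), 50L)
  expect_equal(unname(cnt["OSA"]), 250L)   # 10:1 rescaled to the cap
  expect_equal(unname(cnt["CSA"]), 50L)    # 2:1 rescaled by the same factor
  expect_false("NORMAL" %in% names(cnt))
  # every MSA row is retained
  expect_setequal(rownames(bal)[bal$label == "MSA"],
                  rownames(tab)[tab$label == "MSA"])

  # already proportioned within the cap: nothing is dropped
  ok <- makeEpochTable(c(MSA = 50, OSA = 120, CSA = 60))
  bal2 <- balanceDistinction(ok, cap = 5, seed = 2)
  expect_equal(nrow(bal2), 230L)

  expect_error(balanceDistinction(makeEpochTable(c(MSA = 5, OSA = 5))),
               "present")
})

test_that("balancing subsamples negatives without distorting them", {
  pvals <- vapply(1:200, function(s) {
    tab <- makeEpochTable(c(OSA = 60, NORMAL = 300), seed = 99)
    bal <- balanceDetection(tab, caseConfig("ii"), seed = s)
    stats::ks.test(bal$feat[!bal$positive],
                   tab$feat[tab$label == "NORMAL"])$p.value
  }, numeric(1))
  # nominal rejection behaviour (subsample-vs-parent KS is conservative)
  expect_lte(mean(pvals < 0.05), 0.06)
})
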