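## The three dichotomous case studies with subject-wise splitting and
## case-wise class balancing: (i) apnea vs normal/hypopnea, (ii) apnea vs
## normal (hypopnea epochs dropped), (iii) OSA/MSA vs CSA.

.APNEA_CLASSES <- c("OSA", "CSA", "MSA")

#' Configure a dichotomous case study
#'
#' @param case_id "i" (apnea vs NORMAL+HYP), "ii" (apnea vs NORMAL, HYP
#'   dropped) or "iii" (OSA/MSA vs CSA, NORMAL/HYP dropped).
#' @param registry_id feature registry backing the case (detection subset
#'   for i/ii, distinction subset for iii).
#' @param cap largest-class cap factor for distinction balancing.
#' @param seed integer seed for balancing draws.
#' @return a \linkS4class{CaseConfig}.
#' @examples
#' caseConfig("i")
#' @export
caseConfig <- function(case_id = c("i", "ii", "iii"), registry_id = NULL,
                       cap = 5, seed = 1L) {
  case_id <- match.arg(case_id)
  if (is.null(registry_id))
    registry_id <- if (case_id == "iii") "subset_iii_distinction"
                   else "subset_b_detection"
  pos <- switch(case_id, i = .APNEA_CLASSES, ii = .APNEA_CLASSES,
                iii = c("OSA", "MSA"))
  neg <- switch(case_id, i = c("NORMAL", "HYP"), ii = "NORMAL", iii = "CSA")
  new("CaseConfig", case_id = case_id, positive_classes = pos,
      negative_classes = neg, registry_id = registry_id, cap = cap,
      seed = as.integer(seed))
}

#' Subject-wise train/test split
#'
#' \code{round(fraction * n)} subjects go to training; the split is
#' deterministic under \code{seed} and the two sets are disjoint by
#' construction, so no subject contributes epochs to both.
#'
#' @param subject_ids character vector of (unique) subject ids.
#' @param fraction training fraction.
#' @param seed integer seed.
#' @return a \linkS4class{SplitPlan}.
#' @export
subjectSplit <- function(subject_ids, fraction = 0.7, seed = 1L) {
  subject_ids <- unique(as.character(subject_ids))
  if (length(subject_ids) < 2L) stop("need at least 2 subjects")
  n_train <- round(fraction * length(subject_ids))
  n_train <- min(max(n_train, 1L), length(subject_ids) - 1L)
  train <- withSeed(seed, sample(subject_ids, n_train))
  new("SplitPlan", train_subjects = sort(train),
      test_subjects = sort(setdiff(subject_ids, train)),
      fraction = fraction)
}

## subset rows of an epoch table (data.frame with a label column)
.rowsWithLabels <- function(tab, classes) tab[tab$label %in% classes, ,
                                              drop = FALSE]

#' Balance a detection case (i or ii)
#'
#' Keeps every apnea (positive) row and randomly subsamples the negatives
#' without replacement to the same count. If negatives are the minority
#' the positives are subsampled down instead (with a message). Rows whose
#' label belongs to neither side (HYP in case ii) are dropped first.
#' Applied to the training and test split separately by the evaluation
#' driver.
#'
#' @param epoch_table data.frame with at least a \code{label} column.
#' @param case_config a \linkS4class{CaseConfig} (case i or ii).
#' @param seed integer seed for the subsampling draw.
#' @return the balanced table with a new logical column \code{positive}.
#' @export
balanceDetection <- function(epoch_table, case_config, seed = NULL) {
  stopifnot(is(case_config, "CaseConfig"))
  pos <- .rowsWithLabels(epoch_table, case_config@positive_classes)
  neg <- .rowsWithLabels(epoch_table, case_config@negative_classes)
  if (!nrow(pos) || !nrow(neg))
    stop("both classes must be present before balancing")
  withSeed(seed, {
    if (nrow(neg) >= nrow(pos)) {
      neg <- neg[sample(nrow(neg), nrow(pos)), , drop = FALSE]
    } else {
      message("fewer negatives than positives; subsampling positives down")
      pos <- pos[sample(nrow(pos), nrow(neg)), , drop = FALSE]
    }
    out <- rbind(pos, neg)
    out$positive <- c(rep(TRUE, nrow(pos)), rep(FALSE, nrow(neg)))
    out
  })
}

#' Balance the distinction case (iii)
#'
#' Keeps all MSA rows (the least represented apnea class) and subsamples
#' OSA and CSA so their count ratios to MSA match the full table, rescaled
#' by a common factor so that the largest class does not exceed
#' \code{cap} times the MSA count.
#'
#' @param epoch_table data.frame with a \code{label} column containing
#'   MSA, OSA and CSA rows.
#' @param cap largest-class cap factor.
#' @param seed integer seed.
#' @return the balanced table (MSA, OSA, CSA rows only).
#' @export
balanceDistinction <- function(epoch_table, cap = 5, seed = NULL) {
  counts <- vapply(c("MSA", "OSA", "CSA"), function(cl)
    sum(epoch_table$label == cl), numeric(1))
  if (any(counts == 0)) stop("MSA, OSA and CSA must all be present")
  ratios <- counts[c("OSA", "CSA")] / counts["MSA"]
  s <- min(1, cap / max(ratios, 1))
  withSeed(seed, {
    keep <- epoch_table[epoch_table$label == "MSA", , drop = FALSE]
    for (cl in c("OSA", "CSA")) {
      rows <- which(epoch_table$label == cl)
      target <- round(counts["MSA"] * ratios[[cl]] * s)
      target <- min(target, length(rows))
      keep <- rbind(keep,
                    epoch_table[sample(rows, target), , drop = FALSE])
    }
    keep
  })
}
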