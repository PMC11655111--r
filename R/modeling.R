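## Classical-model training and evaluation: the five model families,
## random hyperparameter search scored by subject-grouped 5-fold CV, and
## the repeated balanced evaluation reported as mean +/- SD of
## sensitivity, specificity, predictive values and accuracy.

#' Confusion-matrix metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), PPV TP/(TP+FP),
#' NPV TN/(TN+FN), accuracy (TP+TN)/N. A zero-denominator ratio is
#' returned as NA (flagged undefined), never as 0.
#'
#' @param tp,fn,tn,fp non-negative confusion counts (total > 0).
#' @return named list: sens, spec, ppv, npv, acc.
#' @examples
#' computeMetrics(9, 1, 8, 2)
#' @export
computeMetrics <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  if (tp + fn + tn + fp == 0) stop("all confusion counts are zero")
  rat <- function(a, b) if (b > 0) a / b else NA_real_
  list(sens = rat(tp, tp + fn), spec = rat(tn, tn + fp),
       ppv = rat(tp, tp + fp), npv = rat(tn, tn + fn),
       acc = (tp + tn) / (tp + fn + tn + fp))
}

#' Construct a model specification
#'
#' @param family one of decision_tree, discriminant, naive_bayes, svm,
#'   knn.
#' @param search_space named list overriding parts of the family's default
#'   hyperparameter space (see the vignette for the spaces).
#' @param budget number of random-search evaluations.
#' @param cv_folds subject-grouped cross-validation folds.
#' @param seed integer seed making the search deterministic.
#' @return a \linkS4class{ModelSpec}.
#' @examples
#' modelSpec("svm", search_space = list(kernel = "linear"), budget = 5L)
#' @export
modelSpec <- function(family, search_space = list(), budget = 200L,
                      cv_folds = 5L, seed = 1L) {
  new("ModelSpec", family = family, search_space = search_space,
      budget = as.integer(budget), cv_folds = as.integer(cv_folds),
      seed = as.integer(seed))
}

.defaultSpace <- function(family) {
  switch(family,
    decision_tree = list(maxdepth = c(1L, 30L), minbucket = c(1L, 50L)),
    discriminant = list(type = c("linear", "quadratic")),
    naive_bayes = list(laplace = c(0, 0)),
    svm = list(kernel = c("linear", "radial"), log10_cost = c(-2, 2),
               log10_gamma = c(-3, 1)),
    knn = list(k = c(1L, 50L), metric = c("euclidean", "cosine")))
}

## one random draw from the (possibly overridden) space
.sampleConfig <- function(family, space) {
  pick <- function(v) if (length(v) == 1L) v else sample(v, 1L)
  rng <- function(v) if (is.integer(space[[v]]))
    sample(space[[v]][1]:space[[v]][2], 1L)
  else runif(1, space[[v]][1], space[[v]][2])
  switch(family,
    decision_tree = list(maxdepth = rng("maxdepth"),
                         minbucket = rng("minbucket")),
    discriminant = list(type = pick(space$type)),
    naive_bayes = list(laplace = 0),
    svm = {
      k <- pick(space$kernel)
      list(kernel = k, cost = 10^runif(1, space$log10_cost[1],
                                       space$log10_cost[2]),
           gamma = if (k == "radial")
             10^runif(1, space$log10_gamma[1], space$log10_gamma[2])
           else NA_real_)
    },
    knn = list(k = rng("k"), metric = pick(space$metric)))
}

## fit one configured model on x (epochs x features, already imputed and
## z-scored) with factor labels y; returns an object .predictFit can use
.fitConfig <- function(family, config, x, y) {
  switch(family,
    decision_tree = {
      d <- data.frame(y = y, x)
      rpart::rpart(y ~ ., data = d, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = config$maxdepth,
                     minbucket = config$minbucket, cp = 1e-4, xval = 0))
    },
    discriminant = if (config$type == "linear") MASS::lda(x, grouping = y)
                   else MASS::qda(x, grouping = y),
    naive_bayes = e1071::naiveBayes(x, y, laplace = config$laplace),
    svm = e1071::svm(x, y, kernel = config$kernel, cost = config$cost,
                     gamma = if (is.na(config$gamma)) 1 / ncol(x)
                             else config$gamma, scale = FALSE),
    knn = list(train = x, y = y, k = config$k, metric = config$metric))
}

.predictFit <- function(family, fit, x) {
  switch(family,
    decision_tree = predict(fit, newdata = data.frame(x), type = "class"),
    discriminant = predict(fit, x)$class,
    naive_bayes = predict(fit, x),
    svm = predict(fit, x),
    knn = {
      tr <- fit$train; te <- x
      if (fit$metric == "cosine") {   # unit rows: cosine == euclidean order
        nr <- sqrt(rowSums(tr^2)); nr[nr == 0] <- 1
        tr <- tr / nr
        nr <- sqrt(rowSums(te^2)); nr[nr == 0] <- 1
        te <- te / nr
      }
      class::knn(tr, te, fit$y, k = min(fit$k, nrow(tr)))
    })
}

## training-median imputation + z-scoring fitted on the training rows
.fitPreproc <- function(x) {
  med <- apply(x, 2, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- med[j]
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(median = med, center = mu, scale = sdv,
       apply = function(z) {
         for (j in seq_len(ncol(z))) z[is.na(z[, j]), j] <- med[j]
         sweep(sweep(z, 2, mu, "-"), 2, sdv, "/")
       })
}

#' Tune and train one model family
#'
#' Random hyperparameter search over the family's space: \code{budget}
#' configurations are drawn, each scored by subject-grouped
#' \code{cv_folds}-fold cross-validated accuracy on the training table
#' (folds never split a subject), and the best configuration is refit on
#' all training rows. Features are median-imputed and z-scored with
#' statistics from the full training table (per fold, from the fold's
#' training part). Deterministic under the spec's seed.
#'
#' @param model_spec a \linkS4class{ModelSpec}.
#' @param train_table numeric matrix, epochs x features.
#' @param labels factor (or coercible) with exactly 2 levels.
#' @param subjects subject id per row, for grouped folds (one pseudo
#'   subject per row when NULL).
#' @return list with elements family, config, cv_accuracy, fit, preproc
#'   and a \code{predict(newdata)} closure.
#' @export
tuneAndTrain <- function(model_spec, train_table, labels, subjects = NULL) {
  stopifnot(is(model_spec, "ModelSpec"))
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("degenerate single-class training input")
  if (is.null(subjects)) subjects <- as.character(seq_len(nrow(train_table)))
  family <- model_spec@family
  space <- utils::modifyList(.defaultSpace(family), model_spec@search_space)
  withSeed(model_spec@seed, {
    su <- unique(subjects)
    fold_of <- sample(rep_len(seq_len(min(model_spec@cv_folds, length(su))),
                              length(su)))
    names(fold_of) <- su
    folds <- fold_of[subjects]
    configs <- lapply(seq_len(model_spec@budget), function(i)
      .sampleConfig(family, space))
    scores <- vapply(configs, function(cf) {
      accs <- vapply(unique(folds), function(f) {
        tr <- folds != f
        if (nlevels(droplevels(y[tr])) < 2L) return(NA_real_)
        pp <- .fitPreproc(train_table[tr, , drop = FALSE])
        fit <- try(.fitConfig(family, cf,
                              pp$apply(train_table[tr, , drop = FALSE]),
                              y[tr]), silent = TRUE)
        if (inherits(fit, "try-error")) return(NA_real_)
        ph <- try(.predictFit(family, fit,
                              pp$apply(train_table[!tr, , drop = FALSE])),
                  silent = TRUE)
        if (inherits(ph, "try-error")) return(NA_real_)
        mean(ph == y[!tr])
      }, numeric(1))
      if (all(is.na(accs))) -Inf else mean(accs, na.rm = TRUE)
    }, numeric(1))
    best <- configs[[which.max(scores)]]
    pp <- .fitPreproc(train_table)
    fit <- .fitConfig(family, best, pp$apply(train_table), y)
    list(family = family, config = best,
         cv_accuracy = max(scores), fit = fit, preproc = pp,
         predict = function(newdata)
           .predictFit(family, fit, pp$apply(newdata)))
  })
}

## assemble the epoch table (label, subject + features) for one case
.caseTable <- function(features, case_config) {
  x <- featureMatrix(features)
  tab <- data.frame(label = epochLabels(features),
                    subject = epochSubjects(features),
                    stringsAsFactors = FALSE)
  wanted <- switch(case_config@case_id,
                   i = c(case_config@positive_classes, "NORMAL", "HYP"),
                   ii = c(case_config@positive_classes, "NORMAL"),
                   iii = c("OSA", "MSA", "CSA"))
  keep <- tab$label %in% wanted
  list(tab = tab[keep, , drop = FALSE], x = x[keep, , drop = FALSE])
}

#' Evaluate a case study end to end
#'
#' For each repeat: re-draw the case-wise balancing on the training and
#' test splits separately (fresh substream), tune and train every family
#' on the balanced training rows, predict the balanced test rows, and
#' compute the confusion metrics. The subject-wise 70/30 split is fixed
#' across repeats; the reported SD therefore reflects balancing (and
#' search) variability. The best family maximises min(sens, spec) among
#' families whose mean accuracy is within one SD of the best accuracy.
#'
#' @param features a \linkS4class{PSGFeatureSet} for the whole cohort.
#' @param case_config a \linkS4class{CaseConfig}.
#' @param model_specs named list of \linkS4class{ModelSpec}; default one
#'   spec per family with a small search budget.
#' @param repeats number of re-balanced evaluations.
#' @param fraction training fraction of subjects.
#' @param seed root seed (split, balancing and search substreams).
#' @param shuffle_labels permute epoch labels per repeat before balancing
#'   (null-calibration mode).
#' @return list with \code{reports} (named \linkS4class{MetricsReport}
#'   per family), \code{best_family}, and \code{split} (the
#'   \linkS4class{SplitPlan}).
#' @export
evaluateCase <- function(features, case_config, model_specs = NULL,
                         repeats = 20L, fraction = 0.7, seed = 1L,
                         shuffle_labels = FALSE) {
  stopifnot(is(features, "PSGFeatureSet"), is(case_config, "CaseConfig"))
  if (is.null(model_specs)) {
    fams <- c("decision_tree", "discriminant", "naive_bayes", "svm", "knn")
    model_specs <- lapply(fams, modelSpec, budget = 20L)
    names(model_specs) <- fams
  }
  ct <- .caseTable(features, case_config)
  split <- subjectSplit(unique(ct$tab$subject), fraction,
                        seed = substreamSeed(seed, "split"))
  per <- lapply(names(model_specs), function(f) list())
  names(per) <- names(model_specs)
  for (r in seq_len(repeats)) {
    tab <- ct$tab; x <- ct$x
    if (shuffle_labels)
      tab$label <- withSeed(substreamSeed(seed, paste0("shuffle-", r)),
                            sample(tab$label))
    tab$row_id <- seq_len(nrow(tab))
    bal <- function(rows, tag) {
      sub <- tab[rows, , drop = FALSE]
      s <- substreamSeed(seed, paste0("balance-", tag, "-", r))
      if (case_config@case_id == "iii") {
        out <- balanceDistinction(sub, cap = case_config@cap, seed = s)
        out$positive <- out$label %in% case_config@positive_classes
        out
      } else balanceDetection(sub, case_config, seed = s)
    }
    trs <- bal(tab$subject %in% split@train_subjects, "trs")
    ts <- bal(tab$subject %in% split@test_subjects, "ts")
    ytest <- factor(ts$positive, levels = c(FALSE, TRUE))
    for (f in names(model_specs)) {
      sp <- model_specs[[f]]
      sp@seed <- substreamSeed(seed, paste0("tune-", f, "-", r))
      fit <- tuneAndTrain(sp, ct$x[trs$row_id, , drop = FALSE],
                          factor(trs$positive, levels = c(FALSE, TRUE)),
                          subjects = trs$subject)
      pred <- fit$predict(ct$x[ts$row_id, , drop = FALSE])
      tp <- sum(pred == "TRUE" & ytest == "TRUE")
      fn <- sum(pred == "FALSE" & ytest == "TRUE")
      tn <- sum(pred == "FALSE" & ytest == "FALSE")
      fp <- sum(pred == "TRUE" & ytest == "FALSE")
      met <- computeMetrics(tp, fn, tn, fp)
      per[[f]][[r]] <- data.frame(repeat_ = r, tp = tp, fn = fn, tn = tn,
                                  fp = fp, sens = met$sens, spec = met$spec,
                                  ppv = met$ppv, npv = met$npv,
                                  acc = met$acc)
    }
  }
  reports <- lapply(per, function(rows) {
    pr <- do.call(rbind, rows)
    metrics <- c("sens", "spec", "ppv", "npv", "acc")
    s <- data.frame(metric = metrics,
                    mean = vapply(metrics, function(m)
                      mean(pr[[m]], na.rm = TRUE), numeric(1)),
                    sd = vapply(metrics, function(m)
                      if (nrow(pr) > 1) sd(pr[[m]], na.rm = TRUE) else 0,
                      numeric(1)))
    new("MetricsReport", summary = s, per_repeat = pr)
  })
  acc_mean <- vapply(reports, function(rp)
    rp@summary$mean[rp@summary$metric == "acc"], numeric(1))
  acc_sd <- vapply(reports, function(rp)
    rp@summary$sd[rp@summary$metric == "acc"], numeric(1))
  best_acc <- max(acc_mean)
  cand <- names(reports)[acc_mean >= best_acc - acc_sd[which.max(acc_mean)]]
  minss <- vapply(cand, function(f) {
    s <- reports[[f]]@summary
    min(s$mean[s$metric == "sens"], s$mean[s$metric == "spec"])
  }, numeric(1))
  list(reports = reports, best_family = cand[which.max(minss)],
       split = split)
}
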