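## Dimensionality-reduction stage: z-score normalization with
## training-split statistics, PCA over the covariance matrix,
## loading-based feature retention, the MANOVA class-mean dendrogram and
## the feature correlation matrix.

#' Z-score a feature table with training-split statistics
#'
#' Column means and SDs (n-1 denominator) are computed on the
#' \code{stats_from} rows only and applied to the whole table, so a test
#' split never leaks into the normalization. Columns with zero SD on the
#' statistics rows are dropped with a warning.
#'
#' @param table numeric matrix, epochs in rows, features in columns.
#' @param stats_from row indices (or logical mask) to compute statistics
#'   from; defaults to all rows.
#' @return the normalized matrix, with attributes \code{center} and
#'   \code{scale}.
#' @examples
#' zscoreTable(cbind(f = c(2, 4, 6)))
#' @export
zscoreTable <- function(table, stats_from = seq_len(nrow(table))) {
  if (!nrow(table) || !ncol(table)) stop("empty feature table")
  sub <- table[stats_from, , drop = FALSE]
  mu <- colMeans(sub)
  sdv <- apply(sub, 2, sd)
  drop <- sdv == 0 | !is.finite(sdv)
  if (any(drop)) {
    warning("dropping ", sum(drop), " constant feature(s): ",
            paste(colnames(table)[drop], collapse = ", "))
    table <- table[, !drop, drop = FALSE]
    mu <- mu[!drop]; sdv <- sdv[!drop]
  }
  out <- sweep(sweep(table, 2, mu, "-"), 2, sdv, "/")
  attr(out, "center") <- mu
  attr(out, "scale") <- sdv
  out
}

#' PCA over the covariance matrix
#'
#' Eigendecomposition of the sample covariance of \code{table} (applied
#' after z-scoring in the pipeline, making it the correlation-matrix
#' eigenproblem). Components are ordered by decreasing eigenvalue; each
#' loading column is signed so its largest-magnitude entry is positive.
#'
#' @param table numeric matrix, epochs in rows, features in columns, all
#'   finite.
#' @return a \linkS4class{PCASelectionResult} with loadings and the
#'   explained-variance spectrum (retained features unset).
#' @export
pcaCovariance <- function(table) {
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("need at least 2 rows and 2 columns")
  if (!all(is.finite(table))) stop("non-finite values in feature table")
  C <- cov(table)
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  L <- eig$vectors
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  rownames(L) <- colnames(table)
  colnames(L) <- paste0("PC", seq_len(ncol(L)))
  expl <- ev / sum(ev)
  new("PCASelectionResult", loadings = L, explained = expl,
      cumulative = cumsum(expl), retained = character(0), nPCsUsed = 0L)
}

#' Retain the features that weigh most within the leading components
#'
#' Uses the smallest number of leading components whose cumulative
#' explained variance reaches \code{var_target}; within each of those
#' components the \code{top_k_per_pc} features with the largest absolute
#' loadings are retained (union over components). Retention order is
#' first component of appearance, then absolute loading descending.
#'
#' @param result a \linkS4class{PCASelectionResult} from
#'   \code{\link{pcaCovariance}}.
#' @param var_target cumulative-variance threshold in (0, 1].
#' @param top_k_per_pc features kept per inspected component.
#' @return the result with \code{retained} and \code{nPCsUsed} filled in.
#' @export
selectByLoadings <- function(result, var_target = 0.9, top_k_per_pc = 10L) {
  stopifnot(is(result, "PCASelectionResult"),
            var_target > 0, var_target <= 1)
  npc <- which(result@cumulative >= var_target - 1e-12)[1]
  if (is.na(npc)) npc <- length(result@cumulative)
  feats <- rownames(result@loadings)
  retained <- character(0)
  for (j in seq_len(npc)) {
    w <- abs(result@loadings[, j])
    top <- feats[order(w, decreasing = TRUE)][seq_len(min(top_k_per_pc,
                                                          length(feats)))]
    retained <- c(retained, setdiff(top, retained))
  }
  initialize(result, retained = retained, nPCsUsed = as.integer(npc))
}

## pooled within-class covariance, ridged when singular
.pooledCov <- function(table, labels) {
  p <- ncol(table)
  S <- matrix(0, p, p)
  ntot <- 0L
  for (cl in unique(labels)) {
    X <- table[labels == cl, , drop = FALSE]
    if (nrow(X) < 2L) next
    S <- S + cov(X) * (nrow(X) - 1L)
    ntot <- ntot + nrow(X) - 1L
  }
  S <- S / ntot
  if (inherits(try(solve(S), silent = TRUE), "try-error") ||
      rcond(S) < 1e-12) {
    message("pooled covariance singular; adding ridge 1e-6 * trace/p")
    S <- S + diag(1e-6 * sum(diag(S)) / p, p)
  }
  S
}

#' Class-mean dendrogram under the pooled within-class covariance
#'
#' Computes Mahalanobis distances between the class mean vectors using
#' the pooled within-class covariance (the group-mean structure a one-way
#' MANOVA exposes), then agglomerates the classes. Single linkage is the
#' default, matching the convention of the standard MANOVA-dendrogram
#' implementations and behaving sensibly when an intermediate phenotype
#' (mixed apnea) chains two extremes (obstructive and central) together.
#' Wilks' lambda is reported alongside; the pipeline itself only consumes
#' the distance structure.
#'
#' @param table numeric matrix, epochs in rows, features in columns.
#' @param labels class label per row (at least 2 classes with 2 rows each).
#' @param linkage agglomeration method passed to \code{stats::hclust}.
#' @return a \linkS4class{ClassDendrogram}.
#' @export
manovaDendrogram <- function(table, labels, linkage = "single") {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L || any(table(labels) < 2L))
    stop("need >= 2 classes with >= 2 rows each")
  S <- .pooledCov(table, labels)
  Sinv <- solve(S)
  M <- do.call(rbind, lapply(classes, function(cl)
    colMeans(table[labels == cl, , drop = FALSE])))
  rownames(M) <- classes
  k <- length(classes)
  D <- matrix(0, k, k, dimnames = list(classes, classes))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    d <- M[i, ] - M[j, ]
    D[i, j] <- D[j, i] <- sqrt(drop(t(d) %*% Sinv %*% d))
  }
  hc <- hclust(as.dist(D), method = linkage)
  wilks <- tryCatch({
    fit <- stats::manova(table ~ factor(labels))
    summary(fit, test = "Wilks")$stats[1, "Wilks"]
  }, error = function(e) NA_real_)
  new("ClassDendrogram", hclust = hc, distances = D,
      wilks = as.numeric(wilks))
}

#' Leaf sets of the first (topmost) dendrogram split
#'
#' @param dend a \linkS4class{ClassDendrogram}.
#' @return list of two character vectors of class names.
#' @export
firstSplit <- function(dend) {
  stopifnot(is(dend, "ClassDendrogram"))
  grp <- cutree(dend@hclust, k = 2)
  split(names(grp), unname(grp))
}

#' Export a class dendrogram as a Newick string
#'
#' @param dend a \linkS4class{ClassDendrogram}.
#' @return single character Newick string.
#' @export
dendrogramNewick <- function(dend) {
  stopifnot(is(dend, "ClassDendrogram"))
  ape::write.tree(ape::as.phylo(dend@hclust))
}

#' Pearson correlation matrix of a feature table
#'
#' @param table numeric matrix with finite columns.
#' @return symmetric correlation matrix with unit diagonal;
#'   zero-variance columns get 0 off-diagonal entries and are listed in
#'   the \code{flagged} attribute.
#' @export
correlationMatrix <- function(table) {
  if (!all(is.finite(table))) stop("non-finite values in feature table")
  sdv <- apply(table, 2, sd)
  R <- suppressWarnings(cor(table))
  flagged <- colnames(table)[sdv == 0]
  if (length(flagged)) {
    R[is.na(R)] <- 0
    diag(R) <- 1
  }
  attr(R, "flagged") <- flagged
  R
}
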