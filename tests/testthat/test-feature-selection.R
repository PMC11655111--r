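test_that("z-scoring uses n-1 statistics and drops constants", {
  z <- zscoreTable(cbind(f = c(2, 4, 6)))
  expect_equal(as.numeric(z), c(-1, 0, 1))

  x <- withr::with_seed(1, matrix(rnorm(200), 50, 4,
                                  dimnames = list(NULL, paste0("f", 1:4))))
  z1 <- zscoreTable(x)
  expect_equal(unname(colMeans(z1)), rep(0, 4), tolerance = 1e-12)
  z2 <- zscoreTable(z1)
  expect_equal(as.numeric(z2), as.numeric(z1), tolerance = 1e-12)

  xc <- cbind(x, const = 1)
  expect_warning(zc <- zscoreTable(xc), "constant")
  expect_false("const" %in% colnames(zc))

  # training-split statistics only
  zs <- zscoreTable(x, stats_from = 1:25)
  expect_equal(unname(colMeans(zs[1:25, ])), rep(0, 4), tolerance = 1e-12)
})

test_that("covariance PCA has orthonormal, variance-ordered components", {
  x <- withr::with_seed(2, matrix(rnorm(5000 * 5), 5000, 5,
                                  dimnames = list(NULL, paste0("f", 1:5))))
  p <- pcaCovariance(x)
  expect_equal(sum(explainedVariance(p)), 1)
  expect_true(all(diff(explainedVariance(p)) <= 1e-12))
  expect_equal(unname(crossprod(p@loadings)), diag(5), tolerance = 1e-10)
  # isotropic data spreads variance evenly
  expect_true(all(abs(explainedVariance(p) - 0.2) < 0.03))

  # rank-1 planted factor dominates
  f <- withr::with_seed(3, rnorm(1000))
  y <- outer(f, c(3, -2, 1, 0.5, 0.1)) +
    withr::with_seed(4, matrix(rnorm(5000, sd = 0.1), 1000, 5))
  colnames(y) <- paste0("g", 1:5)
  expect_gt(explainedVariance(pcaCovariance(y))[1], 0.9)

  expect_error(pcaCovariance(cbind(a = c(1, NA), b = c(2, 3))), "finite")
})

test_that("PCA on z-scored data equals the correlation eigenproblem", {
  x <- withr::with_seed(5, matrix(rnorm(300 * 6), 300, 6,
                                  dimnames = list(NULL, paste0("f", 1:6))))
  x[, 2] <- x[, 1] * 2 + x[, 2]
  p <- pcaCovariance(zscoreTable(x))
  ev <- eigen(cor(x), symmetric = TRUE)$values
  expect_equal(explainedVariance(p), ev / sum(ev), tolerance = 1e-9)
})

test_that("loading-based retention keeps dominant features and is stable", {
  f1 <- withr::with_seed(6, rnorm(500)); f2 <- withr::with_seed(7, rnorm(500))
  x <- cbind(a = 5 * f1, b = f1 + 0.05 * rnorm(500),
             c = 4 * f2, d = f2 + 0.05 * rnorm(500)) +
    withr::with_seed(8, matrix(rnorm(2000, sd = 0.05), 500, 4))
  p <- pcaCovariance(x)

  all_kept <- selectByLoadings(p, var_target = 1, top_k_per_pc = 4)
  expect_setequal(retainedFeatures(all_kept), colnames(x))

  top <- selectByLoadings(p, var_target = 0.95, top_k_per_pc = 1)
  expect_setequal(retainedFeatures(top), c("a", "c"))

  # permutation invariance of the retained set
  perm <- c(3, 1, 4, 2)
  p2 <- pcaCovariance(x[, perm])
  expect_setequal(retainedFeatures(selectByLoadings(p2, 0.95, 1)),
                  c("a", "c"))

  # monotone in var_target
  prev <- character(0)
  for (vt in c(0.3, 0.5, 0.7, 0.9, 1)) {
    cur <- retainedFeatures(selectByLoadings(p, vt, 2))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("class-mean distances are Mahalanobis-exact and label-invariant", {
  x <- withr::with_seed(9, rbind(
    matrix(rnorm(200, 0), 100, 2), matrix(rnorm(200, 3), 100, 2),
    matrix(rnorm(200, 6), 100, 2)))
  colnames(x) <- c("u", "v")
  lab <- rep(c("A", "B", "C"), each = 100)
  d <- manovaDendrogram(x, lab)

  S <- psgApnea:::.pooledCov(x, lab)
  for (c1 in c("A", "B")) for (c2 in setdiff(c("B", "C"), c1)) {
    ref <- sqrt(mahalanobis(colMeans(x[lab == c1, ]),
                            colMeans(x[lab == c2, ]), S))
    expect_equal(d@distances[c1, c2], ref, tolerance = 1e-9)
  }

  # identical-mean classes merge at a near-zero height
  lab0 <- rep(c("A", "B"), 150)
  d0 <- manovaDendrogram(x, lab0)
  expect_lt(d0@hclust$height[1], 0.5)

  # relabelling permutes but does not reshape the tree
  ren <- c(A = "Q", B = "R", C = "S")[lab]
  d2 <- manovaDendrogram(x, ren)
  expect_equal(unname(d2@distances[c("Q", "R", "S"), c("Q", "R", "S")]),
               unname(d@distances), tolerance = 1e-12)
  expect_equal(d2@hclust$height, d@hclust$height, tolerance = 1e-12)

  expect_error(manovaDendrogram(x, rep("A", 300)), "2 classes")
  expect_type(dendrogramNewick(d), "character")
})

test_that("correlation matrices behave at the boundaries", {
  x <- withr::with_seed(10, cbind(a = rnorm(100)))
  x <- cbind(x, b = -x[, "a"], c = rnorm(100))
  R <- correlationMatrix(x)
  expect_equal(diag(R), c(a = 1, b = 1, c = 1))
  expect_equal(R["a", "b"], -1)

  worst <- max(vapply(1:500, function(s) withr::with_seed(s, {
    abs(cor(rnorm(200), rnorm(200)))
  }), numeric(1)))
  expect_lt(worst, 0.35)

  xz <- cbind(x, z = rep(1, 100))
  Rz <- correlationMatrix(xz)
  expect_equal(attr(Rz, "flagged"), "z")
  expect_true(all(Rz["z", colnames(x)] == 0))
  expect_equal(Rz["z", "z"], 1)
})
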