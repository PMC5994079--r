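test_that("similarity matrix matches direct correlation computation", {
  set.seed(7)
  X <- matrix(abs(rnorm(12)), 4, 3, dimnames = list(NULL, paste0("c", 1:3)))
  S <- similarityMatrix(X, "pearson")
  # brute-force Pearson on one pair
  a <- X[, 1]; b <- X[, 2]
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(S[1, 2], r, tolerance = 1e-12)
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 3))
  expect_true(all(S >= -1 & S <= 1))
  # identical cells correlate perfectly
  X2 <- cbind(X, X[, 1])
  expect_equal(similarityMatrix(X2)[1, 4], 1)
  # monotone transform leaves Spearman at 1
  X3 <- cbind(a = X[, 1], b = X[, 1]^3, c = X[, 2])
  expect_equal(similarityMatrix(X3, "spearman")[1, 2], 1)
})

test_that("constant cells get zero correlations with a warning", {
  X <- cbind(c1 = c(1, 2, 3), c2 = c(2, 2, 2), c3 = c(3, 1, 2))
  expect_warning(S <- similarityMatrix(X), "constant")
  expect_equal(unname(S[2, c(1, 3)]), c(0, 0))
  expect_equal(S[2, 2], 1)
})

test_that("pca scores keep the right number of ordered components", {
  set.seed(1)
  S100 <- similarityMatrix(matrix(rnorm(30 * 100), 30, 100))
  sc <- pcaScores(S100)
  expect_equal(ncol(sc), 5)          # 5% of 100 components
  v <- apply(sc, 2, var)
  expect_true(all(diff(v) <= 1e-8))  # decreasing explained variance
  # small p clamps to the minimum of 2 components
  S30 <- similarityMatrix(matrix(rnorm(20 * 30), 20, 30))
  expect_equal(ncol(pcaScores(S30)), 2)
  expect_error(pcaScores(S100[1:2, 1:2]), "too few")
  # scores match prcomp on the column-centered matrix (up to sign)
  pr <- prcomp(S30, center = TRUE)
  expect_equal(abs(unname(pcaScores(S30))), abs(unname(pr$x[, 1:2])),
               tolerance = 1e-8)
})

test_that("k-means recovers separable blobs and is seed-deterministic", {
  b <- makeBlobs(60, 2, seed = 3)
  l1 <- kmeansCluster(b$scores, 2, seed = 11)
  expect_equal(adjustedRandIndex(l1, b$labels), 1)
  expect_identical(as.integer(l1), as.integer(kmeansCluster(b$scores, 2, seed = 11)))
  expect_error(kmeansCluster(b$scores, 1, seed = 1), "k must be >= 2")
  expect_error(kmeansCluster(b$scores, 60, seed = 1), "smaller")
})

test_that("mini-batch k-means approximates exact k-means on blobs", {
  b <- makeBlobs(600, 3, seed = 5)
  exact <- kmeansCluster(b$scores, 3, seed = 2)
  mb <- minibatchKmeans(b$scores, 3, seed = 2)
  expect_gte(adjustedRandIndex(exact, mb), 0.95)
  expect_identical(as.integer(mb),
                   as.integer(minibatchKmeans(b$scores, 3, seed = 2)))
  # batch covering all points equals any batch size >= p (full-batch limit)
  full1 <- minibatchKmeans(b$scores, 3, seed = 9, batchSize = 600)
  full2 <- minibatchKmeans(b$scores, 3, seed = 9, batchSize = 10000)
  expect_identical(as.integer(full1), as.integer(full2))
})

test_that("landmark scores cluster like the exact mode on separable data", {
  sim <- simulateCells(nGenes = 300, nCells = 150, nClusters = 3, seed = 6,
                       dropout = list(type = "binomial_thin", rate = 1))
  X <- suppressWarnings(preprocessCounts(
    SummarizedExperiment::assay(sim, "counts")))$X
  lsc <- landmarkScores(X, "pearson", mLandmarks = 100, seed = 1)
  expect_equal(ncol(lsc), 5)   # ceil(0.05 * 100)
  lExact <- kmeansCluster(pcaScores(similarityMatrix(X, "pearson")), 3, seed = 4)
  lLand <- kmeansCluster(lsc, 3, seed = 4)
  expect_gte(adjustedRandIndex(lExact, lLand), 0.9)
  expect_identical(landmarkScores(X, "pearson", mLandmarks = 100, seed = 1),
                   lsc)
  # m >= p falls back to the exact computation
  expect_equal(dim(suppressMessages(
    landmarkScores(X, "pearson", mLandmarks = 150, seed = 1))),
    dim(pcaScores(similarityMatrix(X, "pearson"))))
})

test_that("ensemble grid size is |metrics| x |ks| with derived seeds", {
  X <- suppressWarnings(preprocessCounts(
    simCounts(nGenes = 100, nCells = 40, nClusters = 2, seed = 7)))$X
  e1 <- buildEnsemble(X, ks = 3:4, metrics = "pearson", seed = 1)
  expect_equal(length(e1), 2)
  e2 <- buildEnsemble(X, ks = 2:4, seed = 1)
  expect_equal(length(e2), 6)
  expect_equal(e2@configs$metric, rep(c("pearson", "spearman"), each = 3))
  # determinism of the whole ensemble
  expect_identical(clusterLabels(buildEnsemble(X, ks = 2:4, seed = 1)),
                   clusterLabels(e2))
  # per-config seeds differ and derive from (seed, metric, k)
  expect_equal(length(unique(e2@configs$seed)), 6)
  expect_equal(e2@configs$seed[1], childSeed(1, "kmeans", "pearson", 2))
})

test_that("k range auto-clamps for small cell numbers", {
  X <- suppressWarnings(preprocessCounts(
    simCounts(nGenes = 120, nCells = 30, nClusters = 2, seed = 8)))$X
  # a grid reaching p shrinks to the small-sample range: 6..10 at 30 cells
  e <- suppressMessages(buildEnsemble(X, ks = 10:30, seed = 1))
  expect_equal(sort(unique(e@configs$k)), 6:10)
  expect_equal(length(e), 10)
  expect_error(suppressMessages(buildEnsemble(X[, 1:2], seed = 1)), "cells")
})

test_that("predicted clusters are pure on well-separated synthetic data", {
  sim <- simulateCells(nGenes = 400, nCells = 90, nClusters = 3, seed = 9,
                       logFC = 1.5,
                       dropout = list(type = "binomial_thin", rate = 1))
  X <- suppressWarnings(preprocessCounts(
    SummarizedExperiment::assay(sim, "counts")))$X
  truth <- cellClusters(sim)
  e <- buildEnsemble(X, ks = 3:6, metrics = "pearson", seed = 2)
  for (h in seq_len(length(e))) {
    lab <- clusterLabels(e)[, h]
    purity <- vapply(split(truth, lab),
                     function(g) max(table(g)) / length(g), 0)
    expect_gte(min(purity), 0.9)
  }
})
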