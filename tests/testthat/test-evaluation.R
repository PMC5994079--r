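test_that("binomial thinning keeps totals near the expected fraction", {
  m <- simCounts(nGenes = 200, nCells = 40, nClusters = 2, seed = 13,
                 dropout = list(type = "binomial_thin", rate = 1))
  expect_identical(downsampleCounts(m, 1, seed = 1), m)   # rate 1 no-op
  d <- downsampleCounts(m, 0.25, seed = 1)
  expect_true(all(d <= m))
  expect_true(all(d[m == 0] == 0))
  N <- sum(m)
  expect_lt(abs(sum(d) - 0.25 * N), 3 * sqrt(N * 0.25 * 0.75))
  expect_identical(downsampleCounts(m, 0.25, seed = 1), d) # deterministic
  expect_error(downsampleCounts(m, 0), "rate")
  expect_error(downsampleCounts(m, 1.2), "rate")
})

test_that("two-stage thinning composes like a single pass", {
  m <- matrix(rpois(400, 20), 20, 20)
  t1 <- vapply(1:200, function(s)
    sum(downsampleCounts(downsampleCounts(m, 0.5, seed = s), 0.5,
                         seed = s + 7000)), 0)
  t2 <- vapply(1:200, function(s) sum(downsampleCounts(m, 0.25, seed = s)), 0)
  # same mean within 4 SE of the difference of means, similar variances
  sePool <- sqrt(var(t1) / 200 + var(t2) / 200)
  expect_lt(abs(mean(t1) - mean(t2)), 4 * sePool)
  expect_lt(max(var(t1), var(t2)) / min(var(t1), var(t2)), 1.5)
})

test_that("zeros are classified by cluster-uniform absence vs full positivity", {
  full <- rbind(silent = c(0, 0, 0, 3, 4, 2),   # zero across cluster 1
                expr = c(2, 3, 0, 1, 0, 2))
  colnames(full) <- paste0("c", 1:6)
  down <- full
  down[2, c(1, 4)] <- 0     # dropout: positive in full, zero after thinning
  lab <- classifyZeros(full, down, c(1, 1, 1, 2, 2, 2))
  expect_equal(unname(lab[1, 1:3]), rep("true_zero", 3))
  expect_equal(unname(lab[2, c(1, 4)]), rep("dropout_zero", 2))
  # zero in both matrices but cluster-mates positive -> unlabeled
  expect_equal(unname(lab[2, 3]), "unlabeled")
  expect_true(all(is.na(lab[down > 0])))
  expect_error(classifyZeros(full, down[, 1:5], c(1, 1, 1, 2, 2)), "differ")
})

test_that("discrimination tallies and F1 follow their definitions", {
  lab <- matrix(c("dropout_zero", "dropout_zero", "dropout_zero",
                  "true_zero", "unlabeled", NA), 2, 3)
  imp <- matrix(c(1, 1, 0, 1, 5, 5), 2, 3)   # dz imputed, dz imputed,
  sc <- discriminationScores(imp, lab)       # dz missed, tz imputed
  expect_equal(sc[c("tp", "tn", "fp", "fn")], list(tp = 2, tn = 0, fp = 1, fn = 1))
  expect_equal(sc$precision, 2 / 3)
  expect_equal(sc$recall, 2 / 3)
  expect_equal(sc$f1, 2 / 3)
  # perfect discrimination
  imp2 <- matrix(c(1, 1, 1, 0, 0, 0), 2, 3)
  expect_equal(discriminationScores(imp2, lab)$f1, 1)
  # nothing imputed: recall 0, f1 0
  sc0 <- discriminationScores(matrix(0, 2, 3), lab)
  expect_equal(sc0$recall, 0)
  expect_equal(sc0$f1, 0)
  # unlabeled entries never change the score
  lab2 <- lab; lab2[lab2 == "unlabeled"] <- NA
  expect_equal(discriminationScores(imp, lab2), sc)
})

test_that("adjusted Rand index agrees with the pair-counting oracle", {
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_equal(adjustedRandIndex(1:6, 1:6), 1)
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(7, 7, 3, 3)), 1) # relabeling
  expect_equal(adjustedRandIndex(rep(1, 5), rep(2, 5)), 1) # degenerate case
  set.seed(31)
  for (rep in 1:25) {
    N <- sample(3:12, 1)
    a <- sample.int(4, N, replace = TRUE)
    b <- sample.int(4, N, replace = TRUE)
    expect_equal(adjustedRandIndex(a, b), pairCountARI(a, b),
                 tolerance = 1e-12)
  }
  expect_error(adjustedRandIndex(1:3, 1:4), "length")
})

test_that("ARI matches an installed independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(17)
  for (rep in 1:10) {
    a <- sample.int(3, 20, replace = TRUE)
    b <- sample.int(5, 20, replace = TRUE)
    expect_equal(adjustedRandIndex(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("cross-ARI averages partial ARIs over overlapping cells", {
  base <- setNames(rep(1:4, each = 5), paste0("c", 1:20))
  expect_equal(crossARI(replicate(5, base, simplify = FALSE)), 1)
  # identical on the shared first half, disjoint second halves
  l1 <- setNames(c(1, 1, 2, 2, 3, 3), c("a", "b", "c", "d", "e", "f"))
  l2 <- setNames(c(1, 1, 2, 2, 9, 9), c("a", "b", "c", "d", "x", "y"))
  expect_equal(crossARI(list(l1, l2)), 1)
  # independent labelings hover near zero
  set.seed(23)
  rand <- replicate(8, setNames(sample.int(5, 1000, replace = TRUE),
                                paste0("c", 1:1000)), simplify = FALSE)
  expect_lt(abs(crossARI(rand)), 0.05)
  expect_warning(
    crossARI(list(setNames(1:2, c("a", "b")), setNames(1:2, c("x", "y")),
                  setNames(2:1, c("a", "b")))),
    "skipped")
  expect_error(crossARI(list(l1)), "at least 2")
})

test_that("kendall tau-b matches the enumerated pair computation", {
  expect_equal(kendallTau(1:5, 2 * (1:5)), 1)
  expect_equal(kendallTau(1:5, 5:1), -1)
  # worked tie case: 4 concordant pairs, ties in y -> 4 / sqrt(6 * 4)
  expect_equal(kendallTau(c(1, 2, 3, 4), c(1, 1, 2, 2)), 4 / sqrt(24),
               tolerance = 1e-12)
  expect_warning(z <- kendallTau(c(1, 1, 1), 1:3), "constant")
  expect_equal(z, 0)
})

test_that("imputation concordance is affine-invariant over the zero mask", {
  X <- randomSmallX(8, 6, pZero = 0.5)
  r1 <- ensembleImpute(X, list(sample(c(1, 1, 2, 2, 3, 3))))
  expect_equal(imputationConcordance(r1, r1), 1)
  # affine transform of the imputed entries leaves correlation at 1
  Y <- imputed(r1)
  zm <- zeroMask(r1)
  Y2 <- Y; Y2[zm] <- 2 * Y[zm] + 0.3
  r2 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(logcounts = SummarizedExperiment::assay(r1, "logcounts"),
                  imputed = Y2))
  r2 <- new("ImputedExperiment", r2)
  expect_equal(imputationConcordance(r1, r2), 1, tolerance = 1e-12)
  # different inputs are rejected
  X3 <- X; X3[X3 == 0][1] <- 1
  r3 <- ensembleImpute(X3, list(rep(1:2, 3)))
  expect_error(imputationConcordance(r1, r3), "zero masks")
})
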