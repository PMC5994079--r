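# Independent oracles used across the suite. These deliberately take the
# slow, literal route so they stay independent of the package internals.

# ARI by direct pair counting: walk every item pair and tally co-membership
# agreement, then apply the chance correction to the pair counts.
pairCountARI <- function(a, b) {
  N <- length(a)
  n11 <- n10 <- n01 <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    sa <- a[i] == a[j]
    sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa) n10 <- n10 + 1
    else if (sb) n01 <- n01 + 1
  }
  Tot <- N * (N - 1) / 2
  expc <- (n11 + n10) * (n11 + n01) / Tot
  mx <- ((n11 + n10) + (n11 + n01)) / 2
  if (mx == expc) return(1)
  (n11 - expc) / (mx - expc)
}

# all set partitions of n items as restricted-growth label vectors
allPartitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxLab) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (l in seq_len(maxLab + 1L))
      rec(c(prefix, l), max(maxLab, l))
  }
  rec(integer(), 0L)
  out
}

# literal double-loop implementation of the two imputation equations:
# per-clustering cluster-mean estimate at each zero, then the arithmetic
# mean over clusterings
oracleImpute <- function(X, labelsList) {
  Y <- X
  for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X))) {
    if (X[i, j] == 0) {
      ests <- vapply(labelsList, function(l) mean(X[i, l == l[j]]), 0)
      Y[i, j] <- mean(ests)
    }
  }
  Y
}

# small random non-negative matrix with a controlled zero fraction
randomSmallX <- function(n, p, pZero = 0.4) {
  X <- matrix(round(abs(rnorm(n * p)), 3), n, p)
  X[runif(n * p) < pZero] <- 0
  dimnames(X) <- list(paste0("g", seq_len(n)), paste0("c", seq_len(p)))
  X
}

# well-separated Gaussian blobs in d dimensions, for clustering checks
makeBlobs <- function(p, k, d = 2, sep = 8, seed = 1) {
  set.seed(seed)
  lab <- sort(rep_len(seq_len(k), p))
  centers <- matrix(rnorm(k * d), k, d) * sep
  pts <- centers[lab, , drop = FALSE] + matrix(rnorm(p * d), p, d)
  rownames(pts) <- paste0("c", seq_len(p))
  list(scores = pts, labels = lab)
}

counts3x2 <- function() {
  m <- matrix(c(1, 2, 2, 4, 3, 6), 3, 2, byrow = TRUE)
  dimnames(m) <- list(c("gA", "gB", "gC"), c("c1", "c2"))
  m
}

simCounts <- function(...) SummarizedExperiment::assay(simulateCells(...), "counts")
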