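#' Cell-cell correlation similarity matrix
#'
#' Pearson or Spearman correlation between every pair of cells (columns)
#' of a log-expression matrix. Spearman is Pearson on within-cell ranks
#' with average ranks for ties. A cell with zero variance across genes has
#' no defined correlation; its off-diagonal entries are set to 0 with a
#' warning and the diagonal stays 1.
#'
#' @param X Log-expression matrix, genes x cells (p >= 2 cells).
#' @param metric `"pearson"` or `"spearman"`.
#' @return Symmetric p x p matrix with unit diagonal, entries in [-1, 1].
#' @export
similarityMatrix <- function(X, metric = c("pearson", "spearman")) {
  metric <- match.arg(metric)
  X <- asDenseMatrix(X)
  p <- ncol(X)
  if (p < 2) stop("need at least 2 cells")
  const <- apply(X, 2, function(v) max(v) == min(v))
  S <- suppressWarnings(stats::cor(X, method = metric))
  if (any(const)) {
    warning(sum(const), " cell(s) constant across genes; correlations set to 0")
    S[const, ] <- 0
    S[, const] <- 0
  }
  S[!is.finite(S)] <- 0
  diag(S) <- 1
  S <- (S + t(S)) / 2
  dimnames(S) <- list(colnames(X), colnames(X))
  S
}

## number of principal components: a fraction of p, at least 2, at most p-1
.pcaDim <- function(frac, p) min(max(ceiling(frac * p), 2L), p - 1L)

## scores of the top-d principal components of the column-centered matrix M
## (rows = observations); component signs fixed so the largest-magnitude
## loading of each component is positive
.pcaOfMatrix <- function(M, d) {
  Mc <- sweep(M, 2, colMeans(M))
  e <- eigen(crossprod(Mc), symmetric = TRUE)
  V <- e$vectors[, seq_len(d), drop = FALSE]
  flip <- vapply(seq_len(d), function(j) {
    v <- V[, j]
    v[which.max(abs(v))] < 0
  }, TRUE)
  V[, flip] <- -V[, flip]
  sc <- Mc %*% V
  rownames(sc) <- rownames(M)
  colnames(sc) <- paste0("PC", seq_len(d))
  sc
}

#' Principal-component scores of a similarity matrix
#'
#' Column-centres the p x p similarity matrix and returns the scores of its
#' first `ceiling(frac * p)` principal components (clamped to [2, p-1]),
#' ordered by decreasing explained variance. With the default `frac = 0.05`
#' this is the first 5% of the components, e.g. d = 5 for 100 cells.
#'
#' @param S Symmetric similarity matrix from [similarityMatrix()].
#' @param frac Fraction of components to keep.
#' @return p x d score matrix.
#' @export
pcaScores <- function(S, frac = 0.05) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) stop("S must be square")
  p <- nrow(S)
  if (p < 3) stop("too few cells to cluster (need p >= 3)")
  .pcaOfMatrix(S, .pcaDim(frac, p))
}

## k-means++ initial centers (row indices sampled proportional to squared
## distance from the nearest chosen center)
.kppCenters <- function(scores, k) {
  p <- nrow(scores)
  idx <- integer(k)
  idx[1] <- sample.int(p, 1)
  if (k > 1) {
    d2 <- colSums((t(scores) - scores[idx[1], ])^2)
    for (c in 2:k) {
      pr <- d2
      pr[idx[seq_len(c - 1)]] <- 0
      if (sum(pr) == 0) {           # fewer distinct points than k
        pr <- rep(1, p)
        pr[idx[seq_len(c - 1)]] <- 0
      }
      idx[c] <- sample.int(p, 1, prob = pr)
      d2 <- pmin(d2, colSums((t(scores) - scores[idx[c], ])^2))
    }
  }
  scores[idx, , drop = FALSE]
}

## index of the nearest center for each row of B
.nearestCenter <- function(B, centers) {
  cross <- B %*% t(centers)                      # n x k
  cn <- rowSums(centers^2)
  max.col(sweep(2 * cross, 2, cn), ties.method = "first")
}

#' Exact k-means base clustering
#'
#' Lloyd's k-means on the PCA score matrix with k-means++ seeding,
#' `nStart` restarts and selection of the restart with the lowest total
#' within-cluster sum of squares. Deterministic given `seed`. A restart
#' that converges with an empty cluster is re-seeded.
#'
#' @param scores p x d score matrix from [pcaScores()] or
#'   [landmarkScores()].
#' @param k Number of clusters (2 <= k < p).
#' @param seed Integer seed for this clustering.
#' @param nStart Number of seeded restarts.
#' @param maxIter Maximum Lloyd iterations per restart.
#' @return Named integer vector of labels in `1..k` with attribute
#'   `config` (a list with `k`, `seed`, `mode`).
#' @export
kmeansCluster <- function(scores, k, seed = 1L, nStart = 10L, maxIter = 300L) {
  scores <- as.matrix(scores)
  p <- nrow(scores)
  if (k < 2) stop("k must be >= 2")
  if (k >= p) stop("k must be smaller than the number of cells")
  best <- NULL
  withSeed(seed, {
    for (r in seq_len(nStart)) {
      fit <- NULL
      for (attempt in 1:10) {       # re-seed on empty clusters / dup centers
        cen <- .kppCenters(scores, k)
        fit <- tryCatch(
          withCallingHandlers(
            stats::kmeans(scores, centers = cen, iter.max = maxIter,
                          algorithm = "Lloyd"),
            warning = function(w) invokeRestart("muffleWarning")),
          error = function(e) NULL)
        if (!is.null(fit) && all(fit$size > 0)) break
        fit <- NULL
      }
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best)) stop("k-means failed to produce a valid clustering")
  labels <- as.integer(best$cluster)
  names(labels) <- rownames(scores)
  attr(labels, "config") <- list(k = k, seed = seed, mode = "exact")
  labels
}

#' Mini-batch k-means for large datasets
#'
#' Web-scale k-means: centres are updated from random mini-batches with
#' per-centre learning rates equal to the inverse of the number of points
#' the centre has absorbed, so each centre tracks the running mean of its
#' assigned points. Used by the large-scale clustering mode where full
#' Lloyd iterations over all cells are too slow. Deterministic given
#' `seed`; with `batchSize >= p` every iteration uses the full dataset,
#' recovering a full-batch assignment step.
#'
#' @inheritParams kmeansCluster
#' @param batchSize Number of cells per mini-batch.
#' @param nIter Number of mini-batch iterations.
#' @return Named integer labels in `1..k` with a `config` attribute.
#' @export
minibatchKmeans <- function(scores, k, seed = 1L, batchSize = 100L,
                            nIter = 100L) {
  scores <- as.matrix(scores)
  p <- nrow(scores)
  if (k < 2) stop("k must be >= 2")
  if (k >= p) stop("k must be smaller than the number of cells")
  labels <- withSeed(seed, {
    centers <- .kppCenters(scores, k)
    cnt <- rep(0, k)
    for (it in seq_len(nIter)) {
      b <- if (batchSize >= p) seq_len(p) else sample.int(p, batchSize)
      B <- scores[b, , drop = FALSE]
      a <- .nearestCenter(B, centers)
      ns <- tabulate(a, k)
      pres <- which(ns > 0)
      sums <- rowsum(B, group = a)            # rows ordered by center id
      centers[pres, ] <- (centers[pres, , drop = FALSE] * cnt[pres] +
                          sums) / (cnt[pres] + ns[pres])
      cnt <- cnt + ns
      if (it %% 10 == 0 && any(cnt == 0)) {   # dead center: restart at the
        far <- .nearestCenter(scores, centers)  # point farthest from its center
        d2 <- rowSums((scores - centers[far, , drop = FALSE])^2)
        for (cdead in which(cnt == 0)) {
          centers[cdead, ] <- scores[which.max(d2), ]
          d2[which.max(d2)] <- 0
        }
      }
    }
    .nearestCenter(scores, centers)
  })
  labels <- as.integer(labels)
  names(labels) <- rownames(scores)
  attr(labels, "config") <- list(k = k, seed = seed, mode = "large_scale",
                                 batchSize = batchSize)
  labels
}

#' Landmark PCA scores without the full cell-cell matrix
#'
#' Large-scale replacement for `pcaScores(similarityMatrix(X))`: samples
#' `mLandmarks` cells without replacement, computes the rectangular p x m
#' correlation matrix of all cells against the landmarks, and returns the
#' top principal-component scores of that matrix
#' (d = `ceiling(0.05 * mLandmarks)` clamped to [2, m-1]). Avoids the
#' O(p^2) similarity matrix. If `mLandmarks >= p` it falls back to the
#' exact computation.
#'
#' @param X Log-expression matrix, genes x cells.
#' @param metric `"pearson"` or `"spearman"`.
#' @param mLandmarks Number of landmark cells.
#' @param seed Integer seed for the landmark sample.
#' @return p x d score matrix.
#' @export
landmarkScores <- function(X, metric = c("pearson", "spearman"),
                           mLandmarks = 1000L, seed = 1L) {
  metric <- match.arg(metric)
  X <- asDenseMatrix(X)
  p <- ncol(X)
  if (mLandmarks >= p) {
    shdLog("mLandmarks >= p; falling back to the exact similarity PCA")
    return(pcaScores(similarityMatrix(X, metric)))
  }
  if (mLandmarks < 3) stop("mLandmarks must be >= 3")
  lm <- withSeed(childSeed(seed, "landmarks"), sample.int(p, mLandmarks))
  R <- suppressWarnings(stats::cor(X, X[, lm, drop = FALSE], method = metric))
  R[!is.finite(R)] <- 0
  rownames(R) <- colnames(X)
  .pcaOfMatrix(R, .pcaDim(0.05, mLandmarks))
}

## mimic the small-sample adjustment used for a 30-cell dataset
## (default 10:15 -> 6:10): when max(ks) >= p shrink the range to
## [ceiling(p/5), floor(p/3)], each bounded below by 2
.clampKs <- function(ks, p) {
  ks <- sort(unique(as.integer(ks)))
  ks <- ks[ks >= 2]
  if (!length(ks)) return(integer())
  if (max(ks) >= p) {
    hi <- max(2L, as.integer(floor(p / 3)))
    lo <- max(2L, as.integer(ceiling(p / 5)))
    if (lo > hi) lo <- hi
    new <- seq.int(lo, hi)
    new <- new[new < p]
    shdLog("k range ", min(ks), ":", max(ks), " too large for p = ", p,
           "; clamped to ", if (length(new)) paste(range(new), collapse = ":")
           else "<empty>")
    ks <- new
  }
  ks
}

#' Build the ensemble of base clusterings
#'
#' Produces one clustering per (metric, k) combination over the grid of
#' correlation metrics and cluster numbers: similarity matrix (or landmark
#' correlations in large-scale mode), PCA scores, then k-means (mini-batch
#' k-means in large-scale mode). With the defaults — both metrics and
#' k = 10..15 — the ensemble has H = 12 members. When `max(ks)` is not
#' below the number of cells the range is shrunk automatically (a 30-cell
#' dataset gets k = 6..10) and the adjustment is logged. Configuration
#' seeds are derived deterministically from the master seed, the metric
#' and k, so the whole ensemble is reproducible in both modes.
#'
#' @param X Log-expression matrix, genes x cells.
#' @param ks Integer vector of cluster numbers (default `10:15`).
#' @param metrics Correlation metrics to use.
#' @param mode `"auto"` (large-scale when p > `largeThreshold`), `"exact"`
#'   or `"large_scale"`.
#' @param seed Master seed.
#' @param frac Fraction of principal components to keep.
#' @param mLandmarks,batchSize Large-scale mode parameters.
#' @param largeThreshold Cell count above which `"auto"` picks large-scale
#'   mode.
#' @param nStart,maxIter Passed to [kmeansCluster()].
#' @return A [ClusterEnsemble-class] object.
#' @examples
#' X <- matrix(abs(rnorm(40 * 20)), 40, 20)
#' buildEnsemble(X, ks = 2:3, metrics = "pearson", seed = 1)
#' @export
buildEnsemble <- function(X, ks = 10:15,
                          metrics = c("pearson", "spearman"),
                          mode = c("auto", "exact", "large_scale"),
                          seed = 1L, frac = 0.05, mLandmarks = 1000L,
                          batchSize = 100L, largeThreshold = 5000L,
                          nStart = 10L, maxIter = 300L) {
  mode <- match.arg(mode)
  metrics <- match.arg(metrics, c("pearson", "spearman"), several.ok = TRUE)
  X <- asDenseMatrix(X)
  p <- ncol(X)
  if (mode == "auto") mode <- if (p > largeThreshold) "large_scale" else "exact"
  ks <- .clampKs(ks, p)
  if (!length(ks))
    stop("no usable k values for p = ", p, " cells; set ks explicitly")
  cellIds <- if (is.null(colnames(X))) paste0("cell", seq_len(p)) else colnames(X)
  labs <- matrix(NA_integer_, p, 0)
  cfg <- list()
  for (metric in metrics) {
    scores <- if (mode == "exact")
      pcaScores(similarityMatrix(X, metric), frac)
    else
      landmarkScores(X, metric, mLandmarks = min(mLandmarks, p - 1L),
                     seed = childSeed(seed, "landmark", metric))
    for (k in ks) {
      s <- childSeed(seed, "kmeans", metric, k)
      l <- if (mode == "exact")
        kmeansCluster(scores, k, seed = s, nStart = nStart, maxIter = maxIter)
      else
        minibatchKmeans(scores, k, seed = s, batchSize = batchSize)
      labs <- cbind(labs, as.integer(l))
      cfg[[length(cfg) + 1L]] <- data.frame(metric = metric, k = k,
                                            mode = mode, seed = s)
    }
  }
  configs <- do.call(rbind, cfg)
  colnames(labs) <- paste0(configs$metric, "_k", configs$k)
  rownames(labs) <- cellIds
  new("ClusterEnsemble", labels = labs, configs = configs,
      cellIds = cellIds, seed = as.integer(seed))
}
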