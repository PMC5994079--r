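#' Binomial down-sampling of a count matrix
#'
#' Simulates reduced sequencing depth at the matrix level: each count c is
#' replaced by a Binomial(c, rate) draw, so the expected total is `rate`
#' times the original total. Thinning at rate r1 and then r2 is
#' distributionally identical to one pass at r1*r2. Deterministic given
#' `seed`.
#'
#' @param m Count matrix (genes x cells).
#' @param rate Retention probability in (0, 1].
#' @param seed Integer seed.
#' @return Down-sampled count matrix, same dimnames.
#' @export
downsampleCounts <- function(m, rate, seed = 1L) {
  m <- validateCounts(asDenseMatrix(m))
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0 || rate > 1)
    stop("rate must be in (0, 1]")
  if (rate == 1) return(m)
  d <- m
  nz <- which(m > 0)
  d[nz] <- withSeed(seed, stats::rbinom(length(nz), m[nz], rate))
  d
}

#' Label the zeros of a down-sampled matrix as true or dropout zeros
#'
#' A zero entry (i, j) of the down-sampled matrix is a *true zero* when
#' gene i is zero in the full matrix across every cell of j's reference
#' cluster (expression genuinely absent in that population); it is a
#' *dropout zero* when the full matrix is positive at (i, j) (expression
#' lost to down-sampling). Zeros that are zero in the full matrix but
#' whose cluster is not uniformly zero fall in neither class and are
#' returned as `"unlabeled"`; they are excluded from discrimination
#' scoring.
#'
#' @param fullX Log-expression (or count) matrix of the full dataset.
#' @param downX Matrix of the down-sampled dataset; must share gene and
#'   cell identifiers with `fullX`.
#' @param clusters Reference cluster label per cell (known labels, or a
#'   base clustering of the full matrix).
#' @return Character matrix with dimensions of `downX`: `"true_zero"`,
#'   `"dropout_zero"` or `"unlabeled"` at the zero entries of `downX`,
#'   `NA` elsewhere.
#' @export
classifyZeros <- function(fullX, downX, clusters) {
  fullX <- asDenseMatrix(fullX)
  downX <- asDenseMatrix(downX)
  if (!identical(dim(fullX), dim(downX)))
    stop("full and down-sampled matrices differ in dimension")
  if (!is.null(rownames(fullX)) && !is.null(rownames(downX)) &&
      (!identical(rownames(fullX), rownames(downX)) ||
       !identical(colnames(fullX), colnames(downX))))
    stop("full and down-sampled matrices differ in gene or cell ids")
  cl <- as.integer(as.factor(clusters))
  if (length(cl) != ncol(downX)) stop("one reference cluster per cell required")
  ## genes uniformly zero within each reference cluster, in the full data
  posPerCluster <- t(rowsum(t(fullX > 0) * 1, group = cl))   # n x K
  zeroInCluster <- posPerCluster == 0
  lab <- matrix(NA_character_, nrow(downX), ncol(downX),
                dimnames = dimnames(downX))
  z <- downX == 0
  tz <- z & zeroInCluster[, cl, drop = FALSE]
  dz <- z & (fullX > 0)
  lab[z] <- "unlabeled"
  lab[tz] <- "true_zero"
  lab[dz] <- "dropout_zero"
  lab
}

#' Precision, recall and F1 for dropout-vs-true-zero discrimination
#'
#' An entry counts as *imputed* when its imputed value exceeds `eps`
#' (default 0: any positive value). Over the labeled zeros only: TP are
#' imputed dropout zeros, TN non-imputed true zeros, FP imputed true
#' zeros, FN non-imputed dropout zeros; `"unlabeled"` zeros are ignored.
#' F1 is the harmonic mean of precision and recall (0 when undefined).
#'
#' @param result An [ImputedExperiment-class] computed on the down-sampled
#'   matrix, or the imputed matrix itself.
#' @param labels Label matrix from [classifyZeros()].
#' @param eps Imputation threshold.
#' @return List with `tp`, `tn`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
discriminationScores <- function(result, labels, eps = 0) {
  Y <- if (is(result, "ImputedExperiment")) imputed(result)
       else asDenseMatrix(result)
  if (!identical(dim(Y), dim(labels)))
    stop("imputed matrix and label matrix differ in dimension")
  dz <- labels == "dropout_zero" & !is.na(labels)
  tz <- labels == "true_zero" & !is.na(labels)
  if (!any(dz) && !any(tz)) stop("no labeled zero entries to score")
  imp <- Y > eps
  tp <- sum(imp & dz); fn <- sum(!imp & dz)
  fp <- sum(imp & tz); tn <- sum(!imp & tz)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       precision = precision, recall = recall, f1 = f1)
}

#' Adjusted Rand index of two partitions
#'
#' Hubert–Arabie chance-corrected agreement between two labelings of the
#' same items, computed from the contingency table:
#' `(sum C(n_ij,2) - E) / (M - E)` with
#' `E = sum C(a_i,2) * sum C(b_j,2) / C(N,2)` and
#' `M = (sum C(a_i,2) + sum C(b_j,2)) / 2`. Equals 1 for identical
#' partitions (including the degenerate case where both labelings place
#' all items in a single cluster) and is near 0 for independent random
#' labelings.
#'
#' @param a,b Labelings of the same N >= 2 items (any atomic type).
#' @return A real number <= 1.
#' @examples
#' adjustedRandIndex(c(1, 1, 2, 2), c(1, 2, 1, 2))  # -0.5
#' @export
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b)) stop("labelings differ in length")
  N <- length(a)
  if (N < 2) stop("need at least 2 items")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sij <- sum(choose2(tab))
  sa <- sum(choose2(rowSums(tab)))
  sb <- sum(choose2(colSums(tab)))
  E <- sa * sb / choose2(N)
  M <- (sa + sb) / 2
  if (M == E) return(1)   # both partitions trivial (e.g. both single-cluster)
  (sij - E) / (M - E)
}

#' Mean pairwise ARI across repeated clustering runs
#'
#' Clustering-robustness criterion: the ARI is computed for every pair of
#' runs and averaged (100 runs give 100*99/2 pairs). Runs may cover
#' different cell subsets (cell-level down-sampling); each pair is scored
#' on the overlap of its cell ids (a partial ARI), and pairs with fewer
#' than 2 overlapping cells are skipped with a warning.
#'
#' @param labelings List of named label vectors (names are cell ids) or of
#'   `list(cells = , labels = )` pairs.
#' @return Mean pairwise (partial) ARI.
#' @export
crossARI <- function(labelings) {
  if (length(labelings) < 2) stop("need at least 2 labelings")
  norm <- lapply(labelings, function(l) {
    if (is.list(l) && all(c("cells", "labels") %in% names(l)))
      stats::setNames(l$labels, l$cells)
    else {
      if (is.null(names(l))) names(l) <- seq_along(l)
      l
    }
  })
  n <- length(norm)
  vals <- c()
  skipped <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    common <- intersect(names(norm[[i]]), names(norm[[j]]))
    if (length(common) < 2) { skipped <- skipped + 1L; next }
    vals <- c(vals, adjustedRandIndex(norm[[i]][common], norm[[j]][common]))
  }
  if (skipped > 0)
    warning(skipped, " pair(s) skipped (fewer than 2 overlapping cells)")
  if (!length(vals)) stop("no scorable pairs")
  mean(vals)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation between an inferred ordering (e.g. a
#' pseudotime) and known ordinal labels (e.g. collection stages). Returns
#' 0 with a warning when either vector is constant.
#'
#' @param pseudotime,timeLabels Numeric/ordinal vectors of equal length
#'   >= 2.
#' @return Tau-b in [-1, 1].
#' @export
kendallTau <- function(pseudotime, timeLabels) {
  x <- as.numeric(pseudotime)
  y <- as.numeric(timeLabels)
  if (length(x) != length(y)) stop("vectors differ in length")
  if (length(x) < 2) stop("need at least 2 observations")
  if (max(x) == min(x) || max(y) == min(y)) {
    warning("constant vector; Kendall tau undefined, returning 0")
    return(0)
  }
  stats::cor(x, y, method = "kendall")
}

#' Concordance of two imputation results
#'
#' Pearson correlation of the imputed values over the zero entries of the
#' shared input matrix — the robustness measure used to compare runs with
#' different k ranges or random seeds.
#'
#' @param r1,r2 [ImputedExperiment-class] objects computed from the same
#'   input (identical zero masks required).
#' @return Pearson correlation over the imputation candidates.
#' @export
imputationConcordance <- function(r1, r2) {
  m1 <- zeroMask(r1); m2 <- zeroMask(r2)
  if (!identical(dim(m1), dim(m2)) || !all(m1 == m2))
    stop("results come from different inputs (zero masks differ)")
  v1 <- imputed(r1)[m1]
  v2 <- imputed(r2)[m2]
  stats::cor(v1, v2)
}

#' Down-sampling discrimination benchmark
#'
#' The evaluation pipeline on one dataset and rate: binomially thin the
#' full counts, filter genes on the thinned matrix (both matrices subset to
#' the kept genes), normalise both, label the zeros of the thinned matrix
#' against the reference clusters, impute the thinned matrix, and score
#' dropout-vs-true-zero discrimination. Also scores a global gene-mean
#' imputer (every zero replaced by its gene's mean over all cells) and the
#' no-imputation baseline, and reports root-mean-square error against the
#' full log-expression at the dropout-zero entries for the imputed values
#' and for leaving zeros in place.
#'
#' @param fullCounts Full (not thinned) count matrix.
#' @param clusters Reference cluster label per cell.
#' @param rate Thinning rate in (0, 1).
#' @param seed Seed for thinning and imputation.
#' @param minCells Gene filter threshold.
#' @param ... Passed to [imputeDropouts()] (e.g. `ks`, `metrics`, `mode`).
#' @return List: `scores` (hot-deck PRF1), `scoresGeneMean`,
#'   `scoresNoImpute`, `rmseImputed`, `rmseZero`, `nDropout`, `nTrueZero`,
#'   and the `result` object.
#' @export
benchmarkDownsampling <- function(fullCounts, clusters, rate, seed = 1L,
                                  minCells = 2L, ...) {
  fullCounts <- validateCounts(asDenseMatrix(fullCounts))
  down <- downsampleCounts(fullCounts, rate, seed = childSeed(seed, "thin"))
  downF <- filterGenes(down, minCells)
  genes <- rownames(downF)
  fullF <- fullCounts[genes, , drop = FALSE]
  fullX <- normalizeLog(fullF)
  res <- imputeDropouts(downF, seed = seed, minCells = minCells, ...)
  stopifnot(identical(rownames(res), genes))
  downX <- SummarizedExperiment::assay(res, "logcounts")
  labels <- classifyZeros(fullX, downX, clusters)
  sc <- discriminationScores(res, labels)
  ## baselines: gene-mean imputer and no imputation
  gm <- downX
  zm <- downX == 0
  gmean <- rowMeans(downX)
  gm[zm] <- (gmean[row(gm)])[zm]
  scGM <- discriminationScores(gm, labels)
  scNone <- discriminationScores(downX, labels)
  dz <- labels == "dropout_zero" & !is.na(labels)
  rmse <- function(Y) sqrt(mean((Y[dz] - fullX[dz])^2))
  list(scores = sc, scoresGeneMean = scGM, scoresNoImpute = scNone,
       rmseImputed = rmse(imputed(res)), rmseZero = rmse(downX),
       nDropout = sum(dz),
       nTrueZero = sum(labels == "true_zero", na.rm = TRUE),
       result = res)
}
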