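#' Per-clustering hot-deck estimates of zero entries
#'
#' Under one base clustering, the estimate for entry (i, j) is the mean of
#' gene i's log-expression over all cells in the cluster containing cell j
#' — including zero entries of cluster mates and cell j's own zero, since
#' the estimator conditions only on cluster membership. A cell in a
#' singleton cluster therefore keeps its zeros at 0.
#'
#' @param X Log-expression matrix, genes x cells.
#' @param labels Integer cluster labels, one per cell (a
#'   [kmeansCluster()] result or any vector of length `ncol(X)`).
#' @param excludeSelf If `TRUE`, the target cell's own zero is excluded
#'   from the cluster mean (singleton clusters then estimate 0).
#' @return n x p matrix of cluster-mean estimates, defined at every entry;
#'   only the entries where `X == 0` are the imputation candidates.
#' @examples
#' X <- rbind(g = c(0, 2, 4, 0))
#' clusterMeanEstimates(X, c(1, 1, 2, 2))[1, c(1, 4)]  # 1.0 and 2.0
#' @export
clusterMeanEstimates <- function(X, labels, excludeSelf = FALSE) {
  X <- asDenseMatrix(X)
  labels <- as.integer(labels)
  if (length(labels) != ncol(X)) stop("one label per cell required")
  sizes <- tabulate(labels)
  used <- which(sizes > 0)
  ## gene-wise cluster sums via rowsum on the transposed matrix
  sums <- t(rowsum(t(X), group = labels))        # n x |used|, ordered by label
  means <- sweep(sums, 2, sizes[used], "/")
  est <- means[, match(labels, used), drop = FALSE]
  if (excludeSelf) {
    n1 <- sizes[labels] - 1L
    est <- ifelse(rep(n1, each = nrow(X)) > 0,
                  (est * rep(sizes[labels], each = nrow(X)) - X) /
                    rep(pmax(n1, 1L), each = nrow(X)),
                  0)
    dim(est) <- dim(X)
  }
  dimnames(est) <- dimnames(X)
  est
}

#' Average hot-deck estimates over an ensemble of clusterings
#'
#' The consensus imputation: every zero entry of `X` is replaced by the
#' arithmetic mean, over the H base clusterings, of its per-clustering
#' cluster-mean estimate; non-zero entries are copied unchanged. An entry
#' whose cluster mates are zero under every clustering stays exactly 0,
#' which is how cluster-consistent true zeros survive imputation.
#'
#' @param X Log-expression matrix, genes x cells.
#' @param ensemble A [ClusterEnsemble-class], or a list of label vectors
#'   covering the same cells.
#' @param keepPerConfig Retain the per-configuration estimates at zero
#'   entries (as a list of numeric vectors over `which(X == 0)`) in the
#'   result metadata.
#' @param excludeSelf Passed to [clusterMeanEstimates()].
#' @return An [ImputedExperiment-class] with assays `logcounts` and
#'   `imputed`.
#' @export
ensembleImpute <- function(X, ensemble, keepPerConfig = FALSE,
                           excludeSelf = FALSE) {
  X <- asDenseMatrix(X)
  if (is(ensemble, "ClusterEnsemble")) {
    labs <- ensemble@labels
    configs <- ensemble@configs
    seed <- ensemble@seed
  } else if (is.list(ensemble) && length(ensemble)) {
    labs <- do.call(cbind, lapply(ensemble, as.integer))
    configs <- data.frame(metric = NA_character_,
                          k = apply(labs, 2, function(l) length(unique(l))),
                          mode = "external", seed = NA_integer_)
    seed <- NA_integer_
  } else stop("ensemble must be a ClusterEnsemble or a non-empty list")
  if (nrow(labs) != ncol(X)) stop("ensemble covers a different number of cells")
  H <- ncol(labs)
  if (H == 0L) stop("empty ensemble")
  zm <- X == 0
  zi <- which(zm)
  acc <- numeric(length(zi))
  perConfig <- if (keepPerConfig) vector("list", H) else NULL
  for (h in seq_len(H)) {
    est <- clusterMeanEstimates(X, labs[, h], excludeSelf = excludeSelf)[zi]
    acc <- acc + est
    if (keepPerConfig) perConfig[[h]] <- est
  }
  Y <- X
  Y[zi] <- acc / H
  md <- list(configs = configs, seed = seed)
  if (keepPerConfig) md$perConfigEstimates <- perConfig
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(logcounts = X, imputed = Y), metadata = md)
  new("ImputedExperiment", se)
}

#' Full hot-deck imputation pipeline for a count matrix
#'
#' Composes the whole pipeline: gene filtering (expressed in fewer than
#' `minCells` cells removed), median-of-ratios size-factor normalisation,
#' log10(x + 1) transformation, the (metric x k) ensemble of base
#' clusterings, and the averaged hot-deck imputation of the zero entries.
#'
#' @param counts Raw count matrix (genes x cells), or a
#'   SummarizedExperiment with a `counts` assay.
#' @param ks,metrics,mode,seed,frac,mLandmarks,batchSize,largeThreshold
#'   Passed to [buildEnsemble()].
#' @param minCells,normalize Passed to [preprocessCounts()].
#' @param keepPerConfig,excludeSelf Passed to [ensembleImpute()].
#' @return An [ImputedExperiment-class]; its `logcounts` assay is the
#'   filtered, normalised log-expression matrix that was imputed, and the
#'   metadata records the configurations and size factors.
#' @examples
#' sim <- simulateCells(nGenes = 60, nCells = 40, nClusters = 2, seed = 1)
#' res <- imputeDropouts(SummarizedExperiment::assay(sim, "counts"),
#'                       ks = 2:3, metrics = "pearson", seed = 1)
#' res
#' @export
imputeDropouts <- function(counts, ks = 10:15,
                           metrics = c("pearson", "spearman"),
                           mode = c("auto", "exact", "large_scale"),
                           seed = 1L, minCells = 2L, normalize = TRUE,
                           frac = 0.05, mLandmarks = 1000L, batchSize = 100L,
                           largeThreshold = 5000L, keepPerConfig = FALSE,
                           excludeSelf = FALSE) {
  pp <- preprocessCounts(counts, minCells = minCells, normalize = normalize)
  ens <- buildEnsemble(pp$X, ks = ks, metrics = metrics, mode = mode,
                       seed = seed, frac = frac, mLandmarks = mLandmarks,
                       batchSize = batchSize, largeThreshold = largeThreshold)
  res <- ensembleImpute(pp$X, ens, keepPerConfig = keepPerConfig,
                        excludeSelf = excludeSelf)
  S4Vectors::metadata(res)$sizeFactors <- pp$sizeFactors
  res
}
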