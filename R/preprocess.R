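#' Remove genes expressed in too few cells
#'
#' Drops genes with a non-zero count in fewer than `minCells` cells
#' (default 2). "Expressed" means count > 0; no CPM-style threshold is
#' applied. Gene order is otherwise preserved.
#'
#' @param m Count matrix (genes x cells) or SummarizedExperiment.
#' @param minCells Minimum number of cells with a positive count.
#' @return The filtered count matrix.
#' @export
filterGenes <- function(m, minCells = 2L) {
  m <- validateCounts(asDenseMatrix(m))
  if (minCells < 1L) stop("minCells must be >= 1")
  keep <- rowSums(m > 0) >= minCells
  if (!any(keep)) stop("all genes removed by the expression filter")
  m[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-cell scaling constants correcting for sequencing depth: each cell's
#' counts are divided by the gene-wise geometric mean across cells, and the
#' size factor is the median of those ratios over usable genes. In the
#' classical estimator only genes with strictly positive counts in every
#' cell are usable. Sparse single-cell matrices often have no such gene; in
#' that case a fallback (with a logged warning) computes each gene's
#' geometric mean over the cells where it is positive and takes, per cell,
#' the median ratio over the genes positive in that cell. The fallback
#' reduces to the classical estimator on dense data.
#'
#' @param m Count matrix (genes x cells); every cell needs at least one
#'   positive count.
#' @return Numeric vector of positive size factors, one per cell, named by
#'   cell.
#' @examples
#' m <- matrix(c(1, 2, 2, 4, 3, 6), 3, 2, byrow = TRUE)
#' computeSizeFactors(m)  # (1/sqrt(2), sqrt(2))
#' @export
computeSizeFactors <- function(m) {
  m <- validateCounts(asDenseMatrix(m))
  if (any(colSums(m) == 0)) stop("every cell needs at least one nonzero count")
  allPos <- rowSums(m > 0) == ncol(m)
  if (any(allPos)) {
    sub <- m[allPos, , drop = FALSE]
    geo <- exp(rowMeans(log(sub)))
    s <- apply(sub / geo, 2, stats::median)
  } else {
    warning("no gene is positive in all cells; ",
            "using positive-cell geometric means (sparse fallback)")
    shdLog("size factors: sparse fallback (no gene positive in all cells)")
    lg <- log(m)
    lg[m == 0] <- NA
    geo <- exp(rowMeans(lg, na.rm = TRUE))   # geometric mean over positive cells
    ratio <- m / geo
    ratio[m == 0] <- NA
    s <- apply(ratio, 2, stats::median, na.rm = TRUE)
  }
  if (any(!is.finite(s)) || any(s <= 0))
    stop("size factor estimation failed (non-positive or non-finite factor)")
  names(s) <- colnames(m)
  s
}

#' Normalise and log-transform counts
#'
#' Produces the log-expression matrix `X[i, j] = log10(count[i, j] / s[j] + 1)`.
#' Zero counts map exactly to zero, so the zero pattern of the expression
#' matrix equals that of the counts — zeros are the imputation candidates.
#'
#' @param m Count matrix (genes x cells).
#' @param s Size factors from [computeSizeFactors()], or `NULL` to compute
#'   them; use `rep(1, ncol(m))` to skip depth normalisation.
#' @return Real-valued matrix on log10 scale, same dimnames as `m`.
#' @export
normalizeLog <- function(m, s = NULL) {
  m <- validateCounts(asDenseMatrix(m))
  if (is.null(s)) s <- computeSizeFactors(m)
  if (length(s) != ncol(m)) stop("one size factor per cell required")
  if (any(!is.finite(s)) || any(s <= 0)) stop("size factors must be positive")
  X <- log10(sweep(m, 2, s, "/") + 1)
  dimnames(X) <- dimnames(m)
  X
}

#' Filter, normalise and log-transform in one step
#'
#' Convenience composition: gene filtering (fewer than `minCells` expressing
#' cells), then median-of-ratios size factors, then `log10(x/s + 1)`.
#' Filtering precedes size-factor computation.
#'
#' @inheritParams filterGenes
#' @param normalize If `FALSE`, use size factors of 1 (raw counts).
#' @return List with `X` (log-expression matrix), `counts` (filtered
#'   counts) and `sizeFactors`.
#' @export
preprocessCounts <- function(m, minCells = 2L, normalize = TRUE) {
  counts <- filterGenes(m, minCells)
  s <- if (normalize) computeSizeFactors(counts)
       else stats::setNames(rep(1, ncol(counts)), colnames(counts))
  list(X = normalizeLog(counts, s), counts = counts, sizeFactors = s)
}
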