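#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Ensemble of base clusterings
#'
#' Holds the H base clusterings produced by [buildEnsemble()]: one cell
#' labelling per (correlation metric, k) configuration, together with the
#' generating configuration table and the master seed.
#'
#' @slot labels integer matrix, cells x H; column h is the labelling of
#'   configuration h, labels in `1..k_h`.
#' @slot configs `data.frame` with one row per configuration: columns
#'   `metric`, `k`, `mode`, `seed`.
#' @slot cellIds character vector of cell identifiers.
#' @slot seed integer master seed.
#' @export
setClass("ClusterEnsemble",
  representation(labels = "matrix", configs = "data.frame",
                 cellIds = "character", seed = "integer"))

setValidity("ClusterEnsemble", function(object) {
  msg <- character()
  if (ncol(object@labels) != nrow(object@configs))
    msg <- c(msg, "one configs row per labels column required")
  if (nrow(object@labels) != length(object@cellIds))
    msg <- c(msg, "one label per cell required")
  if (nrow(object@configs)) {
    bad <- vapply(seq_len(ncol(object@labels)), function(h) {
      l <- object@labels[, h]
      any(l < 1L) || any(l > object@configs$k[h])
    }, TRUE)
    if (any(bad)) msg <- c(msg, "labels out of 1..k range")
  }
  if (length(msg)) msg else TRUE
})

#' Result of ensemble hot-deck imputation
#'
#' A [SummarizedExperiment::SummarizedExperiment] with two assays:
#' `logcounts` (the normalised log10 expression matrix that was imputed)
#' and `imputed` (the same matrix with every zero entry replaced by the
#' ensemble estimate). Non-zero entries are preserved exactly — the
#' defining hot-deck property — and the class validity enforces it.
#' Metadata carries the configuration table, the master seed and,
#' optionally, the per-configuration estimates at zero entries.
#'
#' @export
setClass("ImputedExperiment",
  contains = "SummarizedExperiment")

setValidity("ImputedExperiment", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("logcounts", "imputed") %in% an))
    return("assays 'logcounts' and 'imputed' are required")
  X <- SummarizedExperiment::assay(object, "logcounts")
  Y <- SummarizedExperiment::assay(object, "imputed")
  nz <- X != 0
  if (any(Y[nz] != X[nz]))
    return("non-zero entries must be preserved exactly")
  if (any(Y < 0))
    return("imputed values must be non-negative")
  TRUE
})

#' Synthetic clustered scRNA-seq dataset with ground truth
#'
#' A [SummarizedExperiment::SummarizedExperiment] produced by
#' [simulateCells()], with assays `counts` (observed, after dropout),
#' `trueCounts` (before dropout) and `dropoutMask` (1 where a positive
#' true count was zeroed). `colData` holds the true cluster label and
#' library-size factor per cell; metadata holds the generator parameters
#' and the gene-by-cluster matrix of true log10 mean expression.
#'
#' @export
setClass("SyntheticScExperiment",
  contains = "SummarizedExperiment")

setValidity("SyntheticScExperiment", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("counts", "trueCounts", "dropoutMask") %in% an))
    return("assays 'counts', 'trueCounts', 'dropoutMask' are required")
  obs <- SummarizedExperiment::assay(object, "counts")
  tru <- SummarizedExperiment::assay(object, "trueCounts")
  msk <- SummarizedExperiment::assay(object, "dropoutMask") > 0
  if (any(obs > tru)) return("observed counts must be <= true counts")
  if (any(obs[msk] != 0) || any(tru[msk] <= 0))
    return("dropout mask must flag exactly zeroed positive true counts")
  if (!"cluster" %in% colnames(SummarizedExperiment::colData(object)))
    return("colData must contain a 'cluster' column")
  TRUE
})
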