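#' @describeIn ImputedExperiment-class The imputed log-expression matrix.
#' @export
setMethod("imputed", "ImputedExperiment", function(x)
  SummarizedExperiment::assay(x, "imputed"))

#' @describeIn ImputedExperiment-class Logical matrix, `TRUE` where the
#'   input log-expression was zero (the imputation candidates).
#' @export
setMethod("zeroMask", "ImputedExperiment", function(x)
  SummarizedExperiment::assay(x, "logcounts") == 0)

#' @describeIn ImputedExperiment-class The base-clustering configuration
#'   table (one row per ensemble member).
#' @export
setMethod("imputeConfigs", "ImputedExperiment", function(x)
  S4Vectors::metadata(x)$configs)

#' @describeIn SyntheticScExperiment-class Pre-dropout count matrix.
#' @export
setMethod("trueCounts", "SyntheticScExperiment", function(x)
  SummarizedExperiment::assay(x, "trueCounts"))

#' @describeIn SyntheticScExperiment-class Logical matrix flagging the
#'   simulated dropout events (positive true count observed as zero).
#' @export
setMethod("dropoutMask", "SyntheticScExperiment", function(x)
  SummarizedExperiment::assay(x, "dropoutMask") > 0)

#' @describeIn SyntheticScExperiment-class Ground-truth cluster label per
#'   cell, as a named integer vector.
#' @export
setMethod("cellClusters", "SyntheticScExperiment", function(x) {
  cl <- SummarizedExperiment::colData(x)$cluster
  names(cl) <- colnames(x)
  cl
})

#' @describeIn ClusterEnsemble-class Cells-by-H integer matrix of base
#'   clustering labels.
#' @export
setMethod("clusterLabels", "ClusterEnsemble", function(x) x@labels)

#' @describeIn ClusterEnsemble-class Number of ensemble members H.
#' @param object A `ClusterEnsemble`.
#' @export
setMethod("length", "ClusterEnsemble", function(x) ncol(x@labels))

setMethod("show", "ClusterEnsemble", function(object) {
  cat("ClusterEnsemble with", ncol(object@labels), "base clusterings of",
      nrow(object@labels), "cells\n")
  cfg <- object@configs
  cat("  metrics:", paste(unique(cfg$metric), collapse = ", "),
      "| k:", paste(range(cfg$k), collapse = "-"),
      "| mode:", paste(unique(cfg$mode), collapse = ", "),
      "| master seed:", object@seed, "\n")
})

setMethod("show", "ImputedExperiment", function(object) {
  cat("ImputedExperiment:", nrow(object), "genes x", ncol(object), "cells\n")
  zm <- SummarizedExperiment::assay(object, "logcounts") == 0
  imp <- SummarizedExperiment::assay(object, "imputed")
  cat("  zero entries:", sum(zm),
      sprintf("(%.1f%%)", 100 * mean(zm)),
      "| imputed > 0:", sum(imp[zm] > 0), "\n")
  cfg <- S4Vectors::metadata(object)$configs
  if (!is.null(cfg))
    cat("  ensemble: H =", nrow(cfg), "configurations\n")
})

setMethod("show", "SyntheticScExperiment", function(object) {
  cat("SyntheticScExperiment:", nrow(object), "genes x", ncol(object),
      "cells,", length(unique(SummarizedExperiment::colData(object)$cluster)),
      "clusters\n")
  cat("  dropout events:", sum(dropoutMask(object)), "\n")
})
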