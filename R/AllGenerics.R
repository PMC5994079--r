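#' @rdname ImputedExperiment-class
#' @param x An object.
#' @export
setGeneric("imputed", function(x) standardGeneric("imputed"))

#' @rdname ImputedExperiment-class
#' @export
setGeneric("zeroMask", function(x) standardGeneric("zeroMask"))

#' @rdname ImputedExperiment-class
#' @export
setGeneric("imputeConfigs", function(x) standardGeneric("imputeConfigs"))

#' @rdname SyntheticScExperiment-class
#' @param x An object.
#' @export
setGeneric("trueCounts", function(x) standardGeneric("trueCounts"))

#' @rdname SyntheticScExperiment-class
#' @export
setGeneric("dropoutMask", function(x) standardGeneric("dropoutMask"))

#' @rdname SyntheticScExperiment-class
#' @export
setGeneric("cellClusters", function(x) standardGeneric("cellClusters"))

#' @rdname ClusterEnsemble-class
#' @param x An object.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
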