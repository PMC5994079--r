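#' @importFrom methods new is validObject slot
#' @importFrom stats cor kmeans median prcomp rbinom rnbinom rnorm runif sd
#' @importFrom utils read.table write.table head
NULL

#' Derive a child seed from a master seed and a key
#'
#' Stable 31-bit hash of the master seed together with an arbitrary key
#' (stage name, metric, k, ...), so that independent random streams can be
#' spawned reproducibly from one master seed.
#'
#' @param seed Integer master seed.
#' @param ... Key components (coerced to character).
#' @return An integer in `[0, 2^31 - 2]`.
#' @examples
#' childSeed(1L, "kmeans", "pearson", 10)
#' @export
childSeed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "/")
  h <- 0
  for (x in utf8ToInt(key)) h <- (h * 31 + x) %% 2147483647
  as.integer(h)
}

## run expr under a local, restored RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

shdLog <- function(...) message("[scHotDeck] ", ...)

## coerce SummarizedExperiment / sparse / data.frame input to a dense
## base matrix, keeping dimnames
asDenseMatrix <- function(x, assay = "counts") {
  if (is(x, "SummarizedExperiment")) {
    an <- SummarizedExperiment::assayNames(x)
    a <- if (assay %in% an) assay else an[1L]
    x <- SummarizedExperiment::assay(x, a)
  }
  if (is(x, "Matrix")) x <- as.matrix(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("input must be a numeric matrix (or SummarizedExperiment)")
  x
}

## validate the count-matrix contract: non-negative integral entries,
## unique non-empty gene/cell identifiers
validateCounts <- function(m) {
  if (nrow(m) == 0L || ncol(m) == 0L)
    stop("count matrix must have at least one gene and one cell")
  if (anyNA(m)) stop("count matrix contains NA entries")
  if (any(m < 0)) stop("count matrix contains negative entries")
  if (any(m != round(m))) stop("count matrix contains non-integer entries")
  if (is.null(rownames(m)))
    rownames(m) <- paste0("gene", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- paste0("cell", seq_len(ncol(m)))
  if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(m))) stop("duplicate cell identifiers")
  storage.mode(m) <- "double"
  m
}
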