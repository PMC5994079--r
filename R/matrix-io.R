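#' Read a gene-by-cell matrix from MTX, CSV or TSV
#'
#' Reads a count (or real-valued expression) matrix with genes as rows and
#' cells as columns. For Matrix Market files the gene and cell identifiers
#' live in plain-text sidecar files (10x style), by default `<stem>.genes.txt`
#' and `<stem>.barcodes.txt` next to the matrix (also accepted:
#' `genes.tsv`/`features.tsv` and `barcodes.tsv` in the same directory).
#' 10x writes genes as rows too, but a transposed file must be handled by
#' the caller — there is deliberately no auto-detection, since silent
#' transposition is the costliest failure mode.
#'
#' @param path Path to the matrix file.
#' @param format One of `"mtx"`, `"csv"`, `"tsv"`; default guessed from the
#'   file extension.
#' @param genes,cells Optional explicit paths to the sidecar identifier
#'   lists (MTX only; one id per line, first column used).
#' @param counts If `TRUE` (default) validate the count contract
#'   (non-negative integral entries); set `FALSE` for real-valued matrices
#'   such as imputed output.
#' @return A dense numeric matrix with unique rownames (genes) and
#'   colnames (cells).
#' @examples
#' d <- tempfile(fileext = ".csv")
#' writeCountMatrix(matrix(0:5, 2, 3, dimnames = list(c("g1", "g2"), NULL)), d)
#' readCountMatrix(d)
#' @export
readCountMatrix <- function(path, format = c("auto", "mtx", "csv", "tsv"),
                            genes = NULL, cells = NULL, counts = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                     stop("cannot guess format from extension of ", path))
  }
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    sc <- .sidecarPaths(path, genes, cells)
    rownames(m) <- .readIdList(sc$genes, nrow(m), "gene")
    colnames(m) <- .readIdList(sc$cells, ncol(m), "cell")
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, comment.char = "")
    m <- as.matrix(df)
    if (!is.numeric(m)) stop("non-numeric entries in ", path)
  }
  if (counts) m <- validateCounts(m)
  else {
    if (anyNA(m)) stop("matrix contains NA entries")
    if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers")
    if (anyDuplicated(colnames(m))) stop("duplicate cell identifiers")
  }
  m
}

.sidecarPaths <- function(path, genes, cells) {
  stem <- sub("\\.mtx$", "", path)
  dir <- dirname(path)
  gc <- c(genes,
          paste0(stem, ".genes.txt"), paste0(stem, ".genes.tsv"),
          file.path(dir, c("genes.tsv", "genes.txt", "features.tsv")))
  cc <- c(cells,
          paste0(stem, ".barcodes.txt"), paste0(stem, ".barcodes.tsv"),
          file.path(dir, c("barcodes.tsv", "barcodes.txt")))
  g <- gc[file.exists(gc)][1]
  b <- cc[file.exists(cc)][1]
  if (is.na(g)) stop("gene id sidecar not found next to ", path)
  if (is.na(b)) stop("cell id sidecar not found next to ", path)
  list(genes = g, cells = b)
}

.readIdList <- function(path, n, what) {
  ids <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = "character")[[1]]
  if (length(ids) != n)
    stop(length(ids), " ", what, " ids for ", n, " rows in ", path)
  if (anyDuplicated(ids)) stop("duplicate ", what, " identifiers in ", path)
  ids
}

#' Write a gene-by-cell matrix to MTX, CSV or TSV
#'
#' Inverse of [readCountMatrix()]: integer count matrices round-trip
#' exactly; real-valued matrices are written with enough digits (15
#' significant) to round-trip within floating-point formatting precision.
#' For MTX, identifier sidecars `<stem>.genes.txt` and `<stem>.barcodes.txt`
#' are written next to the matrix.
#'
#' @param m Numeric matrix with rownames (genes) and colnames (cells);
#'   unnamed dimensions get `gene<i>` / `cell<j>` ids.
#' @param path Destination file.
#' @param format `"mtx"`, `"csv"` or `"tsv"` (default from extension).
#' @return Invisibly, `path`.
#' @export
writeCountMatrix <- function(m, path, format = c("auto", "mtx", "csv", "tsv")) {
  format <- match.arg(format)
  m <- asDenseMatrix(m)
  if (nrow(m) == 0L || ncol(m) == 0L)
    stop("refusing to write an empty matrix")
  if (is.null(rownames(m))) rownames(m) <- paste0("gene", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("cell", seq_len(ncol(m)))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                     stop("cannot guess format from extension of ", path))
  }
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(rownames(m), paste0(stem, ".genes.txt"))
    writeLines(colnames(m), paste0(stem, ".barcodes.txt"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- as.data.frame(signif(m, 15))
    utils::write.table(data.frame(gene = rownames(m), df,
                                  check.names = FALSE),
                       path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
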