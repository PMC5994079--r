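#' Simulate a clustered scRNA-seq count matrix with known ground truth
#'
#' Generates negative-binomial counts for `nCells` cells in `nClusters`
#' populations, then applies a dropout model, keeping the pre-dropout
#' counts, the dropout mask and the cluster labels as ground truth. The
#' generative model:
#'
#' * each gene draws a baseline mean from a log-normal distribution
#'   (`baseMean`, `baseSigma` on the natural-log scale), giving the
#'   many-low / few-high expression profile typical of scRNA-seq;
#' * per cluster, a fraction `fracZero` of genes is structurally silent
#'   (mean exactly 0 in that cluster) — these create true zeros that are
#'   consistently zero across all cells of the cluster;
#' * per cluster, a fraction `fracMarker` of the remaining genes is
#'   up-regulated by `logFC` on the natural-log scale (marker genes);
#' * cells scale their means by a log-normal library-size factor
#'   (`libsizeSigma`), and counts are drawn from a negative binomial with
#'   `dispersion` (variance mu + dispersion * mu^2) — overdispersion keeps
#'   dropout distinguishable from mere low expression;
#' * dropout: `list(type = "binomial_thin", rate = )` thins every count
#'   binomially (rate 1 disables dropout), or
#'   `list(type = "logistic", midpoint = , slope = )` zeroes entries with
#'   probability `1 / (1 + exp(slope * (log(mu + 1) - midpoint)))`, so
#'   lowly expressed entries drop out preferentially.
#'
#' All randomness derives from `seed`; identical parameters give a
#' bitwise-identical dataset.
#'
#' @param nGenes,nCells,nClusters Dimensions of the simulation.
#' @param fracMarker Fraction of genes up-regulated per cluster.
#' @param logFC Marker effect on the natural-log scale.
#' @param baseMean Median baseline mean count per gene.
#' @param baseSigma Log-normal spread of baseline gene means.
#' @param libsizeSigma Log-normal spread of cell library-size factors.
#' @param dispersion Negative-binomial dispersion (0 gives Poisson).
#' @param fracZero Fraction of genes structurally silent per cluster.
#' @param dropout Dropout model (see above).
#' @param seed Integer seed.
#' @return A [SyntheticScExperiment-class] with assays `counts` (observed),
#'   `trueCounts` and `dropoutMask`; `colData` columns `cluster` and
#'   `libFactor`; metadata `params` and `trueLogMeans` (gene x cluster
#'   log10(mean + 1)).
#' @examples
#' sim <- simulateCells(nGenes = 100, nCells = 60, nClusters = 3, seed = 1)
#' sim
#' @export
simulateCells <- function(nGenes = 2000L, nCells = 300L, nClusters = 3L,
                          fracMarker = 0.1, logFC = 1.0, baseMean = 2,
                          baseSigma = 1.2, libsizeSigma = 0.3,
                          dispersion = 0.2, fracZero = 0.2,
                          dropout = list(type = "binomial_thin", rate = 0.3),
                          seed = 1L) {
  if (nClusters > nCells) stop("more clusters than cells")
  if (nGenes < 1 || nCells < 1 || nClusters < 1) stop("dimensions must be >= 1")
  if (fracMarker <= 0 || fracMarker > 1) stop("fracMarker must be in (0, 1]")
  if (logFC < 0 || baseMean <= 0 || libsizeSigma < 0 || dispersion < 0 ||
      fracZero < 0 || fracZero >= 1)
    stop("invalid scale parameter")
  if (!is.list(dropout) || is.null(dropout$type) ||
      !dropout$type %in% c("binomial_thin", "logistic"))
    stop("dropout must be list(type = 'binomial_thin'|'logistic', ...)")
  if (dropout$type == "binomial_thin" &&
      (is.null(dropout$rate) || dropout$rate <= 0 || dropout$rate > 1))
    stop("binomial_thin dropout needs rate in (0, 1]")
  if (dropout$type == "logistic" &&
      (is.null(dropout$midpoint) || is.null(dropout$slope)))
    stop("logistic dropout needs midpoint and slope")

  params <- list(nGenes = nGenes, nCells = nCells, nClusters = nClusters,
                 fracMarker = fracMarker, logFC = logFC, baseMean = baseMean,
                 baseSigma = baseSigma, libsizeSigma = libsizeSigma,
                 dispersion = dispersion, fracZero = fracZero,
                 dropout = dropout, seed = seed)

  withSeed(childSeed(seed, "simulate"), {
    base <- exp(stats::rnorm(nGenes, log(baseMean), baseSigma))
    mu <- matrix(base, nGenes, nClusters)          # gene x cluster means
    for (k in seq_len(nClusters)) {
      silent <- sample.int(nGenes, round(fracZero * nGenes))
      mu[silent, k] <- 0
      candidates <- setdiff(seq_len(nGenes), silent)
      markers <- sample(candidates, round(fracMarker * nGenes))
      mu[markers, k] <- mu[markers, k] * exp(logFC)
    }
    cl <- sort(rep_len(seq_len(nClusters), nCells))
    lib <- exp(stats::rnorm(nCells, 0, libsizeSigma))
    muCell <- mu[, cl, drop = FALSE] * rep(lib, each = nGenes)
    tru <- matrix(0, nGenes, nCells)
    pos <- which(muCell > 0)
    tru[pos] <- if (dispersion > 0)
      stats::rnbinom(length(pos), mu = muCell[pos], size = 1 / dispersion)
    else stats::rpois(length(pos), muCell[pos])

    obs <- tru
    if (dropout$type == "binomial_thin") {
      if (dropout$rate < 1) {
        nz <- which(tru > 0)
        obs[nz] <- stats::rbinom(length(nz), tru[nz], dropout$rate)
      }
    } else {
      pdrop <- 1 / (1 + exp(dropout$slope * (log(muCell + 1) - dropout$midpoint)))
      drop <- matrix(stats::runif(length(tru)) < pdrop, nGenes, nCells)
      obs[drop] <- 0
    }
    mask <- obs == 0 & tru > 0

    gids <- sprintf("gene%04d", seq_len(nGenes))
    cids <- sprintf("cell%04d", seq_len(nCells))
    dimnames(tru) <- dimnames(obs) <- dimnames(mask) <- list(gids, cids)
    tlm <- log10(mu + 1)
    dimnames(tlm) <- list(gids, paste0("cluster", seq_len(nClusters)))
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = obs, trueCounts = tru,
                    dropoutMask = mask * 1),
      colData = S4Vectors::DataFrame(cluster = cl, libFactor = lib,
                                     row.names = cids),
      metadata = list(params = params, trueLogMeans = tlm))
    new("SyntheticScExperiment", se)
  })
}
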