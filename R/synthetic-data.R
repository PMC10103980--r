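#' Generate a synthetic gene-position table
#'
#' Lays out non-overlapping gene intervals (1-based, inclusive) along each of
#' \code{nChromosomes} chromosomes named \code{"1"}, \code{"2"}, ...: each
#' chromosome is divided into equal bins, one gene per bin, with the start
#' drawn uniformly from the first half of the bin and the end strictly inside
#' it. This mirrors the gene/chromosome/start/stop position files consumed by
#' expression-based copy-number tools.
#'
#' @param nChromosomes number of chromosomes.
#' @param genesPerChromosome genes per chromosome.
#' @param chromosomeLength chromosome length in base pairs.
#' @param seed integer seed; the same seed gives a byte-identical table.
#' @return A \link[GenomicRanges]{GRanges} with one range per gene, named by
#'   gene id (\code{"g<chrom>_<index>"}), sorted by (chromosome, start).
#' @examples
#' gp <- makeGenePositions(2, 5, 1e6, seed = 1)
#' @export
makeGenePositions <- function(nChromosomes, genesPerChromosome,
                              chromosomeLength = 1e8, seed = 1L) {
  if (nChromosomes < 1 || genesPerChromosome < 1 || chromosomeLength < 1)
    stop("nChromosomes, genesPerChromosome and chromosomeLength must be >= 1")
  withSeed(seed, {
    binWidth <- chromosomeLength / genesPerChromosome
    chrom <- rep(as.character(seq_len(nChromosomes)),
                 each = genesPerChromosome)
    binStart <- rep((seq_len(genesPerChromosome) - 1) * binWidth,
                    times = nChromosomes)
    n <- nChromosomes * genesPerChromosome
    start <- floor(binStart + runif(n) * binWidth / 2) + 1
    end <- floor(binStart + binWidth / 2 + runif(n) * (binWidth / 2 - 1)) + 1
    end <- pmax(end, start)
    gr <- GRanges(chrom, IRanges(start = start, end = end))
    names(gr) <- paste0("g", chrom, "_",
                        rep(seq_len(genesPerChromosome), nChromosomes))
    gr
  })
}

# Draw per-cell x per-chromosome copy ratios. Reference cells are all 1.0;
# each observation cell is aneuploid with probability aneuploidFraction, in
# which case 1..maxAlteredChromosomes whole chromosomes get ratios drawn from
# copyRatios.
drawKaryotype <- function(config, chromNames, cellIds, group) {
  nCells <- length(cellIds)
  truth <- matrix(1, nrow = nCells, ncol = length(chromNames),
                  dimnames = list(cellIds, chromNames))
  obs <- which(group == "observation")
  if (config@aneuploidFraction > 0 && length(obs)) {
    hit <- obs[runif(length(obs)) < config@aneuploidFraction]
    for (i in hit) {
      nAlt <- sample.int(config@maxAlteredChromosomes, 1L)
      chroms <- sample.int(length(chromNames), nAlt)
      truth[i, chroms] <- config@copyRatios[
        sample.int(length(config@copyRatios), nAlt, replace = TRUE)]
    }
  }
  truth
}

#' Simulate a single-cell count matrix with planted aneuploidy
#'
#' Draws gamma-Poisson (negative-binomial) counts for a two-group design:
#' \code{nRef} presumed-euploid reference cells and \code{nObs} observation
#' cells of which a fraction carry whole-chromosome copy-number alterations.
#' The expected count of gene g in cell i is
#' \code{baseline(g) * libraryFactor(i) * ratio(i, chrom(g))}: per-gene
#' baseline means are log-normal, per-cell library factors are log-normal
#' with the configured CV (mean 1), and the copy ratio multiplies every gene
#' on an altered chromosome. Mitochondrial genes sit on the \code{"MT"}
#' pseudo-contig with a 10x elevated baseline (so mitochondrial content is a
#' realistic few percent) and are never altered; they exist to exercise QC.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param positions gene positions from \code{\link{makeGenePositions}}
#'   covering at least \code{config@nChromosomes} chromosomes.
#' @return A list with elements \code{counts} (a
#'   \link[SummarizedExperiment]{SummarizedExperiment} of genes x cells with
#'   assay \code{"counts"}, \code{rowData} columns \code{chromosome},
#'   \code{start}, \code{end}, \code{mito}, and \code{colData} column
#'   \code{cell_group}) and \code{karyotype} (cells x chromosomes matrix of
#'   true copy ratios; 1.0 = euploid).
#' @examples
#' cfg <- simulationConfig(nRef = 20, nObs = 20, nChromosomes = 2,
#'                         genesPerChromosome = 40, seed = 1)
#' sim <- simulateCounts(cfg, makeGenePositions(2, 40, seed = 1))
#' @export
simulateCounts <- function(config, positions) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  chromNames <- as.character(seq_len(config@nChromosomes))
  posChrom <- as.character(seqnames(positions))
  if (!all(chromNames %in% posChrom))
    stop("'positions' must cover all ", config@nChromosomes,
         " configured chromosomes")
  keep <- posChrom %in% chromNames
  positions <- positions[keep]
  posChrom <- posChrom[keep]

  withSeed(config@seed, {
    nGenes <- length(positions)
    nMito <- config@mitoGeneCount
    geneIds <- c(names(positions),
                 if (nMito > 0) paste0("mt-", seq_len(nMito)))
    geneChrom <- c(posChrom, rep("MT", nMito))
    nAll <- nGenes + nMito
    nCells <- config@nRef + config@nObs
    cellIds <- sprintf("cell%04d", seq_len(nCells))
    group <- rep(c("reference", "observation"),
                 c(config@nRef, config@nObs))

    baseline <- rlnorm(nAll, meanlog = log(config@baselineMedian),
                       sdlog = config@baselineMeanLogSd)
    if (nMito > 0) # mitochondrial transcripts are strongly expressed
      baseline[nGenes + seq_len(nMito)] <-
        baseline[nGenes + seq_len(nMito)] * 10
    sdlog <- sqrt(log(1 + config@librarySizeCv^2))
    libFactor <- rlnorm(nCells, meanlog = -sdlog^2 / 2, sdlog = sdlog)

    truth <- drawKaryotype(config, chromNames, cellIds, group)
    # ratio matrix aligned to genes: MT rows stay at 1
    chromIdx <- match(geneChrom, chromNames)
    ratio <- matrix(1, nrow = nAll, ncol = nCells)
    mapped <- !is.na(chromIdx)
    ratio[mapped, ] <- t(truth)[chromIdx[mapped], , drop = FALSE]

    mu <- (baseline * ratio) * rep(libFactor, each = nAll)
    counts <- if (config@nbDispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / config@nbDispersion)
    } else {
      rpois(length(mu), lambda = mu)
    }
    counts <- matrix(as.numeric(counts), nrow = nAll, ncol = nCells,
                     dimnames = list(geneIds, cellIds))

    rd <- S4Vectors::DataFrame(
      chromosome = geneChrom,
      start = c(start(positions), rep(NA_integer_, nMito)),
      end = c(end(positions), rep(NA_integer_, nMito)),
      mito = geneChrom == "MT", row.names = geneIds)
    se <- SummarizedExperiment(
      assays = list(counts = Matrix(counts, sparse = TRUE)),
      rowData = rd,
      colData = S4Vectors::DataFrame(cell_group = group,
                                     row.names = cellIds))
    list(counts = se, karyotype = truth)
  })
}

#' Simulate an exponential growth series
#'
#' Areas follow \code{A0 * exp(k * t)} times a multiplicative log-normal
#' noise factor with mean 1 and coefficient of variation \code{noiseCv}
#' (zero noise gives exact exponential values).
#'
#' @param A0 initial projected area (mm^2), > 0.
#' @param k exponential growth rate (per day).
#' @param days sorted, non-empty vector of measurement days.
#' @param noiseCv CV of the multiplicative noise (>= 0).
#' @param seed integer seed (ignored when \code{noiseCv == 0}).
#' @param subjectId subject label carried into the output.
#' @return A data.frame with columns \code{subject_id}, \code{day},
#'   \code{area_mm2}.
#' @examples
#' simulateGrowthSeries(4, 0.3, 4:16, noiseCv = 0.05, seed = 3)
#' @export
simulateGrowthSeries <- function(A0, k, days, noiseCv = 0, seed = 1L,
                                 subjectId = "s1") {
  if (A0 <= 0) stop("'A0' must be > 0")
  if (length(days) == 0 || is.unsorted(days))
    stop("'days' must be non-empty and sorted")
  if (noiseCv < 0) stop("'noiseCv' must be >= 0")
  area <- A0 * exp(k * days)
  if (noiseCv > 0) {
    sdlog <- sqrt(log(1 + noiseCv^2))
    area <- withSeed(seed,
      area * rlnorm(length(days), meanlog = -sdlog^2 / 2, sdlog = sdlog))
  }
  data.frame(subject_id = subjectId, day = as.numeric(days),
             area_mm2 = area)
}
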