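#' Simulation configuration for the synthetic scRNA-seq generator
#'
#' Bundles every knob of the gamma-Poisson count simulator with planted
#' whole-chromosome copy-number alterations. Defaults describe a two-group
#' droplet experiment: a presumed-euploid reference population and an
#' observation population in which a configurable fraction of cells carry
#' one or more whole-chromosome gains or losses.
#'
#' @slot nRef number of reference cells.
#' @slot nObs number of observation cells.
#' @slot nChromosomes number of autosome-like chromosomes simulated.
#' @slot genesPerChromosome genes per chromosome.
#' @slot aneuploidFraction probability in [0,1] that an observation cell
#'   carries at least one chromosome-scale copy-number alteration.
#' @slot copyRatios allowed per-chromosome copy ratios for altered
#'   chromosomes (1.5 approximates one extra copy of a diploid chromosome,
#'   0.5 a whole-chromosome loss).
#' @slot maxAlteredChromosomes maximum chromosomes altered per aneuploid cell.
#' @slot baselineMedian median per-gene baseline mean count at unit library
#'   size.
#' @slot baselineMeanLogSd log-scale SD of per-gene baseline means.
#' @slot nbDispersion gamma-Poisson overdispersion phi (variance =
#'   mu + phi mu^2); 0 gives Poisson counts.
#' @slot librarySizeCv coefficient of variation of per-cell library-size
#'   factors (log-normal, mean 1).
#' @slot mitoGeneCount number of mitochondrial genes placed on the "MT"
#'   pseudo-contig (excluded from copy-number scoring; exists to exercise QC).
#' @slot seed integer seed; identical seeds give bit-identical output.
#' @export
setClass("SimulationConfig", representation(
  nRef = "integer", nObs = "integer",
  nChromosomes = "integer", genesPerChromosome = "integer",
  aneuploidFraction = "numeric", copyRatios = "numeric",
  maxAlteredChromosomes = "integer",
  baselineMedian = "numeric", baselineMeanLogSd = "numeric",
  nbDispersion = "numeric", librarySizeCv = "numeric",
  mitoGeneCount = "integer", seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  for (nm in c("nRef", "nObs", "nChromosomes", "genesPerChromosome",
               "maxAlteredChromosomes")) {
    if (length(slot(object, nm)) != 1L || is.na(slot(object, nm)) ||
        slot(object, nm) < 1L)
      msg <- c(msg, sprintf("'%s' must be a single count >= 1", nm))
  }
  if (object@mitoGeneCount < 0L)
    msg <- c(msg, "'mitoGeneCount' must be >= 0")
  if (object@aneuploidFraction < 0 || object@aneuploidFraction > 1)
    msg <- c(msg, "'aneuploidFraction' must lie in [0, 1]")
  if (object@aneuploidFraction > 0 && length(object@copyRatios) == 0L)
    msg <- c(msg, "'copyRatios' must be non-empty when aneuploidFraction > 0")
  if (any(object@copyRatios <= 0))
    msg <- c(msg, "'copyRatios' must all be > 0")
  if (object@nbDispersion < 0) msg <- c(msg, "'nbDispersion' must be >= 0")
  if (object@librarySizeCv < 0) msg <- c(msg, "'librarySizeCv' must be >= 0")
  if (object@baselineMedian <= 0) msg <- c(msg, "'baselineMedian' must be > 0")
  if (object@baselineMeanLogSd < 0)
    msg <- c(msg, "'baselineMeanLogSd' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' @param nRef,nObs reference / observation cell counts.
#' @param nChromosomes,genesPerChromosome genome layout.
#' @param aneuploidFraction fraction of observation cells carrying at least
#'   one whole-chromosome copy-number alteration.
#' @param copyRatios allowed copy ratios for altered chromosomes.
#' @param maxAlteredChromosomes maximum altered chromosomes per aneuploid cell.
#' @param baselineMedian median per-gene baseline mean count.
#' @param baselineMeanLogSd log-scale SD of baseline gene means.
#' @param nbDispersion negative-binomial overdispersion (0 = Poisson).
#' @param librarySizeCv CV of per-cell depth factors.
#' @param mitoGeneCount number of mitochondrial genes.
#' @param seed integer seed.
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nRef = 20, nObs = 40, nChromosomes = 3,
#'                         genesPerChromosome = 30, seed = 1)
#' @export
simulationConfig <- function(nRef = 200L, nObs = 400L, nChromosomes = 8L,
                             genesPerChromosome = 250L,
                             aneuploidFraction = 0.1,
                             copyRatios = c(0.5, 1.5),
                             maxAlteredChromosomes = 2L,
                             baselineMedian = 3, baselineMeanLogSd = 1,
                             nbDispersion = 0.1, librarySizeCv = 0.3,
                             mitoGeneCount = 13L, seed = 1L) {
  new("SimulationConfig",
      nRef = as.integer(nRef), nObs = as.integer(nObs),
      nChromosomes = as.integer(nChromosomes),
      genesPerChromosome = as.integer(genesPerChromosome),
      aneuploidFraction = as.numeric(aneuploidFraction),
      copyRatios = as.numeric(copyRatios),
      maxAlteredChromosomes = as.integer(maxAlteredChromosomes),
      baselineMedian = as.numeric(baselineMedian),
      baselineMeanLogSd = as.numeric(baselineMeanLogSd),
      nbDispersion = as.numeric(nbDispersion),
      librarySizeCv = as.numeric(librarySizeCv),
      mitoGeneCount = as.integer(mitoGeneCount), seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nRef, "reference +", object@nObs,
      "observation cells;", object@nChromosomes, "chromosomes x",
      object@genesPerChromosome, "genes (+", object@mitoGeneCount,
      "MT genes)\n")
  cat("  aneuploid fraction", object@aneuploidFraction, "| copy ratios {",
      paste(object@copyRatios, collapse = ", "), "} | seed", object@seed, "\n")
})

#' Smoothed relative copy-number profile
#'
#' A \linkS4class{SummarizedExperiment} of segments (rows, one per retained
#' gene after genomic smoothing) by cells (columns) holding the assay
#' \code{"cnv"}: reference-centered, genome-smoothed relative copy signal on
#' the centered log scale (0 = euploid baseline of the reference group).
#' \code{rowData} carries the per-segment \code{chromosome} and \code{start};
#' \code{colData} carries the per-cell \code{cell_group} label
#' (\code{"reference"} or \code{"observation"}).
#'
#' @export
setClass("CopyNumberProfile", contains = "SummarizedExperiment")

setValidity("CopyNumberProfile", function(object) {
  msg <- character()
  if (!"cnv" %in% assayNames(object))
    msg <- c(msg, "assay 'cnv' is required")
  if (is.null(rowData(object)$chromosome))
    msg <- c(msg, "rowData must contain 'chromosome'")
  if (is.null(colData(object)$cell_group))
    msg <- c(msg, "colData must contain 'cell_group'")
  else if (!all(colData(object)$cell_group %in% c("reference", "observation")))
    msg <- c(msg, "cell_group must be 'reference' or 'observation'")
  if ("cnv" %in% assayNames(object)) {
    if (any(!is.finite(assay(object, "cnv"))))
      msg <- c(msg, "'cnv' values must be finite")
  }
  chrom <- as.character(rowData(object)$chromosome)
  if (length(chrom)) {
    # contiguity: each chromosome label occupies one consecutive block
    if (anyDuplicated(rle(chrom)$values))
      msg <- c(msg, "segments must be grouped contiguously by chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CopyNumberProfile
#'
#' @param values segments x cells numeric matrix of relative copy signal
#'   (centered log scale).
#' @param chromosome per-segment chromosome label (contiguous blocks).
#' @param cellGroup per-cell group label, \code{"reference"} or
#'   \code{"observation"}.
#' @param start optional per-segment genomic start coordinate.
#' @return A \linkS4class{CopyNumberProfile}.
#' @export
CopyNumberProfile <- function(values, chromosome, cellGroup, start = NULL) {
  values <- as.matrix(values)
  rd <- S4Vectors::DataFrame(chromosome = as.character(chromosome))
  if (!is.null(start)) rd$start <- as.integer(start)
  se <- SummarizedExperiment(
    assays = list(cnv = values), rowData = rd,
    colData = S4Vectors::DataFrame(cell_group = as.character(cellGroup)))
  new("CopyNumberProfile", se)
}

setMethod("show", "CopyNumberProfile", function(object) {
  grp <- table(colData(object)$cell_group)
  cat("CopyNumberProfile:", nrow(object), "segments x", ncol(object),
      "cells on", length(unique(rowData(object)$chromosome)),
      "chromosomes\n")
  cat("  cells:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "),
      "\n")
})

#' Per-cell, per-chromosome summed-deviation table
#'
#' Holds the summed deviation statistic D (cells x chromosomes), the
#' per-chromosome distribution peak (kernel-density mode) and standard
#' deviation, and the resulting outlier flags: a cell is an outlier on a
#' chromosome when |D - peak| exceeds \code{multiplier} times the SD.
#'
#' @slot D cells x chromosomes matrix of summed deviations.
#' @slot peak named per-chromosome peak (mode) of the D distribution.
#' @slot sd named per-chromosome standard deviation of D.
#' @slot outlier cells x chromosomes logical matrix of outlier flags.
#' @slot cellGroup per-cell group labels.
#' @slot multiplier SD multiplier used for flagging.
#' @export
setClass("DeviationTable", representation(
  D = "matrix", peak = "numeric", sd = "numeric", outlier = "matrix",
  cellGroup = "character", multiplier = "numeric"))

setValidity("DeviationTable", function(object) {
  msg <- character()
  if (!identical(dim(object@D), dim(object@outlier)))
    msg <- c(msg, "D and outlier must have identical dimensions")
  if (length(object@peak) != ncol(object@D) ||
      length(object@sd) != ncol(object@D))
    msg <- c(msg, "peak and sd must have one entry per chromosome")
  if (length(object@cellGroup) != nrow(object@D))
    msg <- c(msg, "cellGroup must have one entry per cell")
  if (any(object@sd < 0)) msg <- c(msg, "sd must be >= 0")
  zero <- which(object@sd == 0)
  if (length(zero) && any(object@outlier[, zero]))
    msg <- c(msg, "chromosomes with zero SD cannot have outliers")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DeviationTable", function(object) {
  cat("DeviationTable:", nrow(object@D), "cells x", ncol(object@D),
      "chromosomes (multiplier", object@multiplier, ")\n")
  cat("  outlier flags:", sum(object@outlier), "of", length(object@outlier),
      "\n")
})

#' Per-cell aneuploidy calls
#'
#' A cell is called aneuploid when it is an outlier on at least one
#' chromosome. The aneuploid fraction is reported for one cell group.
#'
#' @slot aneuploid named per-cell logical.
#' @slot flaggedChromosomes per-cell list of flagged chromosome labels.
#' @slot group group over which the fraction is computed.
#' @slot aneuploidFraction fraction of aneuploid cells in that group.
#' @slot nCells number of cells in that group.
#' @export
setClass("AneuploidyCall", representation(
  aneuploid = "logical", flaggedChromosomes = "list", group = "character",
  aneuploidFraction = "numeric", nCells = "integer"))

setValidity("AneuploidyCall", function(object) {
  msg <- character()
  if (object@aneuploidFraction < 0 || object@aneuploidFraction > 1)
    msg <- c(msg, "aneuploidFraction must lie in [0, 1]")
  if (length(object@flaggedChromosomes) != length(object@aneuploid))
    msg <- c(msg, "flaggedChromosomes must match aneuploid in length")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AneuploidyCall", function(object) {
  cat("AneuploidyCall:", sum(object@aneuploid), "of",
      length(object@aneuploid), "cells aneuploid overall\n")
  cat(sprintf("  %s group: fraction %.3f over %d cells\n", object@group,
              object@aneuploidFraction, object@nCells))
})

#' Exponential growth-curve fit
#'
#' Nonlinear least-squares fit of projected area versus time to
#' A0 * exp(k t) (tumor) or A1 * exp(k (t - 1)) (tumoroid).
#'
#' @slot prefactor fitted prefactor (A0 or A1), mm^2.
#' @slot rate fitted exponential growth rate k, per day.
#' @slot rss residual sum of squares, mm^4.
#' @slot model "tumor" or "tumoroid".
#' @slot converged logical convergence status.
#' @slot nPoints number of positive-area points used.
#' @export
setClass("ExponentialFit", representation(
  prefactor = "numeric", rate = "numeric", rss = "numeric",
  model = "character", converged = "logical", nPoints = "integer"))

setValidity("ExponentialFit", function(object) {
  msg <- character()
  if (!object@model %in% c("tumor", "tumoroid"))
    msg <- c(msg, "model must be 'tumor' or 'tumoroid'")
  if (object@rss < 0) msg <- c(msg, "rss must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ExponentialFit", function(object) {
  cat(sprintf("ExponentialFit (%s): prefactor %.4g mm^2, k %.4g /day, RSS %.4g (%s, %d points)\n",
              object@model, object@prefactor, object@rate, object@rss,
              if (object@converged) "converged" else "NOT converged",
              object@nPoints))
})
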