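#' Order genes genomically and drop sparse or unpositioned genes
#'
#' Restricts the matrix to genes present in the position table that are
#' expressed (count > 0) in at least \code{minCellsExpressing} cells, and
#' sorts them by (chromosome, start). Chromosomes are ordered numerically
#' where their labels are numeric, otherwise lexicographically; the
#' mitochondrial pseudo-contig is never in the position table and so drops
#' out here, which is what excludes it from copy-number scoring.
#'
#' @param norm a \link[SummarizedExperiment]{SummarizedExperiment} carrying
#'   \code{"counts"} and \code{"logcounts"} assays.
#' @param positions a named \link[GenomicRanges]{GRanges} of gene positions.
#' @param minCellsExpressing minimum number of cells expressing a gene.
#' @return The input restricted to retained genes in genomic order, with
#'   \code{rowData} columns \code{chromosome}, \code{start}, \code{end}
#'   rewritten from \code{positions}.
#' @export
orderGenes <- function(norm, positions, minCellsExpressing = 3) {
  hit <- match(rownames(norm), names(positions))
  expressed <- Matrix::rowSums(assay(norm, "counts") > 0)
  keep <- !is.na(hit) & expressed >= minCellsExpressing
  if (!any(keep))
    stop("no genes remain after position matching and expression filtering")
  out <- norm[keep, ]
  pos <- positions[hit[keep]]
  chrom <- as.character(seqnames(pos))
  lev <- unique(chrom)
  num <- suppressWarnings(as.numeric(lev))
  lev <- if (anyNA(num)) sort(lev) else lev[order(num)]
  ord <- order(match(chrom, lev), start(pos))
  out <- out[ord, ]
  rowData(out)$chromosome <- chrom[ord]
  rowData(out)$start <- start(pos)[ord]
  rowData(out)$end <- end(pos)[ord]
  out
}

#' Center expression on the reference cells
#'
#' Subtracts, for each gene, its mean log-normalized expression over the
#' reference cells, so the presumed-euploid reference defines the zero
#' baseline of the copy-number signal. Idempotent; reference per-gene means
#' are exactly zero afterwards.
#'
#' @param norm a \link[SummarizedExperiment]{SummarizedExperiment} with a
#'   \code{"logcounts"} assay and \code{cell_group} labels including at
#'   least two \code{"reference"} cells.
#' @return The input with a \code{"centered"} assay added (or replaced).
#' @export
centerOnReference <- function(norm) {
  grp <- cellGroups(norm)
  ref <- grp == "reference"
  if (sum(ref) < 2) stop("at least 2 reference cells are required")
  x <- assay(norm, "logcounts")
  refMean <- rowMeans(x[, ref, drop = FALSE])
  assay(norm, "centered") <- x - refMean
  norm
}

# Truncated boxcar moving average along rows within one chromosome block:
# smoothed[j] = mean(x[max(1, j-h) .. min(n, j+h)]), h = (window - 1) / 2.
runningMean <- function(x, window) {
  n <- nrow(x)
  if (window >= 2 * n - 1) {
    return(matrix(rep(colMeans(x), each = n), nrow = n,
                  dimnames = dimnames(x)))
  }
  h <- (window - 1) / 2
  cs <- apply(x, 2, cumsum)
  if (n == 1) cs <- matrix(cs, nrow = 1)
  hi <- pmin(n, seq_len(n) + h)
  lo <- pmax(1, seq_len(n) - h)
  num <- cs[hi, , drop = FALSE] -
    rbind(0, cs)[lo, , drop = FALSE]
  num / (hi - lo + 1)
}

#' Smooth centered expression along the genome
#'
#' Applies, per cell and per chromosome, a uniform (boxcar) moving average of
#' \code{window} genes centered on each gene, truncated at chromosome
#' boundaries (the window never crosses chromosomes; at the ends it shrinks
#' to the available genes). Output has one segment per retained gene.
#'
#' @param centered a \link[SummarizedExperiment]{SummarizedExperiment} with a
#'   \code{"centered"} assay and genes in genomic order (rowData
#'   \code{chromosome} in contiguous blocks).
#' @param window odd window size in genes (default 101).
#' @return A \linkS4class{CopyNumberProfile} of segments x cells.
#' @export
smoothGenomic <- function(centered, window = 101) {
  if (window < 1 || window %% 2 == 0)
    stop("'window' must be a positive odd integer")
  chrom <- as.character(rowData(centered)$chromosome)
  if (is.null(chrom) || anyNA(chrom))
    stop("rowData(centered)$chromosome is required")
  x <- assay(centered, "centered")
  out <- x
  for (blk in split(seq_along(chrom), factor(chrom, unique(chrom)))) {
    out[blk, ] <- runningMean(x[blk, , drop = FALSE], window)
  }
  CopyNumberProfile(out, chromosome = chrom,
                    cellGroup = cellGroups(centered),
                    start = rowData(centered)$start)
}

#' Denoise a copy-number profile against reference variability
#'
#' For each segment, observation values lying within \code{sdMultiplier}
#' reference standard deviations of the zero baseline are set to zero;
#' values outside the band, and all reference cells, pass through unchanged.
#' This suppresses reference-level noise so that only chromosome-scale
#' departures contribute to the deviation statistic.
#'
#' @param profile a \linkS4class{CopyNumberProfile} with at least two
#'   reference cells.
#' @param sdMultiplier half-width of the zeroed band in reference SD units.
#' @return The denoised \linkS4class{CopyNumberProfile}.
#' @export
denoiseProfile <- function(profile, sdMultiplier = 1.5) {
  grp <- cellGroups(profile)
  ref <- grp == "reference"
  if (sum(ref) < 2) stop("at least 2 reference cells are required")
  x <- assay(profile, "cnv")
  sdRef <- apply(x[, ref, drop = FALSE], 1, sd)
  obs <- which(!ref)
  if (length(obs)) {
    band <- sdMultiplier * sdRef
    xo <- x[, obs, drop = FALSE]
    xo[abs(xo) <= band] <- 0
    x[, obs] <- xo
  }
  assay(profile, "cnv") <- x
  profile
}

#' Build a copy-number profile from normalized counts
#'
#' Convenience pipeline for profile construction: order genes genomically,
#' center on the reference cells, clip extreme centered values to
#' \code{[-clip, clip]} (dynamic-range bounding that stabilizes the
#' deviation statistic), smooth along the genome, re-center each segment on
#' the reference so the reference baseline is exactly zero, and optionally
#' denoise.
#'
#' @param norm output of \code{\link{logNormalize}}.
#' @param positions gene positions (\link[GenomicRanges]{GRanges}).
#' @param window smoothing window in genes.
#' @param clip clipping bound on centered values (\code{Inf} disables).
#' @param minCellsExpressing gene expression filter.
#' @param centerCells subtract each cell's median smoothed value before the
#'   final reference re-centering. This removes whole-profile shifts caused
#'   by per-cell depth differences (which the log-normalization cannot fully
#'   undo because of zero inflation) while leaving chromosome-scale events
#'   intact, since the median across segments is robust to a minority of
#'   altered chromosomes.
#' @param denoiseSd SD multiplier for \code{\link{denoiseProfile}};
#'   \code{NULL} skips denoising.
#' @return A \linkS4class{CopyNumberProfile}.
#' @export
inferCopyNumber <- function(norm, positions, window = 101, clip = 3,
                            minCellsExpressing = 3, centerCells = FALSE,
                            denoiseSd = 1.5) {
  ordered <- orderGenes(norm, positions, minCellsExpressing)
  centered <- centerOnReference(ordered)
  if (is.finite(clip)) {
    x <- assay(centered, "centered")
    assay(centered, "centered") <- pmin(pmax(x, -clip), clip)
  }
  profile <- smoothGenomic(centered, window)
  x <- assay(profile, "cnv")
  if (centerCells)
    x <- x - rep(apply(x, 2, median), each = nrow(x))
  # re-center so each segment's reference mean is exactly zero even after
  # clipping and cell centering (smoothing alone preserves a zero mean)
  ref <- cellGroups(profile) == "reference"
  x <- x - rowMeans(x[, ref, drop = FALSE])
  assay(profile, "cnv") <- x
  if (!is.null(denoiseSd)) profile <- denoiseProfile(profile, denoiseSd)
  profile
}
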