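#' Per-segment deviation from the overall mean
#'
#' Subtracts, at each segment, the mean copy-number signal over cells from
#' every cell's value. By default the mean is taken over all cells in the
#' profile (reference and observation); \code{meanOver = "observation"}
#' restricts it to observation cells, for datasets where the reference
#' should not influence the consensus.
#'
#' @param profile a \linkS4class{CopyNumberProfile} with at least two cells.
#' @param meanOver cells over which the per-segment mean is computed.
#' @return A cells x segments numeric matrix of deviations; with
#'   \code{meanOver = "all"} its column means are zero to machine precision.
#' @export
segmentDeviation <- function(profile, meanOver = c("all", "observation")) {
  meanOver <- match.arg(meanOver)
  if (ncol(profile) < 2)
    stop("at least 2 cells are required to define the overall mean")
  x <- Matrix::t(assay(profile, "cnv"))   # cells x segments
  x <- as.matrix(x)
  sel <- if (meanOver == "all") rep(TRUE, nrow(x))
         else cellGroups(profile) == "observation"
  if (!any(sel)) stop("no cells in the requested meanOver group")
  x - rep(colMeans(x[sel, , drop = FALSE]), each = nrow(x))
}

#' Sum deviations across each chromosome
#'
#' Computes the summed-deviation statistic
#' \code{D(i, c) = sum over segments s on chromosome c of dev(i, s)}
#' (signed sum: a whole-chromosome event deviates with uniform sign, so
#' signed summation preserves gain/loss direction).
#'
#' @param dev cells x segments deviation matrix from
#'   \code{\link{segmentDeviation}}.
#' @param segmentChromosome per-segment chromosome labels (no NAs).
#' @return A cells x chromosomes matrix D, chromosome columns in first-seen
#'   segment order.
#' @export
chromosomeDeviationSum <- function(dev, segmentChromosome) {
  segmentChromosome <- as.character(segmentChromosome)
  if (length(segmentChromosome) != ncol(dev))
    stop("one chromosome label per segment is required")
  if (anyNA(segmentChromosome)) {
    bad <- which(is.na(segmentChromosome))
    stop("segment(s) without a chromosome label: ",
         paste(head(bad, 5), collapse = ", "))
  }
  f <- factor(segmentChromosome, levels = unique(segmentChromosome))
  D <- t(rowsum(t(dev), f))
  colnames(D) <- levels(f)
  D
}

#' Estimate the peak (mode) of a distribution
#'
#' Returns the argmax over a 512-point grid spanning [min, max] of a
#' Gaussian kernel density estimate with Silverman's rule-of-thumb
#' bandwidth. With fewer than 10 values, or when all values are equal (so
#' no bandwidth is defined), the median is returned instead.
#'
#' @param values numeric vector, non-empty and finite.
#' @return The estimated mode (a single number).
#' @export
findPeak <- function(values) {
  if (length(values) == 0) stop("'values' must be non-empty")
  if (any(!is.finite(values))) stop("'values' must be finite")
  if (length(values) < 10 || diff(range(values)) == 0)
    return(median(values))
  bw <- stats::bw.nrd0(values)
  if (!is.finite(bw) || bw <= 0) return(median(values))
  d <- density(values, bw = bw, n = 512, from = min(values),
               to = max(values))
  d$x[which.max(d$y)]
}

#' Flag outlier cells on one chromosome
#'
#' A cell is flagged when its absolute deviation from the distribution peak
#' exceeds \code{multiplier} times the sample standard deviation (denominator
#' n - 1) of the column: \code{|D(i) - peak| > multiplier * s}, strict
#' inequality. A zero-variance column yields no flags.
#'
#' @param dColumn per-cell summed deviations for one chromosome (length >= 2).
#' @param peak distribution peak, typically from \code{\link{findPeak}}.
#' @param multiplier SD multiplier (default 2.5).
#' @param sdMethod \code{"sample"} for the ordinary sample SD or \code{"mad"}
#'   for the normal-consistent median absolute deviation.
#' @return Logical vector of flags.
#' @export
callOutliers <- function(dColumn, peak, multiplier = 2.5,
                         sdMethod = c("sample", "mad")) {
  sdMethod <- match.arg(sdMethod)
  if (length(dColumn) < 2) stop("'dColumn' must have length >= 2")
  if (any(!is.finite(dColumn)) || !is.finite(peak))
    stop("'dColumn' and 'peak' must be finite")
  s <- if (sdMethod == "sample") sd(dColumn) else mad(dColumn)
  if (s == 0) return(rep(FALSE, length(dColumn)))
  abs(dColumn - peak) > multiplier * s
}

#' Build the deviation table for a profile
#'
#' Runs \code{\link{segmentDeviation}}, \code{\link{chromosomeDeviationSum}},
#' \code{\link{findPeak}} and the strict \code{multiplier}-SD outlier rule
#' per chromosome. The peak is estimated from all cells' D. The SD that
#' scales the outlier threshold is, by default, taken over the reference
#' cells only: the presumed-euploid reference defines the null spread of D,
#' whereas a pooled SD is deflated by denoised observation cells and
#' inflated by genuine aneuploid cells (masking). \code{sdOver = "all"}
#' reproduces the pooled behavior, which \code{\link{callOutliers}}
#' implements for a single column.
#'
#' @inheritParams segmentDeviation
#' @inheritParams callOutliers
#' @param sdOver cells whose D defines the per-chromosome SD:
#'   \code{"reference"} (default) or \code{"all"}.
#' @return A \linkS4class{DeviationTable}.
#' @export
deviationTable <- function(profile, multiplier = 2.5,
                           meanOver = c("all", "observation"),
                           sdMethod = c("sample", "mad"),
                           sdOver = c("reference", "all")) {
  meanOver <- match.arg(meanOver)
  sdMethod <- match.arg(sdMethod)
  sdOver <- match.arg(sdOver)
  dev <- segmentDeviation(profile, meanOver)
  D <- chromosomeDeviationSum(dev, segmentChromosomes(profile))
  peak <- apply(D, 2, findPeak)
  sel <- if (sdOver == "reference") cellGroups(profile) == "reference"
         else rep(TRUE, nrow(D))
  if (sum(sel) < 2)
    stop("sdOver = 'reference' requires >= 2 reference cells; ",
         "use sdOver = 'all' for profiles without a reference group")
  est <- if (sdMethod == "sample") sd else mad
  s <- apply(D[sel, , drop = FALSE], 2, est)
  outlier <- abs(D - rep(peak, each = nrow(D))) >
    rep(multiplier * s, each = nrow(D))
  outlier[, s == 0] <- FALSE
  dimnames(outlier) <- dimnames(D)
  new("DeviationTable", D = D, peak = peak, sd = s, outlier = outlier,
      cellGroup = cellGroups(profile), multiplier = multiplier)
}

#' Call aneuploid cells and the group aneuploid fraction
#'
#' A cell is aneuploid when it is flagged as an outlier on at least one
#' chromosome. The aneuploid fraction is the share of aneuploid cells in
#' the requested group.
#'
#' @param table a \linkS4class{DeviationTable}.
#' @param group group over which the fraction is computed.
#' @return An \linkS4class{AneuploidyCall}.
#' @export
aneuploidCall <- function(table, group = c("observation", "reference")) {
  group <- match.arg(group)
  inGroup <- table@cellGroup == group
  if (!any(inGroup)) stop("no cells in group '", group, "'")
  aneu <- rowSums(table@outlier) >= 1
  names(aneu) <- rownames(table@D)
  flagged <- apply(table@outlier, 1, function(r)
    colnames(table@outlier)[r], simplify = FALSE)
  new("AneuploidyCall", aneuploid = aneu, flaggedChromosomes = flagged,
      group = group,
      aneuploidFraction = mean(aneu[inGroup]),
      nCells = sum(inGroup))
}

#' Score a copy-number profile for aneuploidy
#'
#' End-to-end scoring: per-segment deviation from the overall mean, signed
#' summation across each chromosome, kernel-density peak and SD per
#' chromosome, outlier flagging at \code{multiplier} SDs from the peak, and
#' aggregation to per-cell aneuploidy calls and the group fraction.
#'
#' @inheritParams deviationTable
#' @inheritParams aneuploidCall
#' @return A list with elements \code{table} (\linkS4class{DeviationTable})
#'   and \code{call} (\linkS4class{AneuploidyCall}).
#' @seealso \code{\link{deviationTable}} for the choice of SD population.
#' @examples
#' prof <- CopyNumberProfile(matrix(rnorm(60), nrow = 6),
#'                           chromosome = rep(c("1", "2"), each = 3),
#'                           cellGroup = rep(c("reference", "observation"),
#'                                           each = 5))
#' res <- scoreAneuploidy(prof)
#' aneuploidFraction(res$call)
#' @export
scoreAneuploidy <- function(profile, multiplier = 2.5,
                            meanOver = c("all", "observation"),
                            sdMethod = c("sample", "mad"),
                            sdOver = c("reference", "all"),
                            group = c("observation", "reference")) {
  tab <- deviationTable(profile, multiplier, meanOver, sdMethod, sdOver)
  list(table = tab, call = aneuploidCall(tab, group))
}
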