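#' Quality-filter cells
#'
#' Retains cells that express at least \code{minGenes} genes (count > 0) and
#' whose mitochondrial fraction of total counts is strictly below
#' \code{maxMitoFrac}. Both statistics are computed on raw counts; the gene
#' set and the order of surviving cells are unchanged. Defaults follow the
#' common droplet QC of keeping cells with a minimum of 1,400 detected genes
#' and less than 15 percent mitochondrial content.
#'
#' @param counts a \link[SummarizedExperiment]{SummarizedExperiment} with a
#'   \code{"counts"} assay and a logical \code{rowData} column \code{mito}.
#' @param minGenes minimum number of detected genes (inclusive).
#' @param maxMitoFrac maximum mitochondrial fraction (exclusive).
#' @return The input restricted to surviving cells, with \code{colData}
#'   columns \code{n_genes} and \code{mito_frac} added.
#' @export
qcFilter <- function(counts, minGenes = 1400, maxMitoFrac = 0.15) {
  mito <- rowData(counts)$mito
  if (is.null(mito) || anyNA(mito))
    stop("rowData(counts)$mito must be a complete logical flag")
  m <- assay(counts, "counts")
  nGenes <- Matrix::colSums(m > 0)
  total <- Matrix::colSums(m)
  mitoCounts <- Matrix::colSums(m[mito, , drop = FALSE])
  mitoFrac <- ifelse(total > 0, mitoCounts / total, 1)
  keep <- nGenes >= minGenes & mitoFrac < maxMitoFrac
  if (!any(keep))
    stop("qcFilter removed all cells (minGenes = ", minGenes,
         ", maxMitoFrac = ", maxMitoFrac, ")")
  out <- counts[, keep]
  colData(out)$n_genes <- as.integer(nGenes[keep])
  colData(out)$mito_frac <- as.numeric(mitoFrac[keep])
  out
}

#' Log-normalize counts
#'
#' Per-cell depth normalization to a fixed scale followed by log1p:
#' \code{value(g, i) = ln(1 + count(g, i) / total(i) * scale)}, the standard
#' log-normalization used for droplet scRNA-seq.
#'
#' @param counts a \link[SummarizedExperiment]{SummarizedExperiment} with a
#'   \code{"counts"} assay; every cell must have total count > 0.
#' @param scale normalization scale factor (default 10,000).
#' @return The input with a dense \code{"logcounts"} assay added.
#' @export
logNormalize <- function(counts, scale = 1e4) {
  m <- assay(counts, "counts")
  total <- Matrix::colSums(m)
  if (any(total == 0)) {
    bad <- colnames(m)[total == 0]
    stop("cell(s) with zero total count cannot be normalized: ",
         paste(head(bad, 5), collapse = ", "))
  }
  norm <- as.matrix(m)
  norm <- log1p(norm * rep(scale / total, each = nrow(norm)))
  dimnames(norm) <- dimnames(m)
  assay(counts, "logcounts") <- norm
  counts
}
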