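# Plain-text readers and writers: 10x-style Matrix Market triplet for
# counts, TSVs for positions, labels, karyotype truth, profiles and calls.
# All writers are deterministic: rerunning with the same inputs produces
# byte-identical files.

tsvWrite <- function(df, path, colNames = TRUE) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = colNames, eol = "\n")
}

#' Write a simulated dataset as a 10x-style triplet
#'
#' Writes \code{matrix.mtx} (Matrix Market, genes as rows),
#' \code{features.tsv} (gene_id, gene_name, mito flag),
#' \code{barcodes.tsv}, \code{labels.tsv} (barcode, group),
#' \code{positions.tsv} (gene_id, chromosome, start, end) and, when
#' karyotype truth is supplied, \code{karyotype.tsv}.
#'
#' @param counts a \link[SummarizedExperiment]{SummarizedExperiment} with a
#'   \code{"counts"} assay (as from \code{\link{simulateCounts}}).
#' @param dir output directory (created if missing).
#' @param karyotype optional cells x chromosomes truth matrix.
#' @return \code{dir}, invisibly.
#' @export
writeCountsTriplet <- function(counts, dir, karyotype = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- assay(counts, "counts")
  Matrix::writeMM(as(as(m, "CsparseMatrix"), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  rd <- rowData(counts)
  tsvWrite(data.frame(gene_id = rownames(counts),
                      gene_name = rownames(counts),
                      mito = as.logical(rd$mito)),
           file.path(dir, "features.tsv"), colNames = FALSE)
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  tsvWrite(data.frame(barcode = colnames(counts),
                      group = cellGroups(counts)),
           file.path(dir, "labels.tsv"))
  pos <- data.frame(gene_id = rownames(counts),
                    chromosome = as.character(rd$chromosome),
                    start = rd$start, end = rd$end)
  tsvWrite(pos[!is.na(pos$start), ], file.path(dir, "positions.tsv"))
  if (!is.null(karyotype)) {
    tsvWrite(data.frame(cell = rownames(karyotype),
                        as.data.frame(karyotype), check.names = FALSE),
             file.path(dir, "karyotype.tsv"))
  }
  invisible(dir)
}

#' Read a 10x-style triplet written by \code{\link{writeCountsTriplet}}
#'
#' @param dir directory holding \code{matrix.mtx}, \code{features.tsv},
#'   \code{barcodes.tsv}, \code{labels.tsv} and optionally
#'   \code{positions.tsv}.
#' @return A \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{"counts"}, \code{rowData} (mito flag plus positions when present)
#'   and \code{colData} \code{cell_group}.
#' @export
readCountsTriplet <- function(dir) {
  m <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  feat <- read.table(file.path(dir, "features.tsv"), sep = "\t",
                     header = FALSE,
                     col.names = c("gene_id", "gene_name", "mito"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  labels <- read.table(file.path(dir, "labels.tsv"), sep = "\t",
                       header = TRUE)
  dimnames(m) <- list(feat$gene_id, barcodes)
  rd <- S4Vectors::DataFrame(mito = as.logical(feat$mito),
                             row.names = feat$gene_id)
  posFile <- file.path(dir, "positions.tsv")
  if (file.exists(posFile)) {
    pos <- read.table(posFile, sep = "\t", header = TRUE,
                      colClasses = c("character", "character", "integer",
                                     "integer"))
    idx <- match(feat$gene_id, pos$gene_id)
    rd$chromosome <- pos$chromosome[idx]
    rd$start <- pos$start[idx]
    rd$end <- pos$end[idx]
  }
  grp <- labels$group[match(barcodes, labels$barcode)]
  SummarizedExperiment(assays = list(counts = m), rowData = rd,
                       colData = S4Vectors::DataFrame(
                         cell_group = grp, row.names = barcodes))
}

#' Read a gene-position table
#'
#' Four-column TSV (gene_id, chromosome, start, end; 1-based inclusive)
#' into a named \link[GenomicRanges]{GRanges}.
#'
#' @param path TSV path.
#' @param header does the file carry a header line?
#' @return A named \link[GenomicRanges]{GRanges}.
#' @export
readGenePositions <- function(path, header = TRUE) {
  df <- read.table(path, sep = "\t", header = header,
                   col.names = c("gene_id", "chromosome", "start", "end"))
  gr <- GRanges(df$chromosome, IRanges(df$start, df$end))
  names(gr) <- df$gene_id
  gr
}

#' Write a copy-number profile and its segment map
#'
#' \code{profile.tsv} holds the dense cells x segments matrix (mirroring the
#' role of a denoised observations table); \code{segments.tsv} maps each
#' segment to its chromosome and start coordinate.
#'
#' @param profile a \linkS4class{CopyNumberProfile}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeProfile <- function(profile, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vals <- t(as.matrix(assay(profile, "cnv")))  # cells x segments
  tsvWrite(data.frame(cell = rownames(vals), group = cellGroups(profile),
                      as.data.frame(vals, check.names = FALSE)),
           file.path(dir, "profile.tsv"))
  rd <- rowData(profile)
  tsvWrite(data.frame(segment = rownames(profile),
                      chromosome = as.character(rd$chromosome),
                      start = if (is.null(rd$start)) NA_integer_
                              else rd$start),
           file.path(dir, "segments.tsv"))
  invisible(dir)
}

#' Write aneuploidy-scoring outputs
#'
#' Writes \code{calls.tsv} (cell, group, aneuploid, flagged_chromosomes),
#' \code{deviations.tsv} (cell x chromosome D) and \code{summary.tsv}
#' (group, n_cells, aneuploid_fraction, plus per-chromosome flag rates).
#'
#' @param table a \linkS4class{DeviationTable}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeCalls <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aneu <- rowSums(table@outlier) >= 1
  flagged <- apply(table@outlier, 1, function(r)
    paste(colnames(table@outlier)[r], collapse = ","))
  tsvWrite(data.frame(cell = rownames(table@D), group = table@cellGroup,
                      aneuploid = aneu, flagged_chromosomes = flagged),
           file.path(dir, "calls.tsv"))
  tsvWrite(data.frame(cell = rownames(table@D),
                      as.data.frame(table@D, check.names = FALSE)),
           file.path(dir, "deviations.tsv"))
  groups <- unique(table@cellGroup)
  rate <- t(vapply(groups, function(g)
    colMeans(table@outlier[table@cellGroup == g, , drop = FALSE]),
    numeric(ncol(table@outlier))))
  tsvWrite(data.frame(group = groups,
                      n_cells = as.integer(table(
                        factor(table@cellGroup, groups))),
                      aneuploid_fraction = vapply(groups, function(g)
                        mean(aneu[table@cellGroup == g]), numeric(1)),
                      rate, check.names = FALSE),
           file.path(dir, "summary.tsv"))
  invisible(dir)
}

#' Write exponential growth fits
#'
#' @param fits a list of \linkS4class{ExponentialFit} objects, named by
#'   subject.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeGrowthFits <- function(fits, path) {
  df <- data.frame(
    subject = if (is.null(names(fits))) seq_along(fits) else names(fits),
    model = vapply(fits, function(f) f@model, character(1)),
    prefactor = vapply(fits, function(f) f@prefactor, numeric(1)),
    k = vapply(fits, function(f) f@rate, numeric(1)),
    rss = vapply(fits, function(f) f@rss, numeric(1)),
    converged = vapply(fits, function(f) f@converged, logical(1)))
  tsvWrite(df, path)
  invisible(path)
}
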