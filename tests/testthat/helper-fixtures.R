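# Shared fixtures and independent oracles used across test files.

# Build a small SummarizedExperiment of counts by hand.
makeCountsSE <- function(counts, mito = rep(FALSE, nrow(counts)),
                         group = rep("observation", ncol(counts)),
                         chromosome = NULL, start = NULL) {
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("c", seq_len(ncol(counts)))
  rd <- S4Vectors::DataFrame(mito = mito, row.names = rownames(counts))
  if (!is.null(chromosome)) rd$chromosome <- chromosome
  if (!is.null(start)) rd$start <- start
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
    rowData = rd,
    colData = S4Vectors::DataFrame(cell_group = group,
                                   row.names = colnames(counts)))
}

# Build a CopyNumberProfile from a segments x cells matrix.
makeProfile <- function(values, chromosome, group) {
  CopyNumberProfile(values, chromosome = chromosome, cellGroup = group)
}

# Random profile generator for property tests.
randomProfile <- function(nCells, nChrom, segPerChrom, nRef = floor(nCells / 2)) {
  vals <- matrix(rnorm(nChrom * segPerChrom * nCells),
                 nrow = nChrom * segPerChrom)
  rownames(vals) <- paste0("s", seq_len(nrow(vals)))
  colnames(vals) <- paste0("c", seq_len(nCells))
  makeProfile(vals, rep(as.character(seq_len(nChrom)), each = segPerChrom),
              rep(c("reference", "observation"), c(nRef, nCells - nRef)))
}

# Straight-line brute-force recomputation of the whole scoring stage,
# independent of the package implementation: explicit loops, no shared code.
bruteForceScore <- function(values, chromosome, group, multiplier = 2.5,
                            sdOver = "reference") {
  nSeg <- nrow(values); nCells <- ncol(values)
  dev <- matrix(NA_real_, nCells, nSeg)
  for (s in seq_len(nSeg)) {
    m <- sum(values[s, ]) / nCells
    for (i in seq_len(nCells)) dev[i, s] <- values[s, i] - m
  }
  chroms <- unique(chromosome)
  D <- matrix(0, nCells, length(chroms), dimnames = list(NULL, chroms))
  for (ci in seq_along(chroms)) {
    for (i in seq_len(nCells)) {
      tot <- 0
      for (s in which(chromosome == chroms[ci])) tot <- tot + dev[i, s]
      D[i, ci] <- tot
    }
  }
  peak <- numeric(length(chroms)); sds <- numeric(length(chroms))
  flags <- matrix(FALSE, nCells, length(chroms), dimnames = list(NULL, chroms))
  for (ci in seq_along(chroms)) {
    v <- D[, ci]
    peak[ci] <- if (length(v) < 10 || max(v) == min(v)) median(v) else {
      d <- density(v, bw = "nrd0", n = 512, from = min(v), to = max(v))
      d$x[which.max(d$y)]
    }
    pop <- if (sdOver == "reference") v[group == "reference"] else v
    sds[ci] <- sd(pop)
    if (sds[ci] > 0)
      flags[, ci] <- abs(v - peak[ci]) > multiplier * sds[ci]
  }
  aneuploid <- rowSums(flags) >= 1
  obs <- group == "observation"
  list(D = D, peak = peak, sd = sds, flags = flags,
       fraction = sum(aneuploid[obs]) / sum(obs))
}

# Full simulation -> QC -> normalization -> profile -> scoring pipeline used
# by the recovery, calibration and monotonicity tests.
runFullPipeline <- function(fraction, ratios, seed, nRef = 200, nObs = 400,
                            nChrom = 8, genesPerChrom = 250,
                            minGenes = 1400, mitoGenes = 13) {
  cfg <- simulationConfig(nRef = nRef, nObs = nObs, nChromosomes = nChrom,
                          genesPerChromosome = genesPerChrom,
                          aneuploidFraction = fraction, copyRatios = ratios,
                          mitoGeneCount = mitoGenes, seed = seed)
  gp <- makeGenePositions(nChrom, genesPerChrom, 1e8, seed = seed)
  sim <- simulateCounts(cfg, gp)
  qc <- qcFilter(sim$counts, minGenes = minGenes)
  norm <- logNormalize(qc)
  prof <- inferCopyNumber(norm, gp)
  res <- scoreAneuploidy(prof)
  obsCells <- colnames(qc)[cellGroups(qc) == "observation"]
  truthFraction <- mean(apply(sim$karyotype[obsCells, , drop = FALSE], 1,
                              function(r) any(r != 1)))
  obsFlagRates <- colMeans(
    outlierFlags(res$table)[cellGroups(res$table) == "observation", ,
                            drop = FALSE])
  list(called = aneuploidFraction(res$call), truth = truthFraction,
       perChromFlagRate = obsFlagRates, profile = prof, table = res$table)
}
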