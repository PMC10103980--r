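---
title: "Calling aneuploid cells from scRNA-seq copy-number profiles"
author: "scploidy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling aneuploid cells from scRNA-seq copy-number profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scploidy)
```

## The problem

Chromosomally unstable tumor cells mis-segregate whole chromosomes during
mitosis, producing aneuploid karyotypes. Single-cell RNA-seq can reveal this
without DNA sequencing: all genes on a gained chromosome are, on average,
transcribed proportionally more, and all genes on a lost chromosome less.
The signal per gene is tiny relative to droplet-sequencing noise, so it must
be aggregated along the genome and compared against a presumed-euploid
reference population.

`scploidy` implements this chain end to end: expression-derived relative
copy-number profiles, a per-chromosome summed-deviation statistic with a
2.5-SD-from-peak outlier rule that classifies individual cells as aneuploid,
a gamma-Poisson simulator with planted whole-chromosome copy-number
alterations (CNAs) that provides ground truth for validation, and the
exponential growth-curve models (projected area versus time) used to
summarize tumor and tumoroid growth.

## Copy-number profile construction

Starting from a genes x cells count matrix with cells labeled `reference`
(presumed euploid) or `observation`:

1. **QC** (`qcFilter`): keep cells with at least 1,400 detected genes and a
   mitochondrial count fraction strictly below 15%. The boundary semantics
   are literal: exactly 1,400 genes is kept, exactly 15% mito is removed.
   Mitochondrial content is computed on raw counts, before normalization.
2. **Log-normalization** (`logNormalize`):
   `value = ln(1 + count / total * 10^4)`, the standard counts-per-ten-
   thousand log transform. Natural logarithm, pseudocount 1.
3. **Genomic ordering** (`orderGenes`): genes are matched to a
   (gene, chromosome, start, end) position table, genes without positions or
   expressed in fewer than `minCellsExpressing = 3` cells are dropped, and
   the rest are sorted by (chromosome, start). Mitochondrial genes sit on an
   `"MT"` pseudo-contig absent from the position table, which excludes them
   from copy-number scoring.
4. **Reference centering** (`centerOnReference`): each gene's mean over the
   reference cells is subtracted, so zero means "expressed like a euploid
   reference cell".
5. **Clipping**: centered values are bounded to ±3 (option `clip` of
   `inferCopyNumber`) before smoothing. On the natural-log scale, |3| is a
   ~20-fold expression change — far beyond any whole-chromosome dosage
   effect — so clipping only tames outlier genes that would otherwise
   dominate a 101-gene average.
6. **Genomic smoothing** (`smoothGenomic`): a uniform (boxcar) moving
   average of `window = 101` genes, per cell and per chromosome, truncated
   at chromosome boundaries (the window shrinks near the ends and never
   crosses chromosomes). One output segment per retained gene. 101 genes is
   the default of the widely used expression-CNV tool this stage
   re-implements; pyramidal weights are a conceivable variant but the
   uniform window is the tested default.
7. **Reference re-centering**: after clipping and smoothing, each segment's
   reference mean is subtracted once more so the reference baseline is zero
   to machine precision (smoothing alone preserves a zero baseline, but
   clipping need not). An optional per-cell median centering
   (`centerCells`) is available to remove whole-profile shifts; under the
   simulator below it changed results negligibly and is off by default.
8. **Denoising** (`denoiseProfile`): per segment, observation values within
   `1.5` reference standard deviations of zero are set to exactly zero;
   values outside the band are kept unchanged, and reference cells pass
   through untouched. The band edge itself is zeroed (ties go to "noise");
   with multiplier 0 the band is degenerate and nothing changes.

Values stay on the centered log scale throughout (0 = euploid baseline).
The downstream statistic only uses differences, so any monotone affine
convention would do; fixing this one makes results deterministic and
testable.

## The aneuploidy statistic

For the profile `x(i, s)` (cell i, segment s):

* **Segment deviation**: `dev(i, s) = x(i, s) - mean_i' x(i', s)`, the
  difference from the consensus at each segment. The consensus mean is taken
  over *all* cells by default (`meanOver = "all"`); an observation-only
  variant is exposed because either reading of "overall" is defensible.
* **Chromosome summation**: `D(i, c) = sum over s on c of dev(i, s)` — a
  *signed* sum. A whole-chromosome event pushes every segment in the same
  direction, so signed summation accumulates the event but cancels
  incoherent noise; taking absolute values per segment would destroy that
  cancellation and the gain/loss direction.
* **Distribution peak**: the mode of `{D(i, c)}` across cells, estimated as
  the argmax over a 512-point grid on [min, max] of a Gaussian kernel
  density estimate with Silverman's rule-of-thumb bandwidth. The median is
  used below n = 10 values (or when all values are equal), where a KDE mode
  is meaningless. A mode rather than a mean/median is used because the bulk
  of cells is euploid and outliers should not shift the center.
* **Outlier rule**: cell i is an outlier on chromosome c when
  `|D(i, c) - peak(c)| > 2.5 * s(c)`, with strict inequality (a value
  exactly at the threshold is not flagged) and no flags when `s(c) = 0`.
* **Aggregation**: a cell is aneuploid when flagged on at least one
  chromosome; the aneuploid fraction is reported per cell group.

### Which cells set the SD scale

The one genuinely open choice is the population whose D defines `s(c)`.
`callOutliers` implements the pooled form (sample SD, denominator n − 1, of
the supplied column). For the full table, however, `deviationTable` defaults
to `sdOver = "reference"`: the SD of the *reference* cells' D. Two effects
motivate this. First, denoising shrinks most euploid observation cells' D
toward zero, so a pooled SD underestimates the null spread and flags noise
cells; second, genuine aneuploid cells inflate a pooled SD and mask one
another. With the reference cells as the null yardstick, simulated
populations with true aneuploid fractions 0, 0.10 and 0.34 are recovered
within ±0.05, while the pooled SD misses the null by ~0.10 (tested in
`test-acceptance.R`). The pooled variant remains available via
`sdOver = "all"`, and a normal-consistent MAD can replace the sample SD via
`sdMethod = "mad"`.

## The simulator

`simulateCounts` draws gamma-Poisson (negative binomial) counts with mean
`baseline(g) * libraryFactor(i) * ratio(i, chrom(g))`:

* `baseline(g)`: log-normal across genes, median `baselineMedian = 3`
  counts, log-SD `baselineMeanLogSd = 1`. With 8 x 250 genes this yields
  ~10,000 counts and ~1,500–1,700 detected genes per cell — a realistic
  droplet profile that passes the 1,400-gene QC for most cells.
* `libraryFactor(i)`: log-normal, mean 1, CV `librarySizeCv = 0.3`.
* `ratio(i, c)`: 1 for reference cells; each observation cell is aneuploid
  with probability `aneuploidFraction`, in which case 1 to
  `maxAlteredChromosomes = 2` whole chromosomes receive ratios from
  `copyRatios` (default {0.5, 1.5}, i.e. one lost or one gained copy of a
  diploid chromosome).
* `nbDispersion = 0.1`: variance `mu + 0.1 mu^2`, typical droplet
  overdispersion; 0 gives Poisson.
* 13 mitochondrial genes on the `"MT"` pseudo-contig with a 10x elevated
  baseline, giving ~5% mitochondrial content; they exist to exercise QC and
  are excluded from scoring.

Everything is a pure function of (config, seed): the same seed reproduces
counts bit for bit.

**What the simulator does not model**: doublets, batch effects, UMI-level
saturation, sub-chromosomal (arm-level) events, cell-cycle or other
structured biological variation, and expression dosage compensation
(the copy ratio multiplies expected expression exactly). Passing the
recovery tests therefore shows the statistic works when expression tracks
copy number multiplicatively under overdispersed counting noise — not that
it is robust to every artifact of real droplet data.

## Growth models

* `projectedArea(L, W) = pi/4 * L * W` — the elliptical approximation from
  two perpendicular caliper measurements (mm); W > L is rejected rather
  than silently swapped.
* `terminalBurden(area)` is TRUE at or above 125 mm², the projected area
  treated as a terminal event in survival analyses.
* `fitExponential` minimizes squared error of `A0 * exp(k t)` (tumors) or
  `A1 * exp(k (t - 1))` (tumoroids, anchored at the day-1 first
  measurement) over (prefactor, k) with Levenberg–Marquardt nonlinear least
  squares, initialized from ordinary least squares on log-areas. The
  log-linear start is exact for noiseless data, in which case it is
  returned directly. Zero-area time points (complete responders) are
  excluded — the exponential model and log initialization are undefined at
  zero — and such subjects belong in `classifyResponse` instead. Fits that
  fail to converge return the log-linear estimate flagged unconverged.
* `classifyResponse`: `complete` when terminal burden is never reached
  within the observation window (100 days by default, matching the usual
  survival-curve horizon); otherwise `partial` when survival reaches the
  reference median (13 days) plus one week; otherwise `none`.
* `simulateGrowthSeries` produces `A0 e^{k t}` times log-normal
  multiplicative noise with mean 1 and the requested CV (log-normal rather
  than `1 + N(0, cv)` so areas stay positive; at the 5% CV used in the
  tests the two are indistinguishable).

## Numerical and testing choices

* Smoothing uses cumulative sums per chromosome block — exact, O(genes),
  no FFT edge effects.
* The KDE grid spans exactly [min, max] so the mode is always attained on
  observed support; `bw.nrd0` can degenerate only for near-constant input,
  which falls back to the median.
* Determinism: all generators restore the caller's RNG state and derive
  everything from explicit seeds; writers emit plain TSV/MatrixMarket text,
  and rerunning any stage with the same seed reproduces files byte for
  byte.
* Problem sizes in the test suite: recovery and calibration use 200
  reference + 400 observation cells over 8 chromosomes x 250 genes (5 seeds
  per condition); oracle-equivalence tests use 100 random profiles of up to
  20 cells x 3 chromosomes x 12 segments checked against a straight-line
  brute-force reimplementation; growth fits are checked against a 200 x 200
  grid-search oracle. These sizes give stable statistics while keeping the
  suite fast.

## A worked example

```{r example, eval = FALSE}
cfg <- simulationConfig(aneuploidFraction = 0.34, seed = 1)
gp  <- makeGenePositions(8, 250, 1e8, seed = 1)
sim <- simulateCounts(cfg, gp)
prof <- inferCopyNumber(logNormalize(qcFilter(sim$counts)), gp)
res <- scoreAneuploidy(prof)
res$call
aneuploidFraction(res$call)
```

## Limitations

* Whole-chromosome events only; focal or arm-level CNAs spread across a
  101-gene window are diluted and largely invisible to the summed statistic.
* The reference population must be euploid; contamination of the reference
  with aneuploid cells shifts the baseline and the SD yardstick.
* The aneuploid fraction is a per-population summary; the per-chromosome
  flags give direction (sign of D) but not an integer copy-number state.
* HMM-based segment state calling, subclustering and Bayesian filtering of
  events — features of full expression-CNV suites — are out of scope.
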