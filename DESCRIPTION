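Package: scploidy
Title: Aneuploidy Calling from Single-Cell RNA-Seq Copy-Number Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls aneuploid cells from single-cell RNA-seq count matrices by
    building reference-centered, genome-smoothed relative copy-number profiles
    and scoring them with a per-chromosome summed-deviation statistic and a
    2.5-SD-from-peak outlier rule. Includes a negative-binomial simulator that
    plants whole-chromosome copy-number alterations with known karyotype truth,
    the standard droplet QC and log-normalization steps, and exponential
    tumor/tumoroid growth-curve models (projected area, nonlinear least-squares
    fits, terminal-burden and responder classification).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
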