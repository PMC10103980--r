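#' @name accessors
#' @title Accessors for scploidy objects
#' @description Slot accessors for the S4 containers: copy-number values,
#'   cell group labels, segment annotation, deviation statistics and calls.
#' @param x an object.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("cnvValues", function(x) standardGeneric("cnvValues"))
#' @rdname accessors
#' @export
setMethod("cnvValues", "CopyNumberProfile",
          function(x) assay(x, "cnv"))

#' @rdname accessors
#' @export
setGeneric("cellGroups", function(x) standardGeneric("cellGroups"))
#' @rdname accessors
#' @export
setMethod("cellGroups", "SummarizedExperiment",
          function(x) as.character(colData(x)$cell_group))
#' @rdname accessors
#' @export
setMethod("cellGroups", "DeviationTable", function(x) x@cellGroup)

#' @rdname accessors
#' @export
setGeneric("segmentChromosomes",
           function(x) standardGeneric("segmentChromosomes"))
#' @rdname accessors
#' @export
setMethod("segmentChromosomes", "CopyNumberProfile",
          function(x) as.character(rowData(x)$chromosome))

#' @rdname accessors
#' @export
setGeneric("deviations", function(x) standardGeneric("deviations"))
#' @rdname accessors
#' @export
setMethod("deviations", "DeviationTable", function(x) x@D)

#' @rdname accessors
#' @export
setGeneric("peakValues", function(x) standardGeneric("peakValues"))
#' @rdname accessors
#' @export
setMethod("peakValues", "DeviationTable", function(x) x@peak)

#' @rdname accessors
#' @export
setGeneric("sdValues", function(x) standardGeneric("sdValues"))
#' @rdname accessors
#' @export
setMethod("sdValues", "DeviationTable", function(x) x@sd)

#' @rdname accessors
#' @export
setGeneric("outlierFlags", function(x) standardGeneric("outlierFlags"))
#' @rdname accessors
#' @export
setMethod("outlierFlags", "DeviationTable", function(x) x@outlier)

#' @rdname accessors
#' @export
setGeneric("isAneuploid", function(x) standardGeneric("isAneuploid"))
#' @rdname accessors
#' @export
setMethod("isAneuploid", "AneuploidyCall", function(x) x@aneuploid)

#' @rdname accessors
#' @export
setGeneric("flaggedChromosomes",
           function(x) standardGeneric("flaggedChromosomes"))
#' @rdname accessors
#' @export
setMethod("flaggedChromosomes", "AneuploidyCall",
          function(x) x@flaggedChromosomes)

#' @rdname accessors
#' @export
setGeneric("aneuploidFraction",
           function(x) standardGeneric("aneuploidFraction"))
#' @rdname accessors
#' @export
setMethod("aneuploidFraction", "AneuploidyCall",
          function(x) x@aneuploidFraction)
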