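#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom stats median rbinom rlnorm rpois runif setNames var
#' @importFrom utils read.table write.table combn head
NULL

#' @rdname gcContent
#' @export
setGeneric("gcContent", function(x, reference, flank = 100L, ...)
    standardGeneric("gcContent"))

#' @rdname VntrCoverage-class
#' @export
setGeneric("spanningCounts", function(x) standardGeneric("spanningCounts"))

#' @rdname VntrCoverage-class
#' @export
setGeneric("reliableCounts", function(x) standardGeneric("reliableCounts"))

#' @rdname VntrCoverage-class
#' @export
setGeneric("repeatSupport", function(x) standardGeneric("repeatSupport"))

#' @rdname VntrCoverage-class
#' @export
setGeneric("totalMapped", function(x) standardGeneric("totalMapped"))

#' @rdname normalizePerMillion
#' @export
setGeneric("normalizePerMillion", function(x, totalMappedReads)
    standardGeneric("normalizePerMillion"))

#' @rdname VntrCatalog-class
#' @export
setGeneric("locusIds", function(x) standardGeneric("locusIds"))

#' @rdname VntrCatalog-class
#' @export
setGeneric("motifs", function(x) standardGeneric("motifs"))
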