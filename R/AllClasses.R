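#' VNTR catalog of tandem-repeat loci
#'
#' A \code{VntrCatalog} is a \link[GenomicRanges]{GRanges} holding one
#' tandem-repeat locus per range, with required metadata columns
#' \code{locus_id} (unique identifier), \code{motif} (consensus repeat unit,
#' A/C/G/T), \code{motif_length} (bp), \code{ref_repeat_count} (reference
#' array length divided by motif length) and \code{annotation} (one of
#' \code{exonic}, \code{intronic}, \code{utr}, \code{promoter},
#' \code{multiple}, \code{none}). Optional columns such as
#' \code{gc_content} and \code{strlike_score} are added by
#' \code{\link{gcContent}} and \code{\link{strlikeScore}}.
#'
#' Coordinates are held 1-based (GRanges convention); BED input/output
#' converts at the boundary, so a locus written as \code{chr1 1000 1100} in
#' BED occupies positions 1001-1100 internally and has array length 100 bp.
#'
#' @param ranges A \code{GRanges} (or coercible object) with at least a
#'   \code{motif} metadata column. \code{locus_id} is derived from the
#'   BED-style coordinates (\code{chrom:start-end}, 0-based start) when
#'   absent; \code{motif_length} and \code{ref_repeat_count} are recomputed
#'   from the motif and the range width.
#'
#' @return \code{VntrCatalog()} returns a \code{VntrCatalog} object.
#'   \code{locusIds()} and \code{motifs()} return character vectors.
#'
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1100),
#'                              motif = "ACGTGG")
#' cat <- VntrCatalog(gr)
#' locusIds(cat)
#' refRepeatCount(cat)
#'
#' @aliases VntrCatalog locusIds motifs refArrayLength refRepeatCount
#' @export VntrCatalog
#' @exportClass VntrCatalog
setClass("VntrCatalog", contains = "GRanges")

.ANNOTATION_LEVELS <- c("exonic", "intronic", "utr", "promoter",
                        "multiple", "none")

.validVntrCatalog <- function(object) {
    msg <- NULL
    mc <- S4Vectors::mcols(object)
    need <- c("locus_id", "motif", "motif_length", "ref_repeat_count",
              "annotation")
    miss <- setdiff(need, colnames(mc))
    if (length(miss))
        return(paste("missing metadata column(s):",
                     paste(miss, collapse = ", ")))
    if (anyDuplicated(mc$locus_id))
        msg <- c(msg, "locus_id values must be unique")
    if (length(object) && any(!grepl("^[ACGT]+$", mc$motif)))
        msg <- c(msg, "motifs must be non-empty strings over A,C,G,T")
    if (length(object) && any(mc$motif_length != nchar(mc$motif)))
        msg <- c(msg, "motif_length must equal nchar(motif)")
    if (length(object) && any(!mc$annotation %in% .ANNOTATION_LEVELS))
        msg <- c(msg, paste("annotation must be one of",
                            paste(.ANNOTATION_LEVELS, collapse = "/")))
    if (is.null(msg)) TRUE else msg
}

setValidity("VntrCatalog", .validVntrCatalog)

.bedId <- function(gr) {
    sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
            GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
}

VntrCatalog <- function(ranges) {
    gr <- methods::as(ranges, "GRanges")
    mc <- S4Vectors::mcols(gr)
    if (is.null(mc$motif))
        stop("a 'motif' metadata column is required")
    mc$motif <- toupper(as.character(mc$motif))
    if (is.null(mc$locus_id))
        mc$locus_id <- .bedId(gr)
    mc$motif_length <- nchar(mc$motif)
    mc$ref_repeat_count <- GenomicRanges::width(gr) / mc$motif_length
    if (is.null(mc$annotation))
        mc$annotation <- rep("none", length(gr))
    S4Vectors::mcols(gr) <- mc
    methods::new("VntrCatalog", gr)
}

#' @rdname VntrCatalog-class
#' @export
setMethod("locusIds", "VntrCatalog", function(x) x$locus_id)

#' @rdname VntrCatalog-class
#' @export
setMethod("motifs", "VntrCatalog", function(x) x$motif)

#' @rdname VntrCatalog-class
#' @param x A \code{VntrCatalog}.
#' @export
refArrayLength <- function(x) GenomicRanges::width(x)

#' @rdname VntrCatalog-class
#' @export
refRepeatCount <- function(x) x$ref_repeat_count

setMethod("show", "VntrCatalog", function(object) {
    cat(class(object), "with", length(object), "loci\n")
    if (length(object)) {
        cat("  motif length:", paste(range(object$motif_length),
                                     collapse = "-"), "bp\n")
        tab <- table(object$annotation)
        cat("  annotation:",
            paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                  collapse = " "), "\n")
    }
    invisible(NULL)
})

#' Genomic context used to curate a VNTR catalog
#'
#' Bundles the annotation intervals the curation filters need: gene bodies
#' (strand-aware, used both for overlap and for the transcription start
#' site), optional exon and UTR sub-features (used only to derive the
#' per-locus annotation label), repeat elements to exclude (LINE/SINE), and
#' segmental duplications to exclude. Any slot may be empty.
#'
#' @param genes,exons,utrs,excludedRepeats,segdups \code{GRanges}; genes
#'   should carry meaningful strand (TSS = 5' end of the gene).
#'
#' @return A \code{VntrAnnotation} object.
#' @examples
#' ann <- VntrAnnotation(genes = GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(500, 5000), strand = "+"))
#'
#' @aliases VntrAnnotation
#' @export VntrAnnotation
#' @exportClass VntrAnnotation
setClass("VntrAnnotation",
    representation(genes = "GRanges", exons = "GRanges", utrs = "GRanges",
                   excludedRepeats = "GRanges", segdups = "GRanges"))

VntrAnnotation <- function(genes = GenomicRanges::GRanges(),
                           exons = GenomicRanges::GRanges(),
                           utrs = GenomicRanges::GRanges(),
                           excludedRepeats = GenomicRanges::GRanges(),
                           segdups = GenomicRanges::GRanges()) {
    methods::new("VntrAnnotation", genes = genes, exons = exons,
                 utrs = utrs, excludedRepeats = excludedRepeats,
                 segdups = segdups)
}

setMethod("show", "VntrAnnotation", function(object) {
    cat(class(object), ": ",
        length(object@genes), " genes, ",
        length(object@exons), " exons, ",
        length(object@utrs), " UTRs, ",
        length(object@excludedRepeats), " excluded repeats, ",
        length(object@segdups), " segdups\n", sep = "")
    invisible(NULL)
})

#' Per-locus, per-sample spanning-read coverage
#'
#' A \code{VntrCoverage} is a
#' \link[SummarizedExperiment]{RangedSummarizedExperiment} with loci as rows
#' (the \code{rowRanges} are the \code{\link{VntrCatalog}}) and samples as
#' columns, carrying two integer assays: \code{spanning} (reads whose
#' aligned span strictly contains the locus) and \code{reliable} (spanning
#' reads that additionally pass the flank-identity filter). Column data
#' records \code{total_mapped}, the number of primary mapped reads per
#' sample, used for per-million normalization. The per-repeat-count support
#' tallies of the reliable reads are kept in
#' \code{metadata(x)$support}, a data.frame with columns \code{locus_id},
#' \code{sample_id}, \code{repeat_count}, \code{n_reads}.
#'
#' @param x A \code{VntrCoverage} object.
#'
#' @return \code{spanningCounts()} and \code{reliableCounts()} return
#'   integer matrices (loci x samples); \code{repeatSupport()} the support
#'   data.frame; \code{totalMapped()} a named integer vector.
#'
#' @aliases VntrCoverage spanningCounts reliableCounts repeatSupport
#'   totalMapped
#' @exportClass VntrCoverage
setClass("VntrCoverage",
    contains = "RangedSummarizedExperiment")

.validVntrCoverage <- function(object) {
    a <- SummarizedExperiment::assayNames(object)
    if (!all(c("spanning", "reliable") %in% a))
        return("assays 'spanning' and 'reliable' are required")
    sp <- SummarizedExperiment::assay(object, "spanning")
    re <- SummarizedExperiment::assay(object, "reliable")
    if (any(re > sp))
        return("reliable counts cannot exceed spanning counts")
    TRUE
}

setValidity("VntrCoverage", .validVntrCoverage)

#' @rdname VntrCoverage-class
#' @export
setMethod("spanningCounts", "VntrCoverage", function(x)
    SummarizedExperiment::assay(x, "spanning"))

#' @rdname VntrCoverage-class
#' @export
setMethod("reliableCounts", "VntrCoverage", function(x)
    SummarizedExperiment::assay(x, "reliable"))

#' @rdname VntrCoverage-class
#' @export
setMethod("repeatSupport", "VntrCoverage", function(x)
    S4Vectors::metadata(x)$support)

#' @rdname VntrCoverage-class
#' @export
setMethod("totalMapped", "VntrCoverage", function(x)
    setNames(SummarizedExperiment::colData(x)$total_mapped, colnames(x)))

setMethod("show", "VntrCoverage", function(object) {
    cat(class(object), "with", nrow(object), "loci x", ncol(object),
        "samples\n")
    sp <- spanningCounts(object)
    if (length(sp))
        cat("  median spanning per locus:",
            paste(head(round(apply(sp, 1, median), 1), 5), collapse = " "),
            if (nrow(object) > 5) "..." else "", "\n")
    invisible(NULL)
})

#' Simulation parameters for the synthetic VNTR cohort generator
#'
#' Holds every knob of the synthetic-data model: catalog geometry, diploid
#' cohort structure, read-length and error models, and the
#' targeted-capture dropout model. Defaults emulate a targeted
#' hybridization-capture HiFi experiment: median read length 4,200 bp,
#' substitution rate 0.2\%, mean 30 reads per locus, GC dropout knee at
#' 0.60 and probe-distance knee at 1,000 bp, and 76\% of loci
#' non-polymorphic. \code{mode = "wgs"} switches to unbiased sampling with
#' median read length 18,000 bp and \code{depth} interpreted as genome-wide
#' coverage.
#'
#' @param seed Integer seed; every simulator output is bit-reproducible
#'   given the seed.
#' @param nLoci Number of curatable loci to plant.
#' @param motifLengthRange,repeatCountRange Integer pairs; motifs are at
#'   least 6 bp.
#' @param nSamples Number of unrelated diploid samples.
#' @param nTrios Number of child-mother-father trios (6 extra samples per
#'   trio are NOT added: each trio contributes 3 samples).
#' @param mode \code{"targeted"} or \code{"wgs"}.
#' @param readLengthMedian,readLengthSdlog Log-normal read-length model
#'   (median in bp); defaults 4200/0.35 targeted, 18000/0.35 wgs.
#' @param substitutionRate Per-base substitution error rate.
#' @param depth Mean reads overlapping a locus per sample (targeted) or
#'   genome-wide coverage (wgs).
#' @param gcKnee,gcSlope,pdKnee,pdSlope,dropoutFloor Logistic capture
#'   dropout model: the expected depth multiplier is
#'   \code{floor + (1-floor) / (1+exp(gcSlope*(gc-gcKnee)))
#'   / (1+exp(pdSlope*(pd-pdKnee)))}; identically 1 in wgs mode, and a
#'   zero slope disables that bias component.
#' @param nonpolymorphicFraction Fraction of loci where all samples carry
#'   the reference repeat count.
#' @param denovoRate Per-child-per-locus probability that one transmitted
#'   allele is replaced by a repeat count absent from both parents (for
#'   negative tests of Mendelian consistency).
#' @param flankLen Unique flank planted on each side of every array (bp);
#'   also the per-locus neighborhood to which reads are confined.
#' @param gcLevels Target GC fractions cycled across loci so both sides of
#'   the GC knee are populated.
#' @param probeDistances Probe-to-array gaps in bp, recycled across loci.
#' @param nSegdupDecoys,nLineDecoys,nChrX Extra loci planted inside
#'   segmental-duplication / LINE decoy intervals or on chrX, to exercise
#'   catalog curation.
#' @param offTargetRate Expected extra reads per locus placed entirely in
#'   flank sequence (never overlapping an array).
#'
#' @return A \code{SimulationParams} object.
#' @examples
#' SimulationParams(seed = 7, nLoci = 20, nSamples = 2)
#'
#' @aliases SimulationParams
#' @export SimulationParams
#' @exportClass SimulationParams
setClass("SimulationParams",
    representation(seed = "integer", nLoci = "integer",
        motifLengthRange = "integer", repeatCountRange = "integer",
        nSamples = "integer", nTrios = "integer", mode = "character",
        readLengthMedian = "numeric", readLengthSdlog = "numeric",
        substitutionRate = "numeric", depth = "numeric",
        gcKnee = "numeric", gcSlope = "numeric", pdKnee = "numeric",
        pdSlope = "numeric", dropoutFloor = "numeric",
        nonpolymorphicFraction = "numeric", denovoRate = "numeric",
        flankLen = "integer", gcLevels = "numeric",
        probeDistances = "numeric", nSegdupDecoys = "integer",
        nLineDecoys = "integer", nChrX = "integer",
        offTargetRate = "numeric"))

.validSimulationParams <- function(object) {
    msg <- NULL
    if (!object@mode %in% c("targeted", "wgs"))
        msg <- c(msg, "mode must be 'targeted' or 'wgs'")
    if (object@nLoci < 1L) msg <- c(msg, "nLoci must be >= 1")
    if (object@motifLengthRange[1] < 1L)
        msg <- c(msg, "motif lengths must be positive")
    if (diff(object@motifLengthRange) < 0 ||
        diff(object@repeatCountRange) < 0)
        msg <- c(msg, "ranges must be non-decreasing pairs")
    rates <- c(object@substitutionRate, object@nonpolymorphicFraction,
               object@denovoRate, object@dropoutFloor)
    if (any(rates < 0 | rates > 1))
        msg <- c(msg, "rates must lie in [0, 1]")
    if (object@depth <= 0) msg <- c(msg, "depth must be positive")
    if (is.null(msg)) TRUE else msg
}

setValidity("SimulationParams", .validSimulationParams)

SimulationParams <- function(seed = 1L, nLoci = 50L,
        motifLengthRange = c(6L, 30L), repeatCountRange = c(3L, 15L),
        nSamples = 4L, nTrios = 0L, mode = c("targeted", "wgs"),
        readLengthMedian = NULL, readLengthSdlog = 0.35,
        substitutionRate = 0.002, depth = 30,
        gcKnee = 0.60, gcSlope = 25, pdKnee = 1000, pdSlope = 0.005,
        dropoutFloor = 0.02, nonpolymorphicFraction = 0.76,
        denovoRate = 0, flankLen = 1000L, gcLevels = c(0.45, 0.70),
        probeDistances = 0, nSegdupDecoys = 0L, nLineDecoys = 0L,
        nChrX = 0L, offTargetRate = 0) {
    mode <- match.arg(mode)
    if (is.null(readLengthMedian))
        readLengthMedian <- if (mode == "targeted") 4200 else 18000
    methods::new("SimulationParams", seed = as.integer(seed),
        nLoci = as.integer(nLoci),
        motifLengthRange = as.integer(motifLengthRange),
        repeatCountRange = as.integer(repeatCountRange),
        nSamples = as.integer(nSamples), nTrios = as.integer(nTrios),
        mode = mode, readLengthMedian = readLengthMedian,
        readLengthSdlog = readLengthSdlog,
        substitutionRate = substitutionRate, depth = depth,
        gcKnee = gcKnee, gcSlope = gcSlope, pdKnee = pdKnee,
        pdSlope = pdSlope, dropoutFloor = dropoutFloor,
        nonpolymorphicFraction = nonpolymorphicFraction,
        denovoRate = denovoRate, flankLen = as.integer(flankLen),
        gcLevels = gcLevels, probeDistances = probeDistances,
        nSegdupDecoys = as.integer(nSegdupDecoys),
        nLineDecoys = as.integer(nLineDecoys), nChrX = as.integer(nChrX),
        offTargetRate = offTargetRate)
}

setMethod("show", "SimulationParams", function(object) {
    cat(class(object), " (", object@mode, " mode)\n",
        "  loci: ", object@nLoci, ", samples: ", object@nSamples,
        ", trios: ", object@nTrios, "\n",
        "  depth ", object@depth, ", read length median ",
        object@readLengthMedian, " bp, substitution rate ",
        object@substitutionRate, "\n", sep = "")
    invisible(NULL)
})
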