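## Read primary mapped alignments (with sequences) from SAM or BAM.
## Plain SAM is converted to a temporary sorted BAM via Rsamtools.
.readAlignments <- function(file) {
    if (grepl("\\.sam$", file, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        file <- Rsamtools::asBam(file, dest, overwrite = TRUE,
                                 indexDestination = TRUE)
    }
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE)
    param <- Rsamtools::ScanBamParam(flag = flag, what = "seq")
    GenomicAlignments::readGAlignments(file, param = param,
                                       use.names = TRUE)
}

#' Does a read's aligned span strictly contain a locus?
#'
#' A read is \emph{spanning} when its reference-aligned interval contains
#' the VNTR array with at least one base of flank on each side:
#' \code{start(read) < start(locus)} and \code{end(read) > end(locus)}
#' (same chromosome).
#'
#' @param reads A \code{GAlignments} or \code{GRanges} of reads.
#' @param locus A length-1 \code{GRanges}/\code{VntrCatalog} row.
#'
#' @return Logical vector, one per read.
#' @examples
#' reads <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
#'     c(991, 1001, 1051), c(1210, 1210, 1150)))
#' locus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1200))
#' isSpanning(reads, locus)   # TRUE FALSE FALSE
#' @export
isSpanning <- function(reads, locus) {
    stopifnot(length(locus) == 1L)
    sameChrom <- as.character(GenomicRanges::seqnames(reads)) ==
        as.character(GenomicRanges::seqnames(locus))
    sameChrom &
        GenomicRanges::start(reads) < GenomicRanges::start(locus) &
        GenomicRanges::end(reads) > GenomicRanges::end(locus)
}

## Per-read flank match rates against the reference, on reference-space
## projected sequences. Returns logical; reads must already span.
.flankReliable <- function(gal, locus, reference, minFlank, minMatch,
                           maxFlankWindow) {
    if (!length(gal)) return(logical(0))
    aStart <- GenomicRanges::start(locus)
    aEnd <- GenomicRanges::end(locus)
    chrom <- as.character(GenomicRanges::seqnames(locus))
    clens <- .contigLengths(reference)
    winL <- min(maxFlankWindow, aStart - 1L)
    winR <- min(maxFlankWindow, clens[[chrom]] - aEnd)
    refL <- if (winL > 0) strsplit(as.character(.getRefSeqs(reference,
        GenomicRanges::GRanges(chrom,
            IRanges::IRanges(aStart - winL, aStart - 1L))))[[1]],
        "")[[1]] else character(0)
    refR <- if (winR > 0) strsplit(as.character(.getRefSeqs(reference,
        GenomicRanges::GRanges(chrom,
            IRanges::IRanges(aEnd + 1L, aEnd + winR))))[[1]],
        "")[[1]] else character(0)
    laid <- GenomicAlignments::sequenceLayer(
        S4Vectors::mcols(gal)$seq, GenomicAlignments::cigar(gal))
    rs <- GenomicRanges::start(gal)
    re <- GenomicRanges::end(gal)
    vapply(seq_along(gal), function(i) {
        wL <- min(maxFlankWindow, aStart - rs[i], winL)
        wR <- min(maxFlankWindow, re[i] - aEnd, winR)
        if (wL < minFlank || wR < minFlank) return(FALSE)
        s <- strsplit(as.character(laid[[i]]), "")[[1]]
        # left flank: last wL ref bases before the array
        offL <- (aStart - wL) - rs[i] + 1L
        mL <- sum(s[offL:(offL + wL - 1L)] ==
                  refL[(winL - wL + 1L):winL])
        if (mL / wL < minMatch) return(FALSE)
        offR <- (aEnd + 1L) - rs[i] + 1L
        mR <- sum(s[offR:(offR + wR - 1L)] == refR[seq_len(wR)])
        mR / wR >= minMatch
    }, logical(1))
}

#' Is a spanning read reliable at a locus?
#'
#' A spanning read is \emph{reliable} when its alignment covers at least
#' \code{minFlank} reference bp on each side of the array and, on each
#' flank separately, the aligned-base identity against the reference is
#' at least \code{minMatch} (deletions count as mismatches). The identity
#' window extends up to \code{maxFlankWindow} bp per side when the read
#' provides that much flank. With exactly 10 bp of flank available the
#' default 95\% forces a perfect flank.
#'
#' @param gal \code{GAlignments} with a \code{seq} metadata column (as
#'   read by \code{\link{countSpanning}}'s loader).
#' @param locus Length-1 locus.
#' @param reference FASTA path, \code{FaFile} or named
#'   \code{DNAStringSet}.
#' @param minFlank Minimum aligned flank per side, bp.
#' @param minMatch Minimum flank identity per side.
#' @param maxFlankWindow Largest flank window used per side, bp.
#'
#' @return Logical vector, one per read; \code{FALSE} where the read does
#'   not span.
#' @export
isReliable <- function(gal, locus, reference, minFlank = 10L,
                       minMatch = 0.95, maxFlankWindow = 100L) {
    ok <- isSpanning(gal, locus)
    out <- logical(length(gal))
    if (any(ok))
        out[ok] <- .flankReliable(gal[ok], locus, reference, minFlank,
                                  minMatch, maxFlankWindow)
    out
}

#' Count spanning and reliable reads per locus per sample
#'
#' Tallies, for every catalog locus and every sample, the reads whose
#' aligned span strictly contains the locus (\code{spanning}) and the
#' subset that also passes the flank-identity filter (\code{reliable});
#' the reliable reads' repeat-count estimates
#' (\code{\link{estimateRepeatCount}}) are tallied into the per-locus
#' support table used by genotyping. Secondary and supplementary
#' alignments are ignored; duplicates are kept.
#'
#' @param files Named character vector of coordinate-sorted BAM (or plain
#'   SAM) files, one per sample; names are sample ids (basenames when
#'   unnamed).
#' @param catalog A \code{\link{VntrCatalog}}.
#' @param reference FASTA path, \code{FaFile} or named
#'   \code{DNAStringSet} (the assembly the reads are aligned to).
#' @inheritParams isReliable
#'
#' @return A \code{\link{VntrCoverage}}.
#'
#' @seealso \code{\link{classifyCoverage}}, \code{\link{callGenotypes}}
#' @export
countSpanning <- function(files, catalog, reference, minFlank = 10L,
                          minMatch = 0.95, maxFlankWindow = 100L) {
    stopifnot(methods::is(catalog, "VntrCatalog"), length(files) >= 1L)
    if (is.null(names(files)))
        names(files) <- sub("\\.(bam|sam)$", "", basename(files),
                            ignore.case = TRUE)
    nL <- length(catalog)
    nS <- length(files)
    spanning <- matrix(0L, nL, nS,
                       dimnames = list(locusIds(catalog), names(files)))
    reliable <- spanning
    totalMapped <- integer(nS)
    supportRows <- list()
    for (s in seq_len(nS)) {
        gal <- .readAlignments(files[[s]])
        totalMapped[s] <- length(gal)
        hits <- IRanges::findOverlaps(catalog,
            GenomicRanges::granges(gal), ignore.strand = TRUE)
        byLocus <- split(S4Vectors::subjectHits(hits),
                         S4Vectors::queryHits(hits))
        for (li in names(byLocus)) {
            i <- as.integer(li)
            locus <- catalog[i]
            g <- gal[byLocus[[li]]]
            sp <- isSpanning(g, locus)
            spanning[i, s] <- sum(sp)
            if (!any(sp)) next
            gsp <- g[sp]
            rel <- .flankReliable(gsp, locus, reference, minFlank,
                                  minMatch, maxFlankWindow)
            reliable[i, s] <- sum(rel)
            if (!any(rel)) next
            rc <- estimateRepeatCount(gsp[rel], locus,
                                      locus$motif_length)
            tab <- table(rc)
            supportRows[[length(supportRows) + 1L]] <- data.frame(
                locus_id = locusIds(catalog)[i],
                sample_id = names(files)[s],
                repeat_count = as.integer(names(tab)),
                n_reads = as.integer(tab))
        }
    }
    support <- if (length(supportRows)) do.call(rbind, supportRows)
        else data.frame(locus_id = character(0), sample_id = character(0),
                        repeat_count = integer(0), n_reads = integer(0))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(spanning = spanning, reliable = reliable),
        rowRanges = catalog,
        colData = S4Vectors::DataFrame(sample_id = names(files),
            total_mapped = totalMapped, row.names = names(files)),
        metadata = list(support = support))
    methods::new("VntrCoverage", se)
}

#' Call genotypes for every locus and sample of a coverage object
#'
#' Applies \code{\link{callGenotype}} to the reliable-read support table
#' of a \code{\link{VntrCoverage}}.
#'
#' @param cov A \code{VntrCoverage}.
#' @param minSupport Minimum reliable reads per called allele.
#'
#' @return Data frame with columns \code{locus_id}, \code{sample_id},
#'   \code{allele1}, \code{allele2} (NA pairs are no-calls), covering
#'   every locus x sample combination.
#' @export
callGenotypes <- function(cov, minSupport = 3L) {
    stopifnot(methods::is(cov, "VntrCoverage"))
    sup <- repeatSupport(cov)
    grid <- expand.grid(locus_id = rownames(cov),
                        sample_id = colnames(cov),
                        stringsAsFactors = FALSE)
    key <- paste(sup$locus_id, sup$sample_id)
    bySite <- split(seq_len(nrow(sup)), key)
    gts <- t(vapply(seq_len(nrow(grid)), function(i) {
        rows <- bySite[[paste(grid$locus_id[i], grid$sample_id[i])]]
        if (is.null(rows))
            return(c(NA_integer_, NA_integer_))
        callGenotype(setNames(sup$n_reads[rows],
                              sup$repeat_count[rows]), minSupport)
    }, integer(2)))
    data.frame(locus_id = grid$locus_id, sample_id = grid$sample_id,
               allele1 = gts[, 1], allele2 = gts[, 2])
}

#' Distance from each locus to the nearest probe
#'
#' 0 when a probe overlaps the locus, otherwise the minimum gap in bp
#' between the locus and any probe interval; \code{NA} when no probe
#' exists (or none shares the locus chromosome).
#'
#' @param catalog A \code{\link{VntrCatalog}} (or \code{GRanges}).
#' @param probes \code{GRanges} of probe-covered intervals.
#'
#' @return Integer vector, one per locus (NA = missing).
#' @examples
#' cat <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1100))
#' probes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(501, 750))
#' probeDistance(cat, probes)   # 250
#' @export
probeDistance <- function(catalog, probes) {
    n <- length(catalog)
    if (is.null(probes) || length(probes) == 0L)
        return(rep(NA_integer_, n))
    hits <- IRanges::distanceToNearest(
        GenomicRanges::granges(catalog), GenomicRanges::granges(probes),
        ignore.strand = TRUE)
    out <- rep(NA_integer_, n)
    out[S4Vectors::queryHits(hits)] <-
        as.integer(S4Vectors::mcols(hits)$distance)
    out
}

.COVERAGE_TIERS <- c("uncovered", "low", "well_covered", "high")

#' Classify per-locus coverage across samples
#'
#' Summarizes each locus's spanning-read counts across samples into a
#' coverage tier based on the cross-sample median: \code{uncovered}
#' (median 0), \code{low} (below \code{wellThreshold}),
#' \code{well_covered} (at least \code{wellThreshold}, the binomially
#' derived 15-read genotyping threshold) and \code{high} (at least
#' \code{highThreshold}). Cross-sample homogeneity is reported as the
#' population variance of counts projected to \code{projectionCap}
#' (counts above the cap are set to the cap before the variance).
#'
#' @param x A \code{\link{VntrCoverage}} or an integer matrix
#'   (loci x samples) of spanning counts.
#' @param wellThreshold,highThreshold Tier thresholds (median spanning
#'   reads).
#' @param projectionCap Projection ceiling for the homogeneity variance.
#'
#' @return Data frame: \code{locus_id}, \code{median_spanning},
#'   \code{tier}, \code{cross_sample_variance}.
#'
#' @examples
#' m <- rbind(L1 = c(100, 80, 70, 90), L2 = c(0, 0, 0, 0))
#' classifyCoverage(m)
#' @export
classifyCoverage <- function(x, wellThreshold = 15L, highThreshold = 63L,
                             projectionCap = 30L) {
    m <- if (methods::is(x, "VntrCoverage")) spanningCounts(x) else x
    if (is.null(dim(m)) || ncol(m) < 1L)
        stop("at least one sample is required")
    med <- apply(m, 1, median)
    proj <- pmin(m, projectionCap)
    # population variance of the projected counts
    pvar <- apply(proj, 1, function(v) mean((v - mean(v))^2))
    tier <- ifelse(med == 0, "uncovered",
            ifelse(med < wellThreshold, "low",
            ifelse(med < highThreshold, "well_covered", "high")))
    data.frame(locus_id = rownames(m), median_spanning = med,
               tier = factor(tier, levels = .COVERAGE_TIERS),
               cross_sample_variance = pvar, row.names = NULL)
}

#' Spanning reads per million mapped reads
#'
#' Normalizes spanning counts by the sample's total primary mapped reads:
#' \code{n_spanning * 1e6 / total_mapped}.
#'
#' @param x A \code{\link{VntrCoverage}} (total mapped reads taken from
#'   its column data) or a numeric matrix/vector of spanning counts.
#' @param totalMappedReads Positive totals, recycled across columns when
#'   \code{x} is a matrix. Ignored for \code{VntrCoverage} input.
#'
#' @return Numeric object shaped like the spanning counts.
#' @examples
#' normalizePerMillion(c(L1 = 15), 1e6)   # 15
#' @rdname normalizePerMillion
#' @export
setMethod("normalizePerMillion", "VntrCoverage",
    function(x, totalMappedReads) {
        tm <- totalMapped(x)
        if (any(tm <= 0)) stop("total mapped reads must be positive")
        sweep(spanningCounts(x), 2, tm, "/") * 1e6
    })

#' @rdname normalizePerMillion
#' @export
setMethod("normalizePerMillion", "ANY", function(x, totalMappedReads) {
    if (any(totalMappedReads <= 0))
        stop("total mapped reads must be positive")
    if (is.matrix(x)) sweep(x, 2, totalMappedReads, "/") * 1e6
    else x * 1e6 / totalMappedReads
})

#' Fraction of mapped reads overlapping any catalog locus
#'
#' On-target efficiency: the fraction of primary mapped reads whose
#' aligned interval overlaps at least one VNTR array (any overlap).
#'
#' @param reads A BAM/SAM path, \code{GAlignments} or \code{GRanges}.
#' @param catalog A non-empty \code{\link{VntrCatalog}}.
#'
#' @return A fraction in [0, 1].
#' @export
spanningEfficiency <- function(reads, catalog) {
    stopifnot(length(catalog) >= 1L)
    if (is.character(reads))
        reads <- .readAlignments(reads)
    gr <- GenomicRanges::granges(reads)
    if (!length(gr)) return(NA_real_)
    mean(IRanges::overlapsAny(gr, GenomicRanges::granges(catalog),
                                    ignore.strand = TRUE))
}
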