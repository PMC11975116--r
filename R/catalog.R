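#' Read candidate tandem-repeat records into a VntrCatalog
#'
#' Ingests raw tandem-repeat records without applying any curation filter
#' (short motifs, repeat-element overlaps etc. are removed later by
#' \code{\link{curateCatalog}}). Two dialects are supported:
#' \describe{
#'   \item{\code{bed}}{Whitespace-delimited columns
#'     \code{chrom start end motif [name]}; 0-based half-open coordinates.
#'     When a name column is present it becomes \code{locus_id}, otherwise
#'     the id is derived as \code{chrom:start-end}.}
#'   \item{\code{trf_dat}}{Tandem Repeats Finder \code{.dat} output:
#'     \code{Sequence: <chrom>} headers followed by 15-field records
#'     (start and end 1-based inclusive, consensus motif in field 14).
#'     The consensus motif is taken verbatim; no re-derivation.}
#' }
#'
#' @param path File to read.
#' @param format \code{"bed"} or \code{"trf_dat"}.
#'
#' @return A \code{\link{VntrCatalog}} with one locus per record.
#'
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t1000\t1100\tACGTGG", bed)
#' readTandemRepeats(bed, "bed")
#' @export
readTandemRepeats <- function(path, format = c("bed", "trf_dat")) {
    if (!file.exists(path))
        stop("file not found: ", path)
    format <- tryCatch(match.arg(format),
        error = function(e) stop("unknown format tag: ", format[1]))
    if (format == "bed") .readCatalogBed(path) else .readTrfDat(path)
}

.emptyCatalog <- function() {
    VntrCatalog(GenomicRanges::GRanges(motif = character(0)))
}

.readCatalogBed <- function(path) {
    lines <- readLines(path)
    lines <- lines[!grepl("^(#|track|browser)", lines) &
                   nzchar(trimws(lines))]
    if (!length(lines)) return(.emptyCatalog())
    fields <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(fields)
    bad <- which(nf < 4L)
    if (length(bad))
        stop("malformed BED record at line ", bad[1],
             ": expected >= 4 fields, got ", nf[bad[1]])
    chrom <- vapply(fields, `[[`, character(1), 1L)
    start <- suppressWarnings(as.integer(vapply(fields, `[[`,
                                                character(1), 2L)))
    end <- suppressWarnings(as.integer(vapply(fields, `[[`,
                                              character(1), 3L)))
    motif <- toupper(vapply(fields, `[[`, character(1), 4L))
    bad <- which(is.na(start) | is.na(end) | end <= start |
                 !grepl("^[ACGT]+$", motif))
    if (length(bad))
        stop("malformed BED record at line ", bad[1])
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start + 1L, end), motif = motif)
    name <- vapply(fields, function(f)
        if (length(f) >= 5L) f[[5L]] else NA_character_, character(1))
    if (!anyNA(name))
        gr$locus_id <- name
    VntrCatalog(gr)
}

.readTrfDat <- function(path) {
    lines <- readLines(path)
    chrom <- NA_character_
    recs <- list()
    for (i in seq_along(lines)) {
        ln <- trimws(lines[[i]])
        if (!nzchar(ln)) next
        if (grepl("^Sequence:", ln)) {
            chrom <- sub("^Sequence:\\s*", "", ln)
            chrom <- strsplit(chrom, "\\s+")[[1]][1]
            next
        }
        if (!grepl("^[0-9]", ln)) next   # version/parameter banner lines
        f <- strsplit(ln, "\\s+")[[1]]
        if (length(f) < 14L)
            stop("malformed TRF record at line ", i,
                 ": expected >= 14 fields, got ", length(f))
        start <- suppressWarnings(as.integer(f[1]))
        end <- suppressWarnings(as.integer(f[2]))
        motif <- toupper(f[14])
        if (is.na(start) || is.na(end) || end < start ||
            !grepl("^[ACGT]+$", motif))
            stop("malformed TRF record at line ", i)
        if (is.na(chrom))
            stop("TRF record at line ", i, " precedes any Sequence header")
        recs[[length(recs) + 1L]] <-
            data.frame(chrom = chrom, start = start, end = end,
                       motif = motif)
    }
    if (!length(recs)) return(.emptyCatalog())
    df <- do.call(rbind, recs)
    VntrCatalog(GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(df$start, df$end), motif = df$motif))
}

.AUTOSOMES <- c(as.character(1:22), paste0("chr", 1:22))

.isAutosome <- function(chrom) as.character(chrom) %in% .AUTOSOMES

## Strand-aware promoter test: locus start within [TSS - flank, TSS) on the
## gene's strand (mirrored for minus-strand genes).
.nearTss <- function(loci, genes, flank) {
    if (!length(genes)) return(rep(FALSE, length(loci)))
    hit <- rep(FALSE, length(loci))
    plus <- genes[BiocGenerics::strand(genes) != "-"]
    minus <- genes[BiocGenerics::strand(genes) == "-"]
    if (length(plus)) {
        win <- GenomicRanges::GRanges(GenomicRanges::seqnames(plus),
            IRanges::IRanges(pmax(1L, GenomicRanges::start(plus) - flank),
                             pmax(1L, GenomicRanges::start(plus) - 1L)))
        anchors <- GenomicRanges::GRanges(GenomicRanges::seqnames(loci),
            IRanges::IRanges(GenomicRanges::start(loci),
                             GenomicRanges::start(loci)))
        hit <- hit | IRanges::overlapsAny(anchors, win)
    }
    if (length(minus)) {
        win <- GenomicRanges::GRanges(GenomicRanges::seqnames(minus),
            IRanges::IRanges(GenomicRanges::end(minus) + 1L,
                             GenomicRanges::end(minus) + flank))
        anchors <- GenomicRanges::GRanges(GenomicRanges::seqnames(loci),
            IRanges::IRanges(GenomicRanges::end(loci),
                             GenomicRanges::end(loci)))
        hit <- hit | IRanges::overlapsAny(anchors, win)
    }
    hit
}

.annotationLabel <- function(loci, ann, tssFlank) {
    genes <- ann@genes
    exons <- ann@exons
    utrs <- ann@utrs
    inGene <- IRanges::overlapsAny(loci, genes)
    hitExon <- IRanges::overlapsAny(loci, exons)
    hitUtr <- IRanges::overlapsAny(loci, utrs)
    # intron = gene body minus exons and UTRs; a gene with no sub-features
    # is all intron for labeling purposes
    introns <- BiocGenerics::setdiff(
        IRanges::reduce(genes, ignore.strand = TRUE),
        IRanges::reduce(c(GenomicRanges::granges(exons),
                                GenomicRanges::granges(utrs)),
                              ignore.strand = TRUE),
        ignore.strand = TRUE)
    hitIntron <- IRanges::overlapsAny(loci, introns)
    promoter <- .nearTss(loci, genes, tssFlank)
    label <- rep("none", length(loci))
    label[promoter] <- "promoter"
    label[inGene & hitIntron] <- "intronic"
    label[inGene & hitUtr] <- "utr"
    label[inGene & hitExon] <- "exonic"
    label[inGene & hitExon & hitIntron] <- "multiple"
    label
}

#' Curate a candidate VNTR catalog
#'
#' Applies the gene-proximal VNTR selection filters, in a fixed order so
#' every exclusion is attributable to exactly one reason:
#' \enumerate{
#'   \item \code{motif}: motif length below \code{minMotif} (default 6 bp);
#'   \item \code{repeat_element}: any overlap with a LINE/SINE interval;
#'   \item \code{segdup}: any overlap with a segmental duplication;
#'   \item \code{proximity}: neither overlapping a gene body nor lying
#'     within \code{tssFlank} bp upstream of a transcription start site
#'     (strand-aware);
#'   \item \code{chromosome}: not autosomal (only when
#'     \code{autosomesOnly}).
#' }
#' Retained loci are labeled \code{exonic}, \code{utr}, \code{intronic},
#' \code{promoter} or \code{multiple} (spanning both exonic and intronic
#' sequence), with precedence exonic > utr > intronic when sub-features
#' coincide. Curation is idempotent.
#'
#' @param candidates A \code{\link{VntrCatalog}} of unfiltered records.
#' @param ann A \code{\link{VntrAnnotation}}.
#' @param tssFlank Promoter window upstream of the TSS, bp.
#' @param minMotif Minimum motif length, bp.
#' @param autosomesOnly Drop loci off chr1-chr22.
#' @param containment If \code{TRUE}, exclusion intervals remove a locus
#'   only when they fully contain it; default is any-overlap (>= 1 bp).
#'
#' @return A curated \code{VntrCatalog}; excluded loci are logged in
#'   \code{metadata(x)$exclusions} (data.frame \code{locus_id},
#'   \code{reason}).
#'
#' @examples
#' cand <- VntrCatalog(GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(2001, 2100), motif = "ACGTGG"))
#' ann <- VntrAnnotation(genes = GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(1500, 3000), strand = "+"))
#' curateCatalog(cand, ann)
#' @export
curateCatalog <- function(candidates, ann, tssFlank = 500L, minMotif = 6L,
                          autosomesOnly = TRUE, containment = FALSE) {
    stopifnot(methods::is(candidates, "VntrCatalog"),
              methods::is(ann, "VntrAnnotation"))
    n <- length(candidates)
    reason <- rep(NA_character_, n)
    ovl <- function(excl) {
        if (!length(excl)) return(rep(FALSE, n))
        if (containment)
            IRanges::overlapsAny(candidates, excl, type = "within",
                                       ignore.strand = TRUE)
        else
            IRanges::overlapsAny(candidates, excl,
                                       ignore.strand = TRUE)
    }
    fail <- candidates$motif_length < minMotif
    reason[is.na(reason) & fail] <- "motif"
    fail <- ovl(ann@excludedRepeats)
    reason[is.na(reason) & fail] <- "repeat_element"
    fail <- ovl(ann@segdups)
    reason[is.na(reason) & fail] <- "segdup"
    proximal <- IRanges::overlapsAny(candidates, ann@genes,
                                           ignore.strand = TRUE) |
        .nearTss(candidates, ann@genes, as.integer(tssFlank))
    reason[is.na(reason) & !proximal] <- "proximity"
    if (autosomesOnly) {
        fail <- !.isAutosome(GenomicRanges::seqnames(candidates))
        reason[is.na(reason) & fail] <- "chromosome"
    }
    keep <- is.na(reason)
    out <- candidates[keep]
    if (length(out))
        out$annotation <- .annotationLabel(out, ann,
                                           as.integer(tssFlank))
    S4Vectors::metadata(out)$exclusions <- data.frame(
        locus_id = locusIds(candidates)[!keep],
        reason = reason[!keep])
    out
}

#' GC content of loci with flanking sequence
#'
#' Fraction of G or C bases (case-insensitive) over each locus interval
#' extended by \code{flank} bp on both sides, truncated at contig edges.
#' N bases are excluded from the denominator; an all-N window yields
#' \code{NA}. The convention (100 bp flank) reflects that capture dropout
#' is driven by the GC of the whole hybridized fragment, not the array
#' alone.
#'
#' @param x A \code{VntrCatalog} (or \code{GRanges}).
#' @param reference An \code{Rsamtools::FaFile}, a FASTA path, or a named
#'   \code{DNAStringSet}.
#' @param flank Flank width in bp on each side.
#' @param ... Unused.
#'
#' @return Numeric vector of GC fractions in [0, 1] (NA where undefined).
#'
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "AATTGGCC"))
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 8),
#'                              motif = "AATTGGCC")
#' gcContent(VntrCatalog(gr), ref, flank = 0)
#' @rdname gcContent
#' @export
setMethod("gcContent", "GRanges", function(x, reference, flank = 100L,
                                           ...) {
    seqs <- .getRefSeqs(reference,
        .clampToContig(x, reference, as.integer(flank)))
    af <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
    gc <- af[, "G"] + af[, "C"]
    den <- rowSums(af[, c("A", "C", "G", "T"), drop = FALSE])
    ifelse(den == 0, NA_real_, gc / den)
})

.contigLengths <- function(reference) {
    if (methods::is(reference, "DNAStringSet"))
        return(setNames(Biostrings::width(reference), names(reference)))
    if (is.character(reference))
        reference <- Rsamtools::FaFile(reference)
    idx <- Rsamtools::scanFaIndex(reference)
    setNames(GenomicRanges::width(idx),
             as.character(GenomicRanges::seqnames(idx)))
}

.clampToContig <- function(gr, reference, flank) {
    len <- .contigLengths(reference)
    chrom <- as.character(GenomicRanges::seqnames(gr))
    if (any(!chrom %in% names(len)))
        stop("interval(s) absent from reference: ",
             paste(unique(chrom[!chrom %in% names(len)]), collapse = ", "))
    GenomicRanges::GRanges(chrom,
        IRanges::IRanges(pmax(1L, GenomicRanges::start(gr) - flank),
                         pmin(len[chrom], GenomicRanges::end(gr) + flank)))
}

.getRefSeqs <- function(reference, gr) {
    if (methods::is(reference, "DNAStringSet")) {
        chrom <- as.character(GenomicRanges::seqnames(gr))
        return(Biostrings::DNAStringSet(vapply(seq_along(gr), function(i)
            as.character(Biostrings::subseq(reference[[chrom[i]]],
                GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i])),
            character(1))))
    }
    if (is.character(reference))
        reference <- Rsamtools::FaFile(reference)
    Rsamtools::getSeq(reference, gr)
}

#' Read curation annotation tracks from BED files
#'
#' Builds a \code{\link{VntrAnnotation}} from standard BED files (via
#' \pkg{rtracklayer}); any argument may be omitted.
#'
#' @param genes BED (with strand column) of gene bodies.
#' @param exons,utrs Optional BED of exon / UTR features.
#' @param excludedRepeats BED of LINE/SINE intervals.
#' @param segdups BED of segmental duplications.
#' @return A \code{VntrAnnotation}.
#' @examples
#' readAnnotation()    # empty annotation
#' @export
readAnnotation <- function(genes = NULL, exons = NULL, utrs = NULL,
                           excludedRepeats = NULL, segdups = NULL) {
    rd <- function(p) {
        if (is.null(p)) GenomicRanges::GRanges()
        else GenomicRanges::granges(rtracklayer::import(p, format = "BED"))
    }
    rdStranded <- function(p) {
        if (is.null(p)) return(GenomicRanges::GRanges())
        g <- rtracklayer::import(p, format = "BED")
        GenomicRanges::granges(g)
    }
    VntrAnnotation(genes = rdStranded(genes), exons = rd(exons),
                   utrs = rd(utrs), excludedRepeats = rd(excludedRepeats),
                   segdups = rd(segdups))
}

#' Write a curated catalog (and its exclusion log) as TSV
#'
#' The catalog is written as six columns (\code{locus_id chrom start end
#' motif annotation}, BED-convention 0-based starts); if an exclusion log
#' is present in \code{metadata(x)$exclusions} it is written next to the
#' catalog with suffix \code{.exclusions.tsv}.
#'
#' @param x A \code{\link{VntrCatalog}}.
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @examples
#' cat <- VntrCatalog(GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(1001, 1100), motif = "ACGTGG"))
#' writeCatalog(cat, tempfile(fileext = ".tsv"))
#' @export
writeCatalog <- function(x, path) {
    df <- data.frame(locus_id = locusIds(x),
        chrom = as.character(GenomicRanges::seqnames(x)),
        start = GenomicRanges::start(x) - 1L,
        end = GenomicRanges::end(x),
        motif = motifs(x), annotation = x$annotation)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    excl <- S4Vectors::metadata(x)$exclusions
    if (!is.null(excl))
        write.table(excl, sub("\\.tsv$", ".exclusions.tsv", path),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
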