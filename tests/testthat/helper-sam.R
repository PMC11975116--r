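## Minimal SAM writer for hand-built fixtures, independent of the
## package's internal writer. `records` needs qname, rname, pos, cigar,
## seq; `contigs` is a named DNAStringSet or named character vector.
write_test_sam <- function(records, contigs, path = tempfile(fileext = ".sam")) {
    if (methods::is(contigs, "DNAStringSet"))
        contigs <- setNames(as.character(contigs), names(contigs))
    lines <- c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                       nchar(contigs)))
    if (nrow(records)) {
        records <- records[order(records$rname, records$pos), ]
        lines <- c(lines,
            sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                    records$qname, records$rname, records$pos,
                    records$cigar, records$seq))
    }
    writeLines(lines, path)
    path
}

## Reference with one perfect VNTR array: flanks of `flank` random bases
## around `copies` copies of `motif`, as a one-contig DNAStringSet plus
## the 1-based array coordinates.
make_test_locus <- function(motif = "ACGTGG", copies = 10, flank = 100,
                            seed = 101) {
    set.seed(seed)
    left <- paste(sample(c("A", "C", "G", "T"), flank, TRUE),
                  collapse = "")
    right <- paste(sample(c("A", "C", "G", "T"), flank, TRUE),
                   collapse = "")
    arr <- strrep(motif, copies)
    ref <- Biostrings::DNAStringSet(setNames(paste0(left, arr, right),
                                             "chr1"))
    list(reference = ref,
         aStart = flank + 1L,
         aEnd = flank + nchar(arr),
         locus = VntrCatalog(GenomicRanges::GRanges("chr1",
             IRanges::IRanges(flank + 1L, flank + nchar(arr)),
             motif = motif)))
}

## Substring of the single contig (1-based inclusive).
ref_substr <- function(ref, from, to) {
    substr(as.character(ref[[1]]), from, to)
}
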