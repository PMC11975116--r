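make_bed <- function(lines) {
    p <- tempfile(fileext = ".bed")
    writeLines(lines, p)
    p
}

test_that("BED catalog records map fields directly without filtering", {
    cat <- readTandemRepeats(make_bed("chr1\t1000\t1100\tACGTGG"), "bed")
    expect_length(cat, 1L)
    expect_identical(locusIds(cat), "chr1:1000-1100")
    expect_identical(cat$motif_length, 6L)
    expect_identical(refArrayLength(cat), 100L)
    expect_equal(refRepeatCount(cat), 100 / 6)
    # 1-based internal coordinates from 0-based BED
    expect_identical(GenomicRanges::start(cat), 1001L)
    # optional name column becomes the id; short motifs are NOT filtered
    cat2 <- readTandemRepeats(make_bed(c(
        "chr1 1000 1100 ACGTGG vntr_a",
        "chr2 50 80 AAAAG vntr_b")), "bed")
    expect_identical(locusIds(cat2), c("vntr_a", "vntr_b"))
    expect_identical(cat2$motif_length, c(6L, 5L))
    # empty file -> empty catalog
    expect_length(readTandemRepeats(make_bed(character(0)), "bed"), 0L)
    # malformed records name the line
    expect_error(readTandemRepeats(make_bed(c(
        "chr1\t0\t10\tACGTGG", "chr1\t5\tACGTGG")), "bed"), "line 2")
    expect_error(readTandemRepeats(make_bed("chr1\t10\t5\tACGTGG"),
                                   "bed"), "line 1")
    expect_error(readTandemRepeats(make_bed("x"), "vcf"),
                 "unknown format")
})

test_that("TRF .dat records parse with their Sequence context", {
    dat <- make_bed(c(
        "Tandem Repeats Finder Program",
        "Sequence: chr1",
        "Parameters: 2 7 7 80 10 50 500",
        paste("1001 1100 6 16.7 6 95 0 180 25 25 25 25 1.9",
              "ACGTGG ACGTGGACGTGG"),
        "Sequence: chr2",
        paste("51 80 5 6.0 5 100 0 60 40 20 20 20 1.8",
              "AAAAG AAAAGAAAAG")))
    cat <- readTandemRepeats(dat, "trf_dat")
    expect_length(cat, 2L)
    expect_identical(as.character(GenomicRanges::seqnames(cat)),
                     c("chr1", "chr2"))
    # TRF coordinates are 1-based inclusive; consensus motif verbatim,
    # and a 5-bp motif is parsed (curation, not parsing, filters it)
    expect_identical(GenomicRanges::start(cat), c(1001L, 51L))
    expect_identical(motifs(cat), c("ACGTGG", "AAAAG"))
    bad <- make_bed(c("Sequence: chr1", "1001 1100 6"))
    expect_error(readTandemRepeats(bad, "trf_dat"), "line 2")
})

test_that("curation applies the filters in order with logged reasons", {
    # candidates: short motif / in-LINE / in-segdup (1 bp overlap) /
    # gene-overlapping keeper / promoter keeper / orphan / chrX
    cand <- VntrCatalog(GenomicRanges::GRanges(
        c("chr1", "chr1", "chr1", "chr1", "chr1", "chr1", "chrX"),
        IRanges::IRanges(
            c(1001, 3001, 5001, 7001, 8600, 12001, 1001),
            width = 100),
        motif = c("AAAAG", "ACGTGG", "ACGTGG", "ACGTGG", "ACGTGG",
                  "ACGTGG", "ACGTGG")))
    ann <- VntrAnnotation(
        genes = GenomicRanges::GRanges(
            c("chr1", "chr1", "chr1", "chr1", "chrX"),
            IRanges::IRanges(c(900, 2900, 4900, 6900, 900),
                             width = c(2200, 2200, 2200, 300, 2200)),
            strand = "+"),
        excludedRepeats = GenomicRanges::GRanges("chr1",
            IRanges::IRanges(3050, 3060)),
        segdups = GenomicRanges::GRanges("chr1",
            IRanges::IRanges(5100, 5300)))   # overlaps locus 3 by 1 bp
    # promoter keeper: gene TSS at 9001, locus start 8601 = 400 bp
    # upstream, no gene-body overlap
    ann@genes <- c(ann@genes, GenomicRanges::GRanges("chr1",
        IRanges::IRanges(9001, 11000), strand = "+"))
    cur <- curateCatalog(cand, ann)
    expect_identical(locusIds(cur),
                     c("chr1:7000-7100", "chr1:8599-8699"))
    expect_identical(cur$annotation, c("intronic", "promoter"))
    excl <- S4Vectors::metadata(cur)$exclusions
    expect_identical(
        excl$reason[match(c("chr1:1000-1100", "chr1:3000-3100",
                            "chr1:5000-5100", "chr1:12000-12100",
                            "chrX:1000-1100"), excl$locus_id)],
        c("motif", "repeat_element", "segdup", "proximity",
          "chromosome"))
    # idempotence and subset property
    cur2 <- curateCatalog(cur, ann)
    expect_identical(locusIds(cur2), locusIds(cur))
    expect_true(all(locusIds(cur) %in% locusIds(cand)))
    # chrX survives when autosomesOnly is off (it overlaps a gene)
    curX <- curateCatalog(cand, ann, autosomesOnly = FALSE)
    expect_true("chrX:1000-1100" %in% locusIds(curX))
})

test_that("promoter windows are strand-aware and annotation precedence holds", {
    loci <- VntrCatalog(GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1400, 5100, 8001, 9100), width = 100),
        motif = "ACGTGG"))
    # minus-strand gene with TSS at its end (5000): upstream window is
    # (5000, 5500], hit by locus 2's end at 5200
    ann <- VntrAnnotation(genes = GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(2000, 3000, 8000, 9000),
                         c(2500, 5000, 8500, 9600)),
        strand = c("+", "-", "+", "+")),
        exons = GenomicRanges::GRanges("chr1",
            IRanges::IRanges(c(8000, 9000), c(8500, 9150))))
    # locus 1 starts 600 bp before TSS 2000: outside the 500 bp window
    cur <- curateCatalog(loci, ann)
    expect_false("chr1:1399-1499" %in% locusIds(cur))
    expect_true("chr1:5099-5199" %in% locusIds(cur))
    expect_identical(cur$annotation[locusIds(cur) == "chr1:5099-5199"],
                     "promoter")
    # locus 3 lies fully in an exon; locus 4 spans exon and intron
    expect_identical(cur$annotation[locusIds(cur) == "chr1:8000-8100"],
                     "exonic")
    expect_identical(cur$annotation[locusIds(cur) == "chr1:9099-9199"],
                     "multiple")
    # a wider window rescues locus 1
    cur2 <- curateCatalog(loci, ann, tssFlank = 700L)
    expect_true("chr1:1399-1499" %in% locusIds(cur2))
})

test_that("GC content counts G/C over the flanked window, N excluded", {
    ref <- Biostrings::DNAStringSet(c(
        chr1 = "AAAAAAAAAA", chr2 = "GCGC", chr3 = "AATTGGCC",
        chr4 = "NNNNNNNN", chr5 = "ANGC"))
    gr <- function(ch, s, e) GenomicRanges::GRanges(ch,
        IRanges::IRanges(s, e), motif = "ACGTGG")
    expect_equal(gcContent(VntrCatalog(gr("chr1", 3, 8)), ref,
                           flank = 0), 0)
    expect_equal(gcContent(VntrCatalog(gr("chr2", 1, 4)), ref,
                           flank = 0), 1)
    expect_equal(gcContent(VntrCatalog(gr("chr3", 1, 8)), ref,
                           flank = 0), 0.5)
    # all-N window is undefined, not zero
    expect_true(is.na(gcContent(VntrCatalog(gr("chr4", 1, 8)), ref,
                                flank = 0)))
    # N excluded from the denominator: G,C of {A,G,C} = 2/3
    expect_equal(gcContent(VntrCatalog(gr("chr5", 1, 4)), ref,
                           flank = 0), 2 / 3)
    # flanks extend the window and truncate at contig edges
    expect_equal(gcContent(VntrCatalog(gr("chr3", 4, 5)), ref,
                           flank = 100), 0.5)
    expect_error(gcContent(VntrCatalog(gr("chr9", 1, 5)), ref),
                 "absent")
})

test_that("GC content is invariant under reverse complement", {
    set.seed(5)
    for (i in 1:10) {
        s <- paste(sample(c("A", "C", "G", "T", "N"), 60, TRUE,
                          prob = c(.3, .2, .2, .25, .05)), collapse = "")
        fwd <- Biostrings::DNAStringSet(c(chr1 = s))
        rev <- Biostrings::DNAStringSet(c(chr1 = as.character(
            Biostrings::reverseComplement(Biostrings::DNAString(s)))))
        g <- VntrCatalog(GenomicRanges::GRanges("chr1",
            IRanges::IRanges(1, 60), motif = "ACGTGG"))
        expect_equal(gcContent(g, fwd, flank = 0),
                     gcContent(g, rev, flank = 0))
    }
})

test_that("curated catalogs round-trip through the TSV writer", {
    cat <- VntrCatalog(GenomicRanges::GRanges("chr1",
        IRanges::IRanges(1001, 1100), motif = "ACGTGG"))
    S4Vectors::metadata(cat)$exclusions <-
        data.frame(locus_id = "x", reason = "motif")
    p <- tempfile(fileext = ".tsv")
    writeCatalog(cat, p)
    back <- read.table(p, header = TRUE, sep = "\t")
    expect_identical(back$start, 1000L)   # BED convention on disk
    expect_identical(back$motif, "ACGTGG")
    expect_true(file.exists(sub("\\.tsv$", ".exclusions.tsv", p)))
})
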