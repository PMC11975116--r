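test_that("spanning requires strict containment with flank on both sides", {
    reads <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        c(991, 1001, 1051, 1000, 991), c(1210, 1210, 1150, 1201, 1200)))
    locus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1200))
    expect_identical(isSpanning(reads, locus),
                     c(TRUE, FALSE, FALSE, TRUE, FALSE))
    # wrong chromosome never spans
    off <- GenomicRanges::GRanges("chr2", IRanges::IRanges(900, 1400))
    expect_false(isSpanning(off, locus))
})

test_that("reliability needs 10 bp flanks at 95% identity on each side", {
    tl <- make_test_locus(motif = "ACGTGG", copies = 8, flank = 100)
    aStart <- tl$aStart; aEnd <- tl$aEnd
    perfect <- ref_substr(tl$reference, aStart - 10, aEnd + 10)
    mism <- perfect
    substr(mism, 5, 5) <- chartr("ACGT", "CAGT",
                                 substr(mism, 5, 5))  # 1 error in left flank
    recs <- data.frame(
        qname = c("ok", "short_left", "one_mismatch"),
        rname = "chr1",
        pos = c(aStart - 10L, aStart - 9L, aStart - 10L),
        cigar = c(sprintf("%dM", nchar(perfect)),
                  sprintf("%dM", nchar(perfect) - 1L),
                  sprintf("%dM", nchar(perfect))),
        seq = c(perfect, substr(perfect, 2, nchar(perfect)), mism))
    sam <- write_test_sam(recs, tl$reference)
    gal <- vntrspan:::.readAlignments(sam)
    rel <- isReliable(gal, tl$locus, tl$reference)
    expect_identical(setNames(rel, NULL)[match(c("ok", "short_left",
        "one_mismatch"), names(gal))], c(TRUE, FALSE, FALSE))
    # with a longer available flank the same single error is tolerated
    long <- ref_substr(tl$reference, aStart - 40, aEnd + 40)
    substr(long, 5, 5) <- chartr("ACGT", "CAGT", substr(long, 5, 5))
    sam2 <- write_test_sam(data.frame(qname = "long", rname = "chr1",
        pos = aStart - 40L, cigar = sprintf("%dM", nchar(long)),
        seq = long), tl$reference)
    expect_true(isReliable(vntrspan:::.readAlignments(sam2), tl$locus,
                           tl$reference))
})

test_that("spanning counts agree with an all-pairs brute-force oracle", {
    p <- SimulationParams(seed = 21, nLoci = 10, nSamples = 1,
                          depth = 15, substitutionRate = 0)
    co <- suppressWarnings(simulateCohort(p, tempfile("oracle")))
    cov <- countSpanning(co$samFiles, co$catalog, co$reference)
    gal <- vntrspan:::.readAlignments(co$samFiles[[1]])
    # oracle: test every read against every locus
    want <- vapply(seq_along(co$catalog), function(i) {
        l <- co$catalog[i]
        sum(as.character(GenomicRanges::seqnames(gal)) ==
                as.character(GenomicRanges::seqnames(l)) &
            GenomicRanges::start(gal) < GenomicRanges::start(l) &
            GenomicRanges::end(gal) > GenomicRanges::end(l))
    }, integer(1))
    expect_identical(unname(spanningCounts(cov)[, 1]), want)
    # reliability never exceeds spanning
    expect_true(all(reliableCounts(cov) <= spanningCounts(cov)))
    # support tallies sum to the reliable counts
    sup <- repeatSupport(cov)
    agg <- tapply(sup$n_reads, sup$locus_id, sum)
    rel <- reliableCounts(cov)[, 1]
    expect_equal(as.vector(agg[names(rel)[rel > 0]]),
                 unname(rel[rel > 0]))
})

test_that("probe distance is the gap to the nearest probe interval", {
    cat <- GenomicRanges::GRanges(c("chr1", "chr1", "chr2"),
        IRanges::IRanges(c(1001, 5001, 1001), width = 100))
    probes <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(501, 1050), c(750, 1169)))
    d <- probeDistance(cat, probes)
    expect_identical(d[1], 0L)          # overlapping probe
    # nearest probe ends at 1169; gap to locus start 5001 = 3831
    expect_identical(d[2], 3831L)
    expect_true(is.na(d[3]))            # no probe on chr2
    expect_true(all(is.na(probeDistance(cat, GenomicRanges::GRanges()))))
    # spec-style example: probe ending 250 bp before the locus start
    d2 <- probeDistance(
        GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1100)),
        GenomicRanges::GRanges("chr1", IRanges::IRanges(501, 750)))
    expect_identical(d2, 250L)
})

test_that("coverage tiers and projected variance follow the thresholds", {
    m <- rbind(a = c(20, 20, 20, 20), b = c(100, 80, 70, 90),
               c = c(0, 0, 0, 0), d = c(5, 8, 2, 40), e = c(63, 63, 70, 63))
    cl <- classifyCoverage(m)
    expect_identical(as.character(cl$tier),
        c("well_covered", "high", "uncovered", "low", "high"))
    expect_equal(cl$cross_sample_variance[1], 0)   # constant counts
    expect_equal(cl$cross_sample_variance[2], 0)   # all project to 30
    expect_equal(cl$median_spanning[4], 6.5)       # even-sample median
    # projection: d -> (5, 8, 2, 30), population variance
    v <- c(5, 8, 2, 30)
    expect_equal(cl$cross_sample_variance[4], mean((v - mean(v))^2))
    # permutation invariance across samples
    cl2 <- classifyCoverage(m[, c(3, 1, 4, 2)])
    expect_equal(cl2$median_spanning, cl$median_spanning)
    expect_identical(cl2$tier, cl$tier)
    expect_error(classifyCoverage(m[, 0, drop = FALSE]), "sample")
})

test_that("per-million normalization scales by total mapped reads", {
    expect_equal(normalizePerMillion(15, 1e6), 15)
    expect_equal(normalizePerMillion(0, 123), 0)
    expect_equal(normalizePerMillion(4, 2e6), 2)
    m <- cbind(s1 = c(10, 0), s2 = c(3, 6))
    expect_equal(normalizePerMillion(m, c(1e6, 3e6)),
                 cbind(s1 = c(10, 0), s2 = c(1, 2)))
    expect_error(normalizePerMillion(5, 0), "positive")
})

test_that("on-target efficiency is the fraction of reads hitting a locus", {
    cat <- VntrCatalog(GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1001, 5001), width = 200), motif = "ACGTGG"))
    # 36 of 100 reads overlap a locus
    hit <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(seq(900, by = 2, length.out = 36), width = 150))
    miss <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(seq(2000, by = 10, length.out = 64), width = 100))
    expect_equal(spanningEfficiency(c(hit, miss), cat), 0.36)
    expect_equal(spanningEfficiency(hit, cat), 1)
    expect_equal(spanningEfficiency(miss, cat), 0)
})

test_that("coverage objects expose counts, support and totals", {
    p <- SimulationParams(seed = 22, nLoci = 4, nSamples = 2, depth = 12,
                          substitutionRate = 0)
    co <- suppressWarnings(simulateCohort(p, tempfile("acc")))
    cov <- countSpanning(co$samFiles, co$catalog, co$reference)
    expect_s4_class(cov, "VntrCoverage")
    expect_identical(dim(cov), c(4L, 2L))
    expect_identical(colnames(spanningCounts(cov)), co$samples)
    expect_true(all(totalMapped(cov) > 0))
    pm <- normalizePerMillion(cov)
    expect_equal(pm[, 1],
                 spanningCounts(cov)[, 1] * 1e6 / totalMapped(cov)[1])
})
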