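test_that("simulation is bit-reproducible under a fixed seed", {
    p <- SimulationParams(seed = 5, nLoci = 6, nSamples = 1, nTrios = 1,
                          depth = 10)
    d1 <- tempfile("rep1"); d2 <- tempfile("rep2")
    c1 <- suppressWarnings(simulateCohort(p, d1))
    c2 <- suppressWarnings(simulateCohort(p, d2))
    expect_identical(as.character(c1$reference),
                     as.character(c2$reference))
    expect_identical(c1$genotypes, c2$genotypes)
    expect_identical(c1$sidecar, c2$sidecar)
    for (s in names(c1$samFiles))
        expect_identical(readLines(c1$samFiles[[s]]),
                         readLines(c2$samFiles[[s]]))
    # a different seed changes the draws but not the structure
    c3 <- suppressWarnings(simulateCohort(
        SimulationParams(seed = 6, nLoci = 6, nSamples = 1, nTrios = 1,
                         depth = 10), tempfile("rep3")))
    expect_false(identical(c1$genotypes$hap1, c3$genotypes$hap1))
    expect_identical(dim(c1$genotypes), dim(c3$genotypes))
})

test_that("planted catalog geometry matches its BED and truth records", {
    p <- SimulationParams(seed = 8, nLoci = 10)
    sim <- simulateReference(p, dir = tempfile("refout"))
    cat <- sim$catalog
    # array length = motif length x repeat count, and the reference
    # really contains the array at the recorded coordinates
    expect_identical(refArrayLength(cat),
                     cat$motif_length * sim$locusInfo$ref_count)
    i <- 3
    arr <- substr(as.character(sim$reference[[sim$locusInfo$chrom[i]]]),
                  sim$locusInfo$array_start[i],
                  sim$locusInfo$array_end[i])
    expect_identical(arr, strrep(sim$locusInfo$motif[i],
                                 sim$locusInfo$ref_count[i]))
    # files round-trip through the package readers
    back <- readTandemRepeats(sim$files$catalog, "bed")
    expect_identical(GenomicRanges::start(back),
                     GenomicRanges::start(cat))
    expect_identical(motifs(back), motifs(cat))
})

test_that("decoy loci are planted to fail curation by construction", {
    p <- SimulationParams(seed = 12, nLoci = 6, nSegdupDecoys = 2,
                          nLineDecoys = 2, nChrX = 1)
    sim <- simulateReference(p)
    cur <- suppressWarnings(curateCatalog(sim$catalog, sim$annotation))
    expect_length(cur, 6L)
    excl <- S4Vectors::metadata(cur)$exclusions
    expect_identical(as.integer(table(excl$reason)[c("segdup",
        "repeat_element", "chromosome")]), c(2L, 2L, 1L))
})

test_that("trio children inherit one allele from each parent", {
    p <- SimulationParams(seed = 13, nLoci = 30, nSamples = 0,
                          nTrios = 2, nonpolymorphicFraction = 0.3)
    sim <- simulateReference(p)
    ind <- simulateIndividuals(p, sim)
    g <- split(ind$genotypes, ind$genotypes$sample_id)
    for (t in seq_len(nrow(ind$ped))) {
        ch <- g[[ind$ped$child[t]]]
        mo <- g[[ind$ped$mother[t]]]
        fa <- g[[ind$ped$father[t]]]
        expect_true(all(ch$hap1 == mo$hap1 | ch$hap1 == mo$hap2))
        expect_true(all(ch$hap2 == fa$hap1 | ch$hap2 == fa$hap2))
    }
    # fully non-polymorphic cohorts are homozygous reference everywhere
    p2 <- SimulationParams(seed = 13, nLoci = 10, nSamples = 2,
                           nonpolymorphicFraction = 1)
    ind2 <- simulateIndividuals(p2, sim <- simulateReference(p2))
    expect_true(all(ind2$genotypes$hap1 == ind2$genotypes$hap2))
    ref <- sim$locusInfo$ref_count[match(ind2$genotypes$locus_id,
                                         sim$locusInfo$locus_id)]
    expect_true(all(ind2$genotypes$hap1 == ref))
})

test_that("a de-novo knob plants non-parental child alleles", {
    p <- SimulationParams(seed = 14, nLoci = 200, nSamples = 0,
                          nTrios = 1, denovoRate = 0.5,
                          nonpolymorphicFraction = 0.5)
    sim <- simulateReference(p)
    ind <- simulateIndividuals(p, sim)
    g <- split(ind$genotypes, ind$genotypes$sample_id)
    ch <- g[[ind$ped$child[1]]]; mo <- g[[ind$ped$mother[1]]]
    fa <- g[[ind$ped$father[1]]]
    bad <- vapply(seq_len(nrow(ch)), function(i)
        !oracle_mendelian(c(ch$hap1[i], ch$hap2[i]),
                          c(mo$hap1[i], mo$hap2[i]),
                          c(fa$hap1[i], fa$hap2[i])), logical(1))
    # about half the loci must carry a de novo allele
    expect_gt(mean(bad), 0.35)
    expect_lt(mean(bad), 0.65)
})

test_that("error-free reads reproduce the truth sidecar exactly", {
    p <- SimulationParams(seed = 15, nLoci = 8, nSamples = 2, depth = 16,
                          substitutionRate = 0)
    co <- suppressWarnings(simulateCohort(p, tempfile("exact")))
    cov <- countSpanning(co$samFiles, co$catalog, co$reference)
    sc <- co$sidecar
    truth <- with(sc[sc$spanning, ],
        table(factor(locus_id, levels = rownames(cov)),
              factor(sample_id, levels = colnames(cov))))
    expect_identical(unname(spanningCounts(cov)),
                     matrix(as.integer(truth), nrow = nrow(cov)))
    # with no substitutions, every spanning read with adequate flanks
    # is reliable: relaxing the flank to 1 bp removes the only gap
    cov1 <- countSpanning(co$samFiles, co$catalog, co$reference,
                          minFlank = 1L)
    expect_identical(reliableCounts(cov1), spanningCounts(cov1))
})

test_that("targeted dropout depresses high-GC and probe-distant loci", {
    p <- SimulationParams(seed = 16, nLoci = 20, nSamples = 1,
                          depth = 24, substitutionRate = 0)
    sim <- simulateReference(p)
    ind <- simulateIndividuals(p, sim)
    rd <- simulateReads(p, sim, ind, tempfile("bias"))
    sc <- rd$sidecar
    spn <- table(factor(sc$locus_id[sc$spanning],
                        levels = sim$locusInfo$locus_id))
    hi <- sim$locusInfo$gc_target >= 0.60
    expect_lt(mean(spn[hi]), mean(spn[!hi]))
    # bias off restores uniform expected depth
    p0 <- SimulationParams(seed = 16, nLoci = 20, nSamples = 1,
                           depth = 24, substitutionRate = 0,
                           gcSlope = 0, pdSlope = 0)
    rd0 <- simulateReads(p0, sim, ind, tempfile("flat"))
    sc0 <- rd0$sidecar
    spn0 <- table(factor(sc0$locus_id[sc0$spanning],
                         levels = sim$locusInfo$locus_id))
    expect_gt(mean(spn0[hi]), 0.5 * mean(spn0[!hi]))
})
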