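## Random DNA of length n with expected GC fraction g.
.randSeq <- function(n, g) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)),
          collapse = "")
}

#' Simulate a reference genome with planted VNTR loci
#'
#' Builds one or more synthetic contigs in which each VNTR locus occupies
#' its own neighborhood: unique random flanks around a perfect tandem
#' array (motif repeated the reference repeat count). Flank and motif GC
#' are driven per locus by \code{gcLevels}, so the catalog populates both
#' sides of the capture-bias GC knee. A capture probe is placed at the
#' per-locus distance given by \code{probeDistances}. Decoy loci planted
#' inside labeled segmental-duplication or LINE intervals, and loci on
#' chrX, exercise the curation filters; all other loci receive a covering
#' gene body so they survive curation as intronic.
#'
#' @param params A \code{\link{SimulationParams}}.
#' @param dir Optional directory; when given, writes
#'   \code{reference.fa} (+ \code{.fai}), \code{catalog.bed},
#'   \code{probes.bed}, \code{genes.bed}, \code{line.bed},
#'   \code{segdup.bed} and \code{params.json}.
#'
#' @return A list: \code{reference} (named \code{DNAStringSet}),
#'   \code{catalog} (\code{\link{VntrCatalog}} of all planted candidates,
#'   decoys included), \code{annotation} (\code{\link{VntrAnnotation}}),
#'   \code{probes} (\code{GRanges}), \code{locusInfo} (per-locus truth:
#'   GC target, probe distance, decoy class) and, when \code{dir} is
#'   given, \code{files}.
#'
#' @examples
#' sim <- simulateReference(SimulationParams(seed = 1, nLoci = 5))
#' sim$catalog
#' @export
simulateReference <- function(params, dir = NULL) {
    stopifnot(methods::is(params, "SimulationParams"))
    set.seed(params@seed)
    p <- params
    nMain <- p@nLoci
    decoy <- c(rep("none", nMain), rep("segdup", p@nSegdupDecoys),
               rep("line", p@nLineDecoys), rep("chrx", p@nChrX))
    nAll <- length(decoy)
    chrom <- ifelse(decoy == "chrx", "chrX", "chr1")
    gc <- rep_len(p@gcLevels, nAll)
    pd <- rep_len(p@probeDistances, nAll)
    mlen <- sample(seq(p@motifLengthRange[1], p@motifLengthRange[2]),
                   nAll, replace = TRUE)
    rcount <- sample(seq(p@repeatCountRange[1], p@repeatCountRange[2]),
                     nAll, replace = TRUE)
    motif <- vapply(seq_len(nAll), function(i)
        .randSeq(mlen[i], gc[i]), character(1))
    F <- p@flankLen
    spacer <- 200L + as.integer(max(0, max(pd)))
    leftPad <- pmax(F, as.integer(pd) + 140L)
    info <- data.frame(chrom = chrom, gc_target = gc, probe_dist = pd,
                       motif = motif, ref_count = rcount, decoy = decoy,
                       array_start = NA_integer_, array_end = NA_integer_)
    seqs <- list(chr1 = character(0), chrX = character(0))
    cursor <- c(chr1 = 0L, chrX = 0L)
    probes <- list(); genes <- list(); segdups <- list(); lines <- list()
    lv <- unique(chrom)
    for (i in seq_len(nAll)) {
        ch <- chrom[i]
        chf <- factor(ch, levels = lv)
        arr <- strrep(motif[i], rcount[i])
        La <- nchar(arr)
        block <- paste0(.randSeq(leftPad[i], gc[i]), arr,
                        .randSeq(F, gc[i]), .randSeq(spacer, 0.5))
        aStart <- cursor[[ch]] + leftPad[i] + 1L
        aEnd <- aStart + La - 1L
        info$array_start[i] <- aStart
        info$array_end[i] <- aEnd
        seqs[[ch]] <- c(seqs[[ch]], block)
        cursor[[ch]] <- cursor[[ch]] + nchar(block)
        if (decoy[i] == "none") {
            pe <- if (pd[i] == 0) aStart + 60L else aStart - pd[i] - 1L
            probes[[length(probes) + 1L]] <- GenomicRanges::GRanges(chf,
                IRanges::IRanges(max(1L, pe - 119L), pe))
        }
        genes[[length(genes) + 1L]] <- GenomicRanges::GRanges(chf,
            IRanges::IRanges(max(1L, aStart - 300L), aEnd + 300L),
            strand = "+")
        if (decoy[i] == "segdup")
            segdups[[length(segdups) + 1L]] <- GenomicRanges::GRanges(chf,
                IRanges::IRanges(max(1L, aStart - 50L), aEnd + 50L))
        if (decoy[i] == "line")
            lines[[length(lines) + 1L]] <- GenomicRanges::GRanges(chf,
                IRanges::IRanges(max(1L, aStart - 50L), aEnd + 50L))
    }
    contigs <- vapply(seqs, paste, character(1), collapse = "")
    contigs <- contigs[nchar(contigs) > 0]
    reference <- Biostrings::DNAStringSet(contigs)
    cat0 <- GenomicRanges::GRanges(factor(info$chrom, levels = lv),
        IRanges::IRanges(info$array_start, info$array_end),
        motif = info$motif)
    catalog <- VntrCatalog(cat0)
    info$locus_id <- locusIds(catalog)
    bindGR <- function(x) if (length(x)) do.call(c, x)
        else GenomicRanges::GRanges()
    probes <- bindGR(probes)
    ann <- VntrAnnotation(genes = bindGR(genes),
                          excludedRepeats = bindGR(lines),
                          segdups = bindGR(segdups))
    out <- list(reference = reference, catalog = catalog,
                annotation = ann, probes = probes, locusInfo = info)
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        fa <- file.path(dir, "reference.fa")
        Biostrings::writeXStringSet(reference, fa)
        Rsamtools::indexFa(fa)
        bed <- function(gr, path, extra = NULL) {
            df <- data.frame(chrom = as.character(
                    GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr) - 1L,
                end = GenomicRanges::end(gr))
            if (!is.null(extra)) df <- cbind(df, extra)
            write.table(df, path, sep = "\t", quote = FALSE,
                        row.names = FALSE, col.names = FALSE)
            path
        }
        files <- list(reference = fa,
            catalog = bed(catalog, file.path(dir, "catalog.bed"),
                data.frame(motif = motifs(catalog),
                           name = locusIds(catalog))),
            probes = bed(probes, file.path(dir, "probes.bed")),
            genes = bed(ann@genes, file.path(dir, "genes.bed"),
                data.frame(name = ".", score = 0L,
                    strand = as.character(
                        BiocGenerics::strand(ann@genes)))),
            line = bed(ann@excludedRepeats, file.path(dir, "line.bed")),
            segdup = bed(ann@segdups, file.path(dir, "segdup.bed")))
        jsonlite::write_json(.paramsAsList(params),
                             file.path(dir, "params.json"),
                             auto_unbox = TRUE, digits = NA)
        out$files <- files
    }
    out
}

.paramsAsList <- function(p) {
    nm <- methods::slotNames(p)
    setNames(lapply(nm, function(s) methods::slot(p, s)), nm)
}

#' Simulate diploid individuals and trios over a catalog
#'
#' Draws per-sample, per-locus diploid repeat counts. A
#' \code{nonpolymorphicFraction} of loci is fixed at the reference repeat
#' count in every sample; at polymorphic loci founder haplotypes are
#' drawn uniformly from \code{repeatCountRange}. Trio children inherit
#' one allele from each parent uniformly; with probability
#' \code{denovoRate} per child-locus one transmitted allele is replaced
#' by a repeat count absent from both parents.
#'
#' @param params A \code{\link{SimulationParams}}.
#' @param sim Output of \code{\link{simulateReference}} (or any list with
#'   a \code{locusInfo} data.frame).
#' @param dir Optional directory: writes \code{truth_genotypes.tsv} and
#'   \code{trios.ped}.
#'
#' @return A list: \code{genotypes} (data.frame \code{sample_id},
#'   \code{locus_id}, \code{hap1}, \code{hap2}), \code{ped} (data.frame
#'   \code{child}, \code{mother}, \code{father}), \code{samples}
#'   (character), \code{polymorphic} (logical per locus).
#'
#' @examples
#' p <- SimulationParams(seed = 1, nLoci = 5, nSamples = 2, nTrios = 1)
#' sim <- simulateReference(p)
#' ind <- simulateIndividuals(p, sim)
#' head(ind$genotypes)
#' @export
simulateIndividuals <- function(params, sim, dir = NULL) {
    stopifnot(methods::is(params, "SimulationParams"))
    p <- params
    set.seed(p@seed + 1000L)
    info <- sim$locusInfo
    nL <- nrow(info)
    rng <- seq(p@repeatCountRange[1], p@repeatCountRange[2])
    poly <- runif(nL) >= p@nonpolymorphicFraction
    unrel <- if (p@nSamples > 0)
        sprintf("S%02d", seq_len(p@nSamples)) else character(0)
    trioIds <- if (p@nTrios > 0) seq_len(p@nTrios) else integer(0)
    ped <- data.frame(child = sprintf("T%d_child", trioIds),
                      mother = sprintf("T%d_mother", trioIds),
                      father = sprintf("T%d_father", trioIds))
    founders <- c(unrel, ped$mother, ped$father)
    drawHap <- function() ifelse(poly,
        sample(rng, nL, replace = TRUE), info$ref_count)
    gts <- list()
    for (s in founders) {
        gts[[s]] <- data.frame(sample_id = s, locus_id = info$locus_id,
                               hap1 = drawHap(), hap2 = drawHap())
    }
    for (t in seq_len(p@nTrios)) {
        mo <- gts[[ped$mother[t]]]; fa <- gts[[ped$father[t]]]
        pickM <- ifelse(runif(nL) < 0.5, mo$hap1, mo$hap2)
        pickF <- ifelse(runif(nL) < 0.5, fa$hap1, fa$hap2)
        if (p@denovoRate > 0) {
            hit <- runif(nL) < p@denovoRate
            for (i in which(hit)) {
                pool <- setdiff(c(rng, max(rng) + 1:2),
                    c(mo$hap1[i], mo$hap2[i], fa$hap1[i], fa$hap2[i]))
                if (runif(1) < 0.5) pickM[i] <- sample(pool, 1)
                else pickF[i] <- sample(pool, 1)
            }
        }
        gts[[ped$child[t]]] <- data.frame(sample_id = ped$child[t],
            locus_id = info$locus_id, hap1 = pickM, hap2 = pickF)
    }
    genotypes <- do.call(rbind, gts)
    rownames(genotypes) <- NULL
    samples <- c(unrel, ped$child, ped$mother, ped$father)
    out <- list(genotypes = genotypes, ped = ped, samples = samples,
                polymorphic = poly)
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        write.table(genotypes, file.path(dir, "truth_genotypes.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(ped, file.path(dir, "trios.ped"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        out$files <- list(
            genotypes = file.path(dir, "truth_genotypes.tsv"),
            ped = file.path(dir, "trios.ped"))
    }
    out
}

## Expected-depth multiplier of the targeted-capture dropout model.
.dropout <- function(p, gc, pd) {
    if (p@mode == "wgs") return(rep(1, length(gc)))
    # a zero slope switches the corresponding bias component off
    fgc <- if (p@gcSlope == 0) rep(1, length(gc))
        else 1 / (1 + exp(p@gcSlope * (gc - p@gcKnee)))
    fpd <- if (p@pdSlope == 0) rep(1, length(pd))
        else 1 / (1 + exp(p@pdSlope * (pd - p@pdKnee)))
    p@dropoutFloor + (1 - p@dropoutFloor) * fgc * fpd
}

## Alignment of a haplotype-local read [s, e] against the reference.
## Local layout: flank F | array of La bases (reference array Lr) | flank.
## Returns list(refStart, cigar) or NULL when the read has no aligned
## base (entirely inside an expanded-array insertion).
.hapAlignment <- function(s, e, F, La, Lr, arrayStart) {
    mmin <- min(La, Lr)
    ops <- character(0); lens <- integer(0)
    add <- function(op, len) {
        if (len <= 0L) return()
        k <- length(ops)
        if (k && ops[k] == op) lens[k] <<- lens[k] + len
        else { ops[k + 1L] <<- op; lens[k + 1L] <<- len }
    }
    oA <- c(max(s, 1L), min(e, F + mmin))
    oB <- c(max(s, F + mmin + 1L), min(e, F + La))       # insertion
    oC <- c(max(s, F + La + 1L), min(e, .Machine$integer.max))
    hasA <- oA[2] >= oA[1]; hasB <- La > Lr && oB[2] >= oB[1]
    hasC <- oC[2] >= oC[1]
    if (!hasA && !hasC) return(NULL)
    if (hasA) add("M", oA[2] - oA[1] + 1L)
    if (hasB) add("I", oB[2] - oB[1] + 1L)
    if (Lr > La && hasA && hasC) add("D", Lr - La)
    if (hasC) add("M", oC[2] - oC[1] + 1L)
    if (ops[1] == "I") ops[1] <- "S"
    if (ops[length(ops)] == "I") ops[length(ops)] <- "S"
    refStart <- if (hasA) arrayStart - F + oA[1] - 1L
        else arrayStart + Lr + (oC[1] - (F + La + 1L))
    list(refStart = refStart,
         cigar = paste0(lens, ops, collapse = ""))
}

.substitute <- function(seq, rate) {
    if (rate <= 0) return(seq)
    n <- nchar(seq)
    k <- rbinom(1, n, rate)
    if (k == 0) return(seq)
    pos <- sample.int(n, k)
    ch <- strsplit(seq, "")[[1]]
    for (j in pos) {
        ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
    }
    paste(ch, collapse = "")
}

#' Simulate aligned read sets with known truth
#'
#' Emits one plain SAM file per sample, with reads pre-aligned at their
#' true coordinates (truth CIGARs; repeat-count differences between a
#' haplotype and the reference appear as a single insertion or deletion
#' at the array's 3' end). In targeted mode the expected reads per locus
#' are thinned by the logistic GC/probe-distance dropout model; in wgs
#' mode sampling is uniform. Read lengths follow a log-normal truncated
#' to the per-locus neighborhood. Substitution errors are planted at
#' \code{substitutionRate}; a truth sidecar records every read's sample,
#' locus, haplotype, allele and spanning status.
#'
#' @param params A \code{\link{SimulationParams}}.
#' @param sim Output of \code{\link{simulateReference}}.
#' @param individuals Output of \code{\link{simulateIndividuals}}.
#' @param dir Directory for the SAM files and \code{truth_reads.tsv}.
#'
#' @return A list: \code{samFiles} (named character vector, one SAM per
#'   sample) and \code{sidecar} (data.frame of per-read truth).
#'
#' @examples
#' p <- SimulationParams(seed = 1, nLoci = 3, nSamples = 1, depth = 10,
#'                       substitutionRate = 0)
#' sim <- simulateReference(p)
#' ind <- simulateIndividuals(p, sim)
#' rd <- simulateReads(p, sim, ind, tempfile("reads"))
#' @export
simulateReads <- function(params, sim, individuals, dir) {
    stopifnot(methods::is(params, "SimulationParams"))
    p <- params
    set.seed(p@seed + 2000L)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    info <- sim$locusInfo
    refChars <- lapply(as.character(sim$reference), function(x)
        x)  # plain character contigs
    contigLens <- setNames(nchar(unlist(refChars)), names(refChars))
    F <- p@flankLen
    gtBySample <- split(individuals$genotypes,
                        individuals$genotypes$sample_id)
    samFiles <- character(0)
    sidecar <- list()
    for (s in individuals$samples) {
        gt <- gtBySample[[s]]
        gt <- gt[match(info$locus_id, gt$locus_id), ]
        recs <- list()
        for (i in seq_len(nrow(info))) {
            ch <- info$chrom[i]
            aStart <- info$array_start[i]
            aEnd <- info$array_end[i]
            m <- nchar(info$motif[i])
            Lr <- aEnd - aStart + 1L
            flankL <- substr(refChars[[ch]], aStart - F, aStart - 1L)
            flankR <- substr(refChars[[ch]], aEnd + 1L, aEnd + F)
            mult <- .dropout(p, info$gc_target[i], info$probe_dist[i])
            for (h in 1:2) {
                a <- if (h == 1) gt$hap1[i] else gt$hap2[i]
                La <- a * m
                hapSeq <- paste0(flankL, strrep(info$motif[i], a),
                                 flankR)
                localLen <- nchar(hapSeq)
                n <- rpois(1, p@depth / 2 * mult)
                if (n == 0) next
                for (r in seq_len(n)) {
                    L <- as.integer(round(rlnorm(1,
                        log(p@readLengthMedian), p@readLengthSdlog)))
                    L <- max(200L, min(L, localLen))
                    sLow <- max(1L, F + 1L - L + 1L)
                    sPos <- sLow + sample.int(F + La - sLow + 1L, 1) - 1L
                    ePos <- min(sPos + L - 1L, localLen)
                    aln <- .hapAlignment(sPos, ePos, F, La, Lr, aStart)
                    if (is.null(aln)) next
                    spanning <- sPos <= F && ePos >= F + La + 1L
                    seq <- .substitute(substr(hapSeq, sPos, ePos),
                                       p@substitutionRate)
                    qn <- sprintf("%s_%s_h%d_r%d", s, info$locus_id[i],
                                  h, r)
                    recs[[length(recs) + 1L]] <- data.frame(qname = qn,
                        rname = ch, pos = aln$refStart,
                        cigar = aln$cigar, seq = seq)
                    sidecar[[length(sidecar) + 1L]] <- data.frame(
                        read_id = qn, sample_id = s,
                        locus_id = info$locus_id[i], haplotype = h,
                        allele = a, spanning = spanning)
                }
            }
            if (p@offTargetRate > 0) {
                n2 <- rpois(1, p@offTargetRate)
                for (r in seq_len(n2)) {
                    L <- min(500L, F - 2L)
                    sPos <- sample.int(F - L, 1)
                    refStart <- aStart - F + sPos - 1L
                    seq <- .substitute(substr(refChars[[ch]], refStart,
                        refStart + L - 1L), p@substitutionRate)
                    qn <- sprintf("%s_%s_ot_r%d", s, info$locus_id[i], r)
                    recs[[length(recs) + 1L]] <- data.frame(qname = qn,
                        rname = ch, pos = refStart,
                        cigar = paste0(L, "M"), seq = seq)
                    sidecar[[length(sidecar) + 1L]] <- data.frame(
                        read_id = qn, sample_id = s,
                        locus_id = info$locus_id[i], haplotype = NA,
                        allele = NA, spanning = FALSE)
                }
            }
        }
        recs <- do.call(rbind, recs)
        path <- file.path(dir, paste0(s, ".sam"))
        .writeSam(recs, contigLens, path)
        samFiles[[s]] <- path
    }
    sidecar <- do.call(rbind, sidecar)
    rownames(sidecar) <- NULL
    write.table(sidecar, file.path(dir, "truth_reads.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(samFiles = samFiles, sidecar = sidecar)
}

.writeSam <- function(recs, contigLens, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("@HD\tVN:1.6\tSO:coordinate", con)
    for (ch in names(contigLens))
        writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch,
                           as.integer(contigLens[[ch]])), con)
    if (is.null(recs) || nrow(recs) == 0L) return(invisible(path))
    recs <- recs[order(recs$rname, recs$pos), ]
    writeLines(sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
        recs$qname, recs$rname, recs$pos, recs$cigar, recs$seq), con)
    invisible(path)
}

#' Run the full synthetic-cohort generator
#'
#' Convenience wrapper: \code{\link{simulateReference}},
#' \code{\link{simulateIndividuals}} and \code{\link{simulateReads}} in
#' sequence, writing all artifacts under \code{dir}.
#'
#' @param params A \code{\link{SimulationParams}}.
#' @param dir Output directory.
#' @return Combined list of all three stages' outputs.
#' @examples
#' \donttest{
#' cohort <- simulateCohort(SimulationParams(seed = 1, nLoci = 4,
#'     nSamples = 1, depth = 10), tempfile("cohort"))
#' }
#' @export
simulateCohort <- function(params, dir) {
    sim <- simulateReference(params, dir = dir)
    ind <- simulateIndividuals(params, sim, dir = dir)
    rd <- simulateReads(params, sim, ind, dir = dir)
    c(sim, ind, rd, list(params = params, dir = dir))
}
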