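#' Call a diploid repeat-count genotype from reliable-read support
#'
#' Implements the accuracy filter and the diploid call rule: repeat counts
#' supported by fewer than \code{minSupport} reliable reads are discarded;
#' if none survive the locus is a no-call, if one survives the call is
#' homozygous, otherwise the two best-supported counts are called
#' heterozygous (support ties broken toward the smaller repeat count).
#'
#' @param support Named integer vector: names are repeat counts, values
#'   the number of reliable reads supporting each count.
#' @param minSupport Minimum reliable reads per called allele.
#'
#' @return Integer vector of length 2, sorted (equal values = homozygous);
#'   \code{c(NA, NA)} for a no-call.
#'
#' @examples
#' callGenotype(c(`5` = 10, `7` = 8))   # (5, 7)
#' callGenotype(c(`5` = 10, `7` = 2))   # (5, 5): 7 fails the filter
#' callGenotype(c(`9` = 1, `4` = 2))    # no-call
#' @export
callGenotype <- function(support, minSupport = 3L) {
    if (!length(support))
        return(c(NA_integer_, NA_integer_))
    counts <- as.integer(names(support))
    if (anyNA(counts))
        stop("support names must be integer repeat counts")
    keep <- support >= minSupport
    counts <- counts[keep]
    support <- support[keep]
    if (!length(counts))
        return(c(NA_integer_, NA_integer_))
    if (length(counts) == 1L)
        return(c(counts, counts))
    o <- order(-support, counts)
    sort(counts[o][1:2])
}

#' Estimate a read's repeat count at a locus
#'
#' Length-ratio estimator standing in for a full HMM genotyper: the number
#' of read bases aligned between the two flank anchors (the last aligned
#' base before the array and the first aligned base after it) is divided
#' by the motif length and rounded half-away-from-zero. Insertions at
#' either array boundary are counted as array sequence, so the estimator
#' is robust to where the aligner places repeat-count indels.
#'
#' @param gal A \code{GenomicAlignments::GAlignments} of reads spanning
#'   the locus (each must align at least one base on each side).
#' @param locus A length-1 \code{GRanges} (or \code{VntrCatalog} row).
#' @param motifLength Motif length in bp.
#'
#' @return Integer vector of repeat-count estimates, one per read.
#'
#' @examples
#' # a 6-bp motif read carrying 8 perfect copies between 20-bp flanks:
#' # 48 aligned bases / 6 -> 8
#' @export
estimateRepeatCount <- function(gal, locus, motifLength) {
    stopifnot(length(locus) == 1L, motifLength >= 1)
    aStart <- GenomicRanges::start(locus)
    aEnd <- GenomicRanges::end(locus)
    cig <- GenomicAlignments::cigar(gal)
    pos <- GenomicRanges::start(gal)
    vapply(seq_along(gal), function(i) {
        nq <- .queryBasesBetweenAnchors(cig[i], pos[i], aStart, aEnd)
        as.integer(floor(nq / motifLength + 0.5))
    }, integer(1))
}

## Query bases between the flank anchors: bases aligned to reference
## positions in [aStart, aEnd] plus insertions landing in [aStart, aEnd+1]
## (i.e. attached to either array boundary or inside it).
.queryBasesBetweenAnchors <- function(cigar, pos, aStart, aEnd) {
    ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
    lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
    refpos <- pos       # next reference base to be consumed
    nq <- 0L
    for (j in seq_along(ops)) {
        op <- ops[j]; len <- lens[j]
        if (op %in% c("M", "=", "X")) {
            lo <- max(refpos, aStart)
            hi <- min(refpos + len - 1L, aEnd)
            if (hi >= lo) nq <- nq + (hi - lo + 1L)
            refpos <- refpos + len
        } else if (op == "I") {
            if (refpos >= aStart && refpos <= aEnd + 1L)
                nq <- nq + len
        } else if (op %in% c("D", "N")) {
            refpos <- refpos + len
        }
        # S/H/P consume no reference and never lie between the anchors
    }
    nq
}

#' Classify consistency of two genotype calls at a locus
#'
#' Three-level taxonomy for the same sample genotyped from two read sets:
#' \describe{
#'   \item{consistent}{the sorted repeat-count pairs are identical;}
#'   \item{partially_consistent}{the pairs differ, the union of observed
#'     alleles has exactly two unique values, and at least one call is
#'     heterozygous -- e.g. (2,5) vs (2,2), where the homozygous side
#'     plausibly lacked spanning reads for the second allele;}
#'   \item{inconsistent}{anything else -- e.g. (2,5) vs (2,7), or (2,2)
#'     vs (4,4) -- which cannot be explained by missing reads;}
#'   \item{not_comparable}{either call is a no-call.}
#' }
#'
#' @param g1,g2 Integer pairs as returned by \code{\link{callGenotype}}.
#'
#' @return A list with \code{value} (one of the four labels above) and
#'   \code{homozygous_side} (\code{"first"}, \code{"second"},
#'   \code{"both"} or \code{"none"}).
#'
#' @examples
#' classifyConsistency(c(2, 5), c(2, 2))  # partially_consistent, second
#' classifyConsistency(c(2, 5), c(2, 7))  # inconsistent
#' @export
classifyConsistency <- function(g1, g2) {
    g1 <- sort(as.integer(g1), na.last = TRUE)
    g2 <- sort(as.integer(g2), na.last = TRUE)
    stopifnot(length(g1) == 2L, length(g2) == 2L)
    hom1 <- !anyNA(g1) && g1[1] == g1[2]
    hom2 <- !anyNA(g2) && g2[1] == g2[2]
    side <- if (hom1 && hom2) "both" else if (hom1) "first"
            else if (hom2) "second" else "none"
    if (anyNA(g1) || anyNA(g2))
        return(list(value = "not_comparable", homozygous_side = side))
    if (identical(g1, g2))
        return(list(value = "consistent", homozygous_side = side))
    uniq <- unique(c(g1, g2))
    if (length(uniq) == 2L && (!hom1 || !hom2))
        return(list(value = "partially_consistent",
                    homozygous_side = side))
    list(value = "inconsistent", homozygous_side = side)
}

#' Mendelian consistency of a trio of genotype calls
#'
#' A child call (a, b) is Mendelian-consistent when some assignment draws
#' one allele from each parent: a from the mother and b from the father,
#' or vice versa.
#'
#' @param child,mother,father Integer pairs (sorted or not). Any no-call
#'   returns \code{NA} (the locus is excluded from denominators).
#'
#' @return \code{TRUE}, \code{FALSE} or \code{NA}.
#'
#' @examples
#' mendelianConsistent(c(2, 5), c(2, 2), c(5, 7))  # TRUE
#' mendelianConsistent(c(3, 3), c(2, 4), c(3, 5))  # FALSE
#' @export
mendelianConsistent <- function(child, mother, father) {
    if (anyNA(child) || anyNA(mother) || anyNA(father))
        return(NA)
    a <- child[1]; b <- child[2]
    (a %in% mother && b %in% father) || (a %in% father && b %in% mother)
}

.normCalls <- function(calls) {
    stopifnot(all(c("locus_id", "sample_id", "allele1", "allele2") %in%
                  colnames(calls)))
    a <- pmin(calls$allele1, calls$allele2)
    b <- pmax(calls$allele1, calls$allele2)
    data.frame(locus_id = calls$locus_id, sample_id = calls$sample_id,
               allele1 = as.integer(a), allele2 = as.integer(b))
}

#' Summarize genotype consistency between two call tables
#'
#' Joins two genotype tables (same samples genotyped from two read sets)
#' on locus and sample, classifies every comparable pair with
#' \code{\link{classifyConsistency}}, and reports per-sample and pooled
#' fractions plus the homozygous-side breakdown of the partially
#' consistent calls. Loci can be restricted to a catalog, to arrays
#' shorter than \code{maxArrayLength} (short-read mode), and to motifs
#' passing the STR-like filter.
#'
#' @param callsA,callsB Data frames with columns \code{locus_id},
#'   \code{sample_id}, \code{allele1}, \code{allele2} (NA for no-calls).
#' @param catalog Optional \code{\link{VntrCatalog}}: restrict to member
#'   loci (and supply array lengths / motifs for the other filters).
#' @param strlikeCutoff If non-NULL and a catalog is given, drop loci
#'   whose motif \code{\link{strlikeScore}} exceeds the cutoff.
#' @param maxArrayLength If non-NULL and a catalog is given, drop loci
#'   with reference array length >= this many bp.
#'
#' @return A list: \code{per_sample} data.frame of fractions,
#'   \code{pooled} named fractions over all comparable pairs,
#'   \code{n_comparable}, \code{partial_homozygous_side} (fractions of
#'   partial calls homozygous in the first/second table), and the
#'   per-pair \code{verdicts} data.frame.
#'
#' @examples
#' a <- data.frame(locus_id = "L1", sample_id = "S1",
#'                 allele1 = 2L, allele2 = 5L)
#' b <- data.frame(locus_id = "L1", sample_id = "S1",
#'                 allele1 = 2L, allele2 = 2L)
#' consistencySummary(a, b)$pooled
#' @export
consistencySummary <- function(callsA, callsB, catalog = NULL,
                               strlikeCutoff = NULL,
                               maxArrayLength = NULL) {
    a <- .normCalls(callsA); b <- .normCalls(callsB)
    keepLoci <- union(a$locus_id, b$locus_id)
    if (!is.null(catalog)) {
        ids <- locusIds(catalog)
        keep <- rep(TRUE, length(catalog))
        if (!is.null(maxArrayLength))
            keep <- keep & refArrayLength(catalog) < maxArrayLength
        if (!is.null(strlikeCutoff))
            keep <- keep &
                !(strlikeScore(motifs(catalog))$score > strlikeCutoff)
        keepLoci <- intersect(keepLoci, ids[keep])
    }
    a <- a[a$locus_id %in% keepLoci, ]
    b <- b[b$locus_id %in% keepLoci, ]
    m <- merge(a, b, by = c("locus_id", "sample_id"),
               suffixes = c("_a", "_b"))
    if (!nrow(m))
        stop("no shared locus/sample pairs between the two call tables")
    v <- lapply(seq_len(nrow(m)), function(i)
        classifyConsistency(c(m$allele1_a[i], m$allele2_a[i]),
                            c(m$allele1_b[i], m$allele2_b[i])))
    m$verdict <- vapply(v, `[[`, character(1), "value")
    m$homozygous_side <- vapply(v, `[[`, character(1), "homozygous_side")
    comp <- m[m$verdict != "not_comparable", ]
    frac <- function(d) {
        n <- nrow(d)
        c(consistent = sum(d$verdict == "consistent") / n,
          partially_consistent =
              sum(d$verdict == "partially_consistent") / n,
          inconsistent = sum(d$verdict == "inconsistent") / n)
    }
    perSample <- do.call(rbind, lapply(split(comp, comp$sample_id),
        function(d) data.frame(sample_id = d$sample_id[1], n = nrow(d),
                               t(frac(d)))))
    rownames(perSample) <- NULL
    part <- comp[comp$verdict == "partially_consistent", ]
    side <- if (nrow(part))
        c(first = mean(part$homozygous_side == "first"),
          second = mean(part$homozygous_side == "second"))
    else c(first = NA_real_, second = NA_real_)
    list(per_sample = perSample, pooled = frac(comp),
         n_comparable = nrow(comp), partial_homozygous_side = side,
         verdicts = m)
}

#' Summarize Mendelian consistency over trios
#'
#' For each trio, restricts to loci with complete calls in child, mother
#' and father (after the optional catalog / array-length / STR-like
#' filters, as in \code{\link{consistencySummary}}) and reports the
#' fraction of loci where the child genotype is explainable by one allele
#' from each parent.
#'
#' @param calls Genotype table (\code{locus_id}, \code{sample_id},
#'   \code{allele1}, \code{allele2}).
#' @param trios Data frame with columns \code{child}, \code{mother},
#'   \code{father} (sample ids, one trio per row).
#' @inheritParams consistencySummary
#'
#' @return A list: \code{per_trio} data.frame (child id, loci tested,
#'   fraction consistent) and \code{pooled} fraction.
#' @examples
#' calls <- data.frame(locus_id = "L1",
#'     sample_id = c("c", "m", "f"),
#'     allele1 = c(2L, 2L, 5L), allele2 = c(5L, 2L, 7L))
#' trios <- data.frame(child = "c", mother = "m", father = "f")
#' mendelianSummary(calls, trios)$pooled
#' @export
mendelianSummary <- function(calls, trios, catalog = NULL,
                             strlikeCutoff = NULL,
                             maxArrayLength = NULL) {
    g <- .normCalls(calls)
    if (!is.null(catalog)) {
        ids <- locusIds(catalog)
        keep <- rep(TRUE, length(catalog))
        if (!is.null(maxArrayLength))
            keep <- keep & refArrayLength(catalog) < maxArrayLength
        if (!is.null(strlikeCutoff))
            keep <- keep &
                !(strlikeScore(motifs(catalog))$score > strlikeCutoff)
        g <- g[g$locus_id %in% ids[keep], ]
    }
    lookup <- split(g, g$sample_id)
    getGt <- function(sample, locus) {
        d <- lookup[[sample]]
        i <- match(locus, d$locus_id)
        if (is.na(i)) c(NA_integer_, NA_integer_)
        else c(d$allele1[i], d$allele2[i])
    }
    perTrio <- lapply(seq_len(nrow(trios)), function(t) {
        ch <- trios$child[t]; mo <- trios$mother[t]; fa <- trios$father[t]
        loci <- Reduce(intersect, lapply(c(ch, mo, fa), function(s)
            lookup[[s]]$locus_id))
        ok <- vapply(loci, function(l)
            mendelianConsistent(getGt(ch, l), getGt(mo, l),
                                getGt(fa, l)), logical(1))
        ok <- ok[!is.na(ok)]
        data.frame(child = ch, n_loci = length(ok),
                   consistent = if (length(ok)) mean(ok) else NA_real_)
    })
    perTrio <- do.call(rbind, perTrio)
    nTot <- sum(perTrio$n_loci)
    pooled <- if (nTot)
        sum(perTrio$consistent * perTrio$n_loci, na.rm = TRUE) / nTot
    else NA_real_
    list(per_trio = perTrio, pooled = pooled)
}
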