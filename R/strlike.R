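#' Mask budget for the STR-like motif score
#'
#' Number of motif positions that may be masked (turned into wildcards)
#' when searching for an imperfect internal repeat: \code{ceiling(n/10)}
#' for motifs up to 40 bp, and 1 for longer motifs (keeping the search
#' cheap where the subset enumeration would otherwise explode). The
#' \code{"alternate"} rule swaps the two regimes; it exists because the
#' published description of the budget is ambiguous.
#'
#' @param n Positive integer motif length (vectorized).
#' @param rule \code{"default"} or \code{"alternate"}.
#' @return Non-negative integer vector.
#' @examples
#' maskBudget(c(6, 40, 41))   # 1 4 1
#' @export
maskBudget <- function(n, rule = c("default", "alternate")) {
    rule <- match.arg(rule)
    n <- as.integer(n)
    if (any(n < 1)) stop("n must be >= 1")
    if (rule == "default")
        ifelse(n <= 40L, as.integer(ceiling(n / 10)), 1L)
    else
        ifelse(n <= 40L, 1L, as.integer(ceiling(n / 10)))
}

## Minimum residual mismatches between the masked motif and the size-n
## window of the doubled motif at offset `off`, allowing up to k masked
## positions. A mask at position s repairs exactly the mismatches j with
## j == s or ((j-1+off) %% n)+1 == s, so each mask repairs at most two
## mismatches; that bound drives the branch pruning.
.offsetResidual <- function(mism, off, n, k, bestSoFar) {
    d <- length(mism)
    if (d == 0L) return(0L)
    if (k == 0L) return(d)
    partner <- ((mism - 1L + off) %% n) + 1L
    cand <- unique(c(mism, partner))
    # cover sets: which mismatches each candidate mask repairs
    cover <- lapply(cand, function(s) which(mism == s | partner == s))
    # drop dominated duplicates (identical cover sets)
    keys <- vapply(cover, paste, character(1), collapse = ",")
    keep <- !duplicated(keys)
    cover <- cover[keep]
    kk <- min(k, length(cover))
    lower <- max(0L, d - 2L * kk)
    best <- d
    idx <- seq_along(cover)
    subsets <- combn(idx, kk)
    for (j in seq_len(ncol(subsets))) {
        covered <- length(unique(unlist(cover[subsets[, j]])))
        res <- d - covered
        if (res < best) {
            best <- res
            if (best <= lower || best == 0L) break
        }
    }
    best
}

#' Score a consensus motif for imperfect internal repeat structure
#'
#' Detects "STR-like" motifs -- consensus repeat units that are themselves
#' near-perfect tandem repeats of a shorter unit (e.g. \code{AAAAGA}),
#' which behave like short tandem repeats and confound repeat-count
#' comparison. Up to \code{k = \link{maskBudget}(n)} motif positions are
#' masked (a masked character matches anything on either side of the
#' comparison), the masked motif \code{M'} is concatenated with itself into
#' \code{M''}, and the score is the maximum over mask sets and window
#' offsets \code{o = 1, ..., n-1} (the trivial identity offsets are
#' skipped) of \code{(n - HammingDistance(M', M''[o..o+n-1])) / n}. A
#' perfect circular internal repeat scores 1; motifs scoring above the
#' cutoff (0.8 by convention) are flagged \code{is_str_like}.
#'
#' The search is exact: for each offset the best mask set is found by
#' enumerating mask subsets with branch-and-bound pruning (each mask can
#' repair at most two mismatches), which agrees with exhaustive
#' enumeration.
#'
#' @param motif Character vector of motifs over A/C/G/T.
#' @param k Mask budget; defaults to \code{maskBudget(nchar(motif), rule)}.
#' @param cutoff Score above which a motif is deemed STR-like.
#' @param rule Budget rule, see \code{\link{maskBudget}}.
#'
#' @return A data.frame with columns \code{motif}, \code{n}, \code{k},
#'   \code{score}, \code{is_str_like} (one row per motif).
#'
#' @examples
#' strlikeScore(c("AAAAAA", "AAAAGA", "GGCCTG"))
#'
#' @seealso \code{\link{filterStrLike}}
#' @export
strlikeScore <- function(motif, k = NULL, cutoff = 0.8,
                         rule = c("default", "alternate")) {
    rule <- match.arg(rule)
    if (any(nchar(motif) == 0L)) stop("empty motif")
    if (any(!grepl("^[ACGTacgt]+$", motif)))
        stop("motifs must be over A,C,G,T")
    res <- lapply(seq_along(motif), function(i) {
        m <- toupper(motif[[i]])
        n <- nchar(m)
        ki <- if (is.null(k)) maskBudget(n, rule) else as.integer(k)
        if (n == 1L)   # no non-trivial window exists
            return(data.frame(motif = m, n = n, k = ki, score = 0,
                              is_str_like = FALSE))
        v <- utf8ToInt(m)
        offs <- seq_len(n - 1L)
        mism <- lapply(offs, function(o)
            which(v != v[((seq_len(n) - 1L + o) %% n) + 1L]))
        sizes <- lengths(mism)
        best <- min(sizes)          # unmasked best as starting bound
        for (o in offs[order(sizes)]) {
            if (best == 0L) break
            if (max(0L, sizes[[o]] - 2L * ki) >= best) next
            r <- .offsetResidual(mism[[o]], o, n, ki, best)
            if (r < best) best <- r
        }
        score <- (n - best) / n
        data.frame(motif = m, n = n, k = ki, score = score,
                   is_str_like = score > cutoff)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Partition a catalog by the STR-like motif filter
#'
#' Splits loci on whether their consensus motif's
#' \code{\link{strlikeScore}} exceeds \code{cutoff} (strictly). STR-like
#' loci are conventionally excluded from genotype-consistency and
#' Mendelian analyses, where a genotyper may disagree on repeat counts
#' even though the underlying sequences agree.
#'
#' @param catalog A \code{\link{VntrCatalog}}.
#' @param cutoff Strict score cutoff, default 0.8.
#'
#' @return A list with elements \code{kept} and \code{discarded}, both
#'   \code{VntrCatalog}s in input order, each carrying a
#'   \code{strlike_score} metadata column.
#'
#' @examples
#' cat <- VntrCatalog(GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(1, 101), c(60, 160)),
#'     motif = c("AAAAAA", "ACGTGG")))
#' filterStrLike(cat)   # AAAAAA discarded (1.0), ACGTGG kept (0.67)
#' @export
filterStrLike <- function(catalog, cutoff = 0.8) {
    if (length(catalog) == 0L)
        return(list(kept = catalog, discarded = catalog))
    sc <- strlikeScore(motifs(catalog), cutoff = cutoff)
    catalog$strlike_score <- sc$score
    list(kept = catalog[!(sc$score > cutoff)],
         discarded = catalog[sc$score > cutoff])
}

#' Tabulate STR-like scores for a set of motifs
#'
#' Convenience wrapper returning the TSV-shaped score table for a motif
#' list (one row per motif: motif, length, mask budget, score, flag).
#'
#' @inheritParams strlikeScore
#' @return The \code{\link{strlikeScore}} data.frame.
#' @examples
#' strlikeTable(c("ACGACG", "ACGTGG"))
#' @export
strlikeTable <- function(motif, cutoff = 0.8,
                         rule = c("default", "alternate")) {
    strlikeScore(motif, cutoff = cutoff, rule = match.arg(rule))
}
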