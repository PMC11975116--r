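## Independent brute-force oracles used to freeze expected values.
## These deliberately re-derive everything from first principles and share
## no code with the package implementation.

## Naive exhaustive STR-like score: enumerate every mask subset of size
## 0..k and every non-trivial window offset of the doubled masked motif;
## a masked position (0) matches anything on either side.
oracle_strlike <- function(m, k = ceiling(nchar(m) / 10)) {
    v <- utf8ToInt(toupper(m))
    n <- length(v)
    if (n == 1L) return(0)
    masksets <- list(integer(0))
    for (sz in seq_len(min(k, n))) {
        cmb <- utils::combn(n, sz)
        for (j in seq_len(ncol(cmb)))
            masksets[[length(masksets) + 1L]] <- cmb[, j]
    }
    best <- 0L
    for (S in masksets) {
        mm <- v
        mm[S] <- 0L
        dd <- c(mm, mm)
        for (o in seq_len(n - 1L)) {
            w <- dd[(o + 1L):(o + n)]
            d <- sum(mm != 0L & w != 0L & mm != w)
            if (n - d > best) best <- n - d
        }
    }
    best / n
}

## Rule-checker for the consistency taxonomy, written directly from the
## three-level definition (not from the implementation).
oracle_consistency <- function(g1, g2) {
    if (anyNA(g1) || anyNA(g2)) return("not_comparable")
    s1 <- sort(g1); s2 <- sort(g2)
    if (all(s1 == s2)) return("consistent")
    het <- (s1[1] != s1[2]) || (s2[1] != s2[2])
    if (length(unique(c(s1, s2))) == 2L && het)
        return("partially_consistent")
    "inconsistent"
}

## Mendelian check by explicit enumeration of the four transmission
## assignments.
oracle_mendelian <- function(child, mother, father) {
    ok <- FALSE
    for (i in 1:2) for (j in 1:2) {
        if (child[1] == mother[i] && child[2] == father[j]) ok <- TRUE
        if (child[1] == father[i] && child[2] == mother[j]) ok <- TRUE
    }
    ok
}

## Random motif over a given alphabet.
random_motif <- function(n, alphabet = c("A", "C", "G", "T")) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## All motifs of lengths 2..maxLen over a 2-letter alphabet.
all_two_letter_motifs <- function(maxLen = 8) {
    unlist(lapply(2:maxLen, function(n) {
        apply(expand.grid(rep(list(c("A", "C")), n)), 1, paste,
              collapse = "")
    }))
}

## All unordered diploid genotypes with alleles in `alleles`.
all_genotypes <- function(alleles) {
    gt <- expand.grid(a = alleles, b = alleles)
    gt <- gt[gt$a <= gt$b, ]
    lapply(seq_len(nrow(gt)), function(i) c(gt$a[i], gt$b[i]))
}
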