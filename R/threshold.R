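#' Probability of miscalling a heterozygous genotype from n spanning reads
#'
#' With \code{n} spanning reads over a heterozygous locus and no allele
#' dropout, each read derives from either allele with probability
#' \code{balance} (default 0.5). The genotyper collapses the call to
#' homozygous when one allele contributes 2 or fewer reads, so the miscall
#' probability is the binomial union
#' \deqn{P_{err}(n) = P(x \ge n-2 \ \mathrm{OR}\ x \le 2)}
#' where \eqn{x \sim Binomial(n, balance)}. For \code{n <= 5} the two tails
#' overlap and the union saturates at 1. At the default balance the value
#' is computed with exact integer arithmetic,
#' \eqn{2 \sum_{i=0}^{2} \binom{n}{i} / 2^n} for \eqn{n \ge 6}.
#'
#' @param n Positive integer number of spanning reads (vectorized).
#' @param balance Per-read probability of sampling the first allele;
#'   0.5 assumes no allele dropout.
#'
#' @return Numeric vector of probabilities in [0, 1].
#'
#' @examples
#' perr(15)          # 0.00739 (242/32768)
#' perr(14)          # 0.01294 (212/16384)
#' minSpanningThreshold(0.01)   # 15
#'
#' @seealso \code{\link{minSpanningThreshold}}, \code{\link{perrTable}}
#' @export
perr <- function(n, balance = 0.5) {
    if (any(n < 1) || any(n != as.integer(n)))
        stop("n must be a positive integer")
    vapply(as.integer(n), function(ni) {
        if (ni <= 5)
            return(1)
        if (balance == 0.5) {
            # exact: both tails have 3 terms, symmetric under p = 0.5
            2 * sum(choose(ni, 0:2)) / 2^ni
        } else {
            lo <- stats::pbinom(2, ni, balance)
            hi <- stats::pbinom(ni - 3, ni, balance, lower.tail = FALSE)
            min(1, lo + hi)
        }
    }, numeric(1))
}

#' Minimum spanning-read threshold for a miscall tolerance
#'
#' Smallest number of spanning reads \code{n} for which the heterozygous
#' miscall probability \code{\link{perr}(n)} falls strictly below
#' \code{alpha}. At \code{alpha = 0.01} the threshold is 15 reads.
#'
#' @param alpha Tolerated miscall probability, in (0, 1].
#' @param balance Passed to \code{\link{perr}}.
#'
#' @return A positive integer.
#' @examples
#' minSpanningThreshold(0.01)
#' @export
minSpanningThreshold <- function(alpha, balance = 0.5) {
    if (alpha <= 0 || alpha > 1)
        stop("alpha must lie in (0, 1]")
    n <- 1L
    while (perr(n, balance) >= alpha)
        n <- n + 1L
    n
}

#' Tabulate the heterozygous miscall probability over a range of n
#'
#' @param nMax Largest read count tabulated.
#' @param nMin Smallest read count tabulated.
#' @param balance Passed to \code{\link{perr}}.
#'
#' @return A data.frame with columns \code{n} and \code{perr}, suitable for
#'   writing as TSV.
#' @examples
#' perrTable(20)
#' @export
perrTable <- function(nMax = 30L, nMin = 1L, balance = 0.5) {
    n <- seq.int(nMin, nMax)
    data.frame(n = n, perr = perr(n, balance))
}
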