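#' @include AllClasses.R
NULL

#' Exact test of Hardy-Weinberg proportions
#'
#' Allele-count-conditional exact test for a diallelic marker. Conditional
#' on the observed allele counts, the probability of every attainable
#' heterozygote count is evaluated, and the p-value is the total probability
#' of configurations no more probable than the observed one (probability
#' ordering, two-sided). The observed configuration is always included
#' (ties compared with relative tolerance 1e-12), so the p-value is strictly
#' positive. The test is symmetric in the allele labels.
#'
#' @param x A [GenotypeCounts-class] object, a length-3 vector
#'   `(nAA, nAa, naa)`, or a 3-row matrix of counts (one column per marker).
#' @return The exact p-value in (0, 1\]; for a matrix input, one p-value
#'   per column.
#' @examples
#' hweExactPvalue(c(25, 50, 25))    # observed het count at the mode -> 1
#' hweExactPvalue(genotypeCounts(1, 0, 1))
#' @export
hweExactPvalue <- function(x) {
    if (is.matrix(x)) {
        if (any(colSums(x) < 1)) stop("empty sample")
        storage.mode(x) <- "integer"
        return(hweExactBatchC(x))
    }
    cn <- .asCounts3(x)
    if (sum(cn) < 1) stop("empty sample")
    hweExactPvalueC(cn[1], cn[2], cn[3])
}

#' Conditional log-probability of a heterozygote count
#'
#' Log of the probability of observing `h` heterozygotes given `nA` copies
#' of one allele among `n` diploid individuals, under Hardy-Weinberg
#' proportions conditional on the allele counts. Probabilities over all
#' attainable `h` (same parity as `nA`) sum to one. Log-factorials are
#' cached across calls, so batch evaluation is cheap.
#'
#' @param h Heterozygote count (same parity as `nA`).
#' @param nA Count of one allele (either orientation; the distribution is
#'   symmetric).
#' @param n Number of individuals.
#' @return The log-probability.
#' @examples
#' exp(logHweProb(2, nA = 2, n = 2))   # 2/3
#' logHweProb(0, nA = 0, n = 5)        # 0: no minor alleles
#' @export
logHweProb <- function(h, nA, n) {
    logHweProbC(as.integer(h), as.integer(nA), as.integer(n))
}
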