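# Independent oracles, written against first principles (no package kernels).

# direct-enumeration exact HWP test: conditional probability of h
# heterozygotes given allele counts, via log-factorials computed with
# lgamma, probability-ordering p-value
naiveHweExact <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    nA <- 2 * nAA + nAa
    nB <- 2 * n - nA
    lfac <- function(x) lgamma(x + 1)
    hs <- seq(nA %% 2, min(nA, nB), by = 2)
    lp <- vapply(hs, function(h) {
        homA <- (nA - h) / 2
        homB <- n - h - homA
        lfac(n) - lfac(homA) - lfac(h) - lfac(homB) +
            h * log(2) + lfac(nA) + lfac(nB) - lfac(2 * n)
    }, numeric(1))
    pr <- exp(lp - max(lp))
    pr <- pr / sum(pr)
    pobs <- pr[match(nAa, hs)]
    min(sum(pr[pr <= pobs * (1 + 1e-12)]), 1)
}

# genotype counts at exact HWP proportions (sizes divisible by 25 with
# p = 0.4 give integer counts: 0.36/0.48/0.16 per block)
hwpCounts <- function(p, n) round(n * c(p^2, 2 * p * (1 - p), (1 - p)^2))

# four-stratum blocks with every block exactly at HWP
hwpBlocks <- function(p, sizes) {
    cc <- lapply(sizes, function(n) hwpCounts(p, n))
    blockCounts(cc[[1]], cc[[2]], cc[[3]], cc[[4]])
}

# random valid BlockCounts / PopulationParams for property loops
randBlocks <- function(nmax = 800) {
    sizes <- sample(20:nmax, 4, replace = TRUE)
    p <- runif(1, 0.1, 0.9)
    m <- vapply(sizes, function(n)
        as.numeric(rmultinom(1, n, c(p^2, 2 * p * (1 - p), (1 - p)^2))),
        numeric(3))
    blockCounts(m[, 1], m[, 2], m[, 3], m[, 4])
}

randPop <- function() {
    K <- runif(4, 0.05, 1)
    populationParams(K / sum(K))
}

# saturated product-multinomial log-likelihood, independent implementation
refSatLogLik <- function(m) {
    ll <- 0
    for (j in seq_len(ncol(m))) {
        nj <- sum(m[, j])
        if (nj == 0) next
        pj <- m[, j] / nj
        nz <- m[, j] > 0
        ll <- ll + sum(m[nz, j] * log(pj[nz]))
    }
    ll
}

# alternative-hypothesis objective in the constrained (P, r) parametrization
# (free simplex for P, log risks for all blocks but `elim`, whose genotype
# distribution is recovered from the population constraint); used to verify
# numerically that the constrained alternative attains the saturated
# likelihood
altObjective <- function(theta, m, K, elim = which.max(K)) {
    eP <- exp(c(0, theta[1:2]))
    P <- eP / sum(eP)
    q <- matrix(0, 3, 4)
    acc <- numeric(3)
    ip <- 3
    for (b in seq_len(4)[-elim]) {
        r <- exp(theta[ip + 0:1]); ip <- ip + 2
        S <- P[1] + r[1] * P[2] + r[2] * P[3]
        q[, b] <- c(P[1], r[1] * P[2], r[2] * P[3]) / S
        acc <- acc + K[b] * q[, b]
    }
    q[, elim] <- (P - acc) / K[elim]
    if (any(q[, elim] < 0)) return(1e8 * (1 + sum(pmax(-q[, elim], 0))))
    nll <- 0
    for (b in 1:4) {
        nz <- m[, b] > 0
        if (any(nz & q[nz, b] <= 0)) return(1e9)
        nll <- nll - sum(m[nz, b] * log(q[nz, b]))
    }
    nll
}
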