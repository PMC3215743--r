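test_that("negative log-likelihood matches the saturated value at its optimum", {
    # blocks drawn exactly proportional to K_ij x HWP genotype frequencies,
    # all relative risks 1: the model value equals the saturated multinomial
    # log-likelihood of those proportions
    p <- 0.5
    bl <- hwpBlocks(p, c(400, 200, 200, 200))
    nll <- negLogLikelihood(list(P = c(p^2, 2 * p * (1 - p), (1 - p)^2),
                                 r = matrix(1, 4, 2)), bl)
    expect_equal(-nll, refSatLogLik(bl@counts), tolerance = 1e-10)
})

test_that("null-constrained likelihood never beats the saturated alternative", {
    set.seed(411)
    for (i in 1:25) {
        bl <- randBlocks()
        pars <- list(p = runif(1, 0.05, 0.95),
                     r = matrix(exp(rnorm(8, 0, 0.5)), 4, 2))
        nll <- negLogLikelihood(pars, bl, nullConstrained = TRUE)
        expect_gte(nll, -refSatLogLik(bl@counts) - 1e-8)
    }
})

test_that("zero-count cells and empty blocks contribute nothing", {
    m <- cbind(c(10, 20, 10), c(0, 0, 0))
    pars <- list(P = c(0.25, 0.5, 0.25), r = matrix(c(1, 2, 1, 2), 2, 2))
    expect_equal(negLogLikelihood(pars, m, model = "two_stratum"),
                 negLogLikelihood(list(P = pars$P,
                                       r = pars$r[1, , drop = FALSE]),
                                  m[, 1, drop = FALSE],
                                  model = "two_stratum"))
    # positive count on a zero-probability cell -> +Inf, not an error
    pars0 <- list(P = c(0.5, 0, 0.5), r = matrix(1, 1, 2))
    expect_identical(negLogLikelihood(pars0, cbind(c(1, 1, 1)),
                                      model = "two_stratum"), Inf)
})

test_that("the constrained alternative attains the saturated maximum", {
    # the four-stratum alternative has as many free parameters as the data
    # have degrees of freedom; a numeric optimization of the constrained
    # (P, r) parametrization must reach the closed-form saturated value
    set.seed(412)
    bl <- randBlocks(nmax = 80)
    K <- jointProbs(randPop())
    m <- bl@counts
    q <- sweep(m + 0.5, 2, colSums(m) + 1.5, "/")
    Ph <- as.numeric(q %*% K)
    elim <- which.max(K)
    th0 <- c(log(Ph[2] / Ph[1]), log(Ph[3] / Ph[1]))
    for (b in seq_len(4)[-elim])
        th0 <- c(th0, log((q[2, b] / q[1, b]) / (Ph[2] / Ph[1])),
                 log((q[3, b] / q[1, b]) / (Ph[3] / Ph[1])))
    opt <- maximizeLikelihood(function(th) altObjective(th, m, K, elim), th0)
    expect_lt(abs(-opt$value - refSatLogLik(m)), 0.01)
})

test_that("four-stratum likelihood reduces to two strata under independence", {
    # K_ij a product measure and trait-independent risks: the four-stratum
    # likelihood must equal the two-stratum likelihood on collapsed counts
    set.seed(413)
    bl <- randBlocks()
    ft <- 0.35; fd <- 0.22
    r2 <- matrix(exp(rnorm(4, 0, 0.4)), 2, 2)    # rows: D=0, D=1
    P <- c(0.3, 0.5, 0.2)
    nll4 <- negLogLikelihood(list(P = P, r = r2[c(1, 1, 2, 2), ]), bl)
    nll2 <- negLogLikelihood(list(P = P, r = r2),
                             collapseBlocks(bl, "disease"),
                             model = "two_stratum")
    expect_equal(nll4, nll2, tolerance = 1e-9)
})

test_that("LRT and eLRT are null at exact HWP data and grow with sample size", {
    p <- 0.4
    r1 <- fitLRT(hwpCounts(p, 1000), hwpCounts(p, 500), f = 0.3)
    expect_lt(statistic(r1), 1e-6)
    expect_gt(pValue(r1), 0.999)
    pop <- populationParams(c(0.56, 0.14, 0.16, 0.14))
    r2 <- fitELRT(hwpBlocks(p, c(1000, 1000, 1000, 1000)), pop)
    expect_lt(statistic(r2), 1e-4)
    expect_identical(r2@df, 1)

    # doubling all counts strictly increases the statistic for non-HWP data
    bad <- blockCounts(c(300, 100, 200), c(120, 60, 90),
                       c(260, 120, 180), c(250, 110, 170))
    bad2 <- blockCounts(2 * c(300, 100, 200), 2 * c(120, 60, 90),
                        2 * c(260, 120, 180), 2 * c(250, 110, 170))
    s1 <- statistic(fitELRT(bad, pop))
    s2 <- statistic(fitELRT(bad2, pop))
    expect_gt(s1, 1)
    expect_gt(s2, 1.8 * s1)
})

test_that("degenerate markers are flagged instead of optimized", {
    pop <- populationParams(c(0.56, 0.14, 0.16, 0.14))
    mono <- blockCounts(c(50, 0, 0), c(20, 0, 0), c(30, 0, 0), c(25, 0, 0))
    r <- fitELRT(mono, pop)
    expect_identical(pValue(r), 1)
    expect_identical(r@diagnostics$flags, "degenerate")
    r2 <- fitLRT(c(10, 0, 0), c(5, 0, 0), f = 0.3)
    expect_identical(pValue(r2), 1)
})

test_that("null fit recovers the allele frequency of HWP-consistent data", {
    pop <- populationParams(c(0.56, 0.14, 0.16, 0.14))
    set.seed(414)
    p <- 0.35
    m <- vapply(c(1200, 900, 1000, 900), function(n)
        as.numeric(rmultinom(1, n, c(p^2, 2 * p * (1 - p), (1 - p)^2))),
        numeric(3))
    bl <- blockCounts(m[, 1], m[, 2], m[, 3], m[, 4])
    r <- fitELRT(bl, pop)
    expect_true(r@converged)
    expect_lt(abs(r@diagnostics$maf.null - p), 0.01)
})

test_that("two-stratum LRT is calibrated on unmatched null-SNP studies", {
    # null SNP (all ORs 1), unmatched sampling: rejection within Monte-Carlo
    # error of the nominal level
    set.seed(415)
    scn <- simulationScenario(maf = 0.4, fD = 0.3, fT = 0.3, poolSize = 1e5)
    pool <- simulatePopulation(scn)
    fd <- mean(pool$D)
    R <- 600
    rej <- 0
    for (i in seq_len(R)) {
        sel <- sampleUnmatched(pool, 1000, 1000, indices = TRUE)
        tab <- function(ix) tabulate(pool$snp4[ix] + 1L, 3L)
        r <- fitLRT(tab(sel$controls), tab(sel$cases), f = fd)
        rej <- rej + (pValue(r) <= 0.05)
    }
    expect_lt(abs(rej / R - 0.05), 3 * sqrt(0.05 * 0.95 / R))
})

test_that("the simplex wrapper finds simple optima and fixed points", {
    op <- maximizeLikelihood(function(x) sum((x - c(2, -1))^2), c(0, 0))
    expect_lt(max(abs(op$par - c(2, -1))), 1e-4)
    expect_true(op$converged)
    # restarting from the optimum does not move the objective
    op2 <- maximizeLikelihood(function(x) sum((x - c(2, -1))^2), op$par)
    expect_lt(abs(op2$value - op$value), 1e-6)
    expect_error(maximizeLikelihood(function(x) NaN, 0), "finite")
})
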