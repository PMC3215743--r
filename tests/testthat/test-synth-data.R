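test_that("pure Bernoulli prevalences are recovered with null effects", {
    scn <- simulationScenario(maf = 0.4, fD = 0.4, fT = 0.25,
                              alpha = rep(0, 8), beta = rep(0, 9))
    scn@alpha[1] <- qlogis(0.25)
    scn@beta[1] <- qlogis(0.4)
    set.seed(431)
    pop <- simulatePopulation(scn, 2e5)
    se <- sqrt(0.25 * 0.75 / 2e5)
    expect_lt(abs(mean(pop$T) - 0.25), 3 * se)
    expect_lt(abs(mean(pop$D) - 0.4), 3 * sqrt(0.4 * 0.6 / 2e5))
})

test_that("intercept calibration hits target prevalences and is monotone", {
    scn <- simulationScenario(maf = 0.4, fD = 0.3, fT = 0.3, poolSize = 2e5)
    cal <- calibrateIntercepts(scn, seed = 7)
    # bisection solves the expected prevalence exactly; the realized one
    # adds binomial noise ~ sqrt(f(1-f)/n)
    expect_lt(abs(cal$fT.hat - 0.3), 0.002 + 3 * sqrt(0.3 * 0.7 / 2e5))
    expect_lt(abs(cal$fD.hat - 0.3), 0.002 + 3 * sqrt(0.3 * 0.7 / 2e5))
    cal5 <- calibrateIntercepts(scn, fD = 0.5, seed = 7)
    expect_gt(cal5$beta0, cal$beta0)
    # all effects zero, target 0.5: intercept at the symmetry point
    scn0 <- simulationScenario(fD = 0.5, fT = 0.5,
                               alpha = c(NA, rep(0, 7)),
                               beta = c(NA, rep(0, 8)), poolSize = 2e5)
    cal0 <- calibrateIntercepts(scn0, seed = 7)
    expect_lt(abs(cal0$alpha0), 1e-9)   # expectation-based: exact
    expect_lt(abs(cal0$beta0), 1e-9)
    expect_error(calibrateIntercepts(scn, fD = 1 - 1e-12, seed = 7),
                 "unreachable")
})

test_that("joint probabilities are estimated as cell fractions", {
    tbl <- data.frame(T = rep(c(0, 1, 0, 1), c(40, 20, 25, 15)),
                      D = rep(c(0, 0, 1, 1), c(40, 20, 25, 15)))
    pp <- estimateJointProbs(tbl)
    expect_equal(unname(jointProbs(pp)), c(0.40, 0.20, 0.25, 0.15))
    expect_equal(fD(pp), unname(jointProbs(pp)[3] + jointProbs(pp)[4]))
    expect_error(estimateJointProbs(data.frame(T = c(0, 1), D = c(0, 0))),
                 "empty")
})

test_that("frequency matching satisfies the tolerance on every draw", {
    scn <- simulationScenario(maf = 0.4, fD = 0.3, fT = 0.3, poolSize = 1e5)
    set.seed(432)
    pool <- simulatePopulation(scn)
    for (i in 1:100) {
        sel <- sampleFrequencyMatched(pool, 400, 400, c = 0.02,
                                      indices = TRUE)
        q1 <- mean(pool$T[sel$cases])
        q0 <- mean(pool$T[sel$controls])
        expect_lte(abs(q0 - q1), 0.02 + 1 / 400)
        expect_identical(length(sel$cases), 400L)
        expect_identical(length(sel$controls), 400L)
        expect_true(all(pool$D[sel$cases] == 1))
        expect_true(all(pool$D[sel$controls] == 0))
    }
    # c = 0: control trait count pinned to round(q1 * n)
    sel <- sampleFrequencyMatched(pool, 400, 400, c = 0, indices = TRUE)
    q1 <- mean(pool$T[sel$cases])
    expect_identical(sum(pool$T[sel$controls]), as.integer(round(400 * q1)))
    expect_error(sampleFrequencyMatched(pool[pool$T == 0 | pool$D == 1, ],
                                        400, 400, c = 0.02),
                 "stratum")
})

test_that("unmatched sampling ignores the trait and keeps arms disjoint", {
    scn <- simulationScenario(maf = 0.4, fD = 0.3, fT = 0.3, poolSize = 1e5)
    set.seed(433)
    pool <- simulatePopulation(scn)
    pt <- mean(pool$T[pool$D == 0])
    sel <- sampleUnmatched(pool, 1000, 1000, indices = TRUE)
    expect_identical(length(intersect(sel$cases, sel$controls)), 0L)
    se <- sqrt(pt * (1 - pt) / 1000)
    expect_lt(abs(mean(pool$T[sel$controls]) - pt), 3 * se)
})

test_that("matched samples of a null SNP stay in HWP", {
    # SNP 4 has no effect on trait or disease, so matching cannot distort
    # its genotype distribution: exact-test rejections stay near nominal
    scn <- simulationScenario(maf = 0.4, fD = 0.3, fT = 0.3, poolSize = 1e5)
    set.seed(434)
    pool <- simulatePopulation(scn)
    R <- 400
    rej <- 0
    for (i in seq_len(R)) {
        sel <- sampleFrequencyMatched(pool, 500, 500, indices = TRUE)
        g <- pool$snp4[c(sel$cases, sel$controls)]
        rej <- rej + (hweExactPvalue(tabulate(g + 1L, 3L)) <= 0.05)
    }
    expect_lt(rej / R, 0.05 + 3 * sqrt(0.05 * 0.95 / R))
})

test_that("population-parameter perturbation stays within the stated band", {
    pop <- populationParams(c(0.56, 0.14, 0.16, 0.14))
    expect_identical(perturbPopulationParams(pop, 0), pop)
    set.seed(435)
    for (i in 1:50) {
        p2 <- perturbPopulationParams(pop, 0.2)
        expect_equal(sum(jointProbs(p2)), 1, tolerance = 1e-12)
        expect_lte(abs(fD(p2) - fD(pop)), 0.2 * fD(pop) + 1e-12)
        k11 <- unname(jointProbs(p2)[4] / fD(p2))
        k11.0 <- unname(jointProbs(pop)[4] / fD(pop))
        expect_lte(abs(k11 - k11.0), 0.2 * k11.0 + 1e-12)
    }
    set.seed(436)
    w <- testthat::capture_warnings(
        for (i in 1:20) perturbPopulationParams(
            populationParams(c(0.05, 0.05, 0.05, 0.85)), 0.99))
    expect_true(any(grepl("truncated", w)))
})
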