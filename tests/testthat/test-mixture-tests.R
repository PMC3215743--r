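test_that("mixture allocation follows the min rule and largest remainders", {
    # sample already at population proportions: everything is used
    a <- mixtureAllocation(c(400, 200, 250, 150),
                           populationParams(c(0.40, 0.20, 0.25, 0.15)))
    expect_identical(a@Nm, 1000L)
    expect_identical(a@draw, c(400L, 200L, 250L, 150L))
    # equal blocks: floor rule plus largest-remainder rounding
    a <- mixtureAllocation(c(500, 500, 500, 500),
                           populationParams(c(0.40, 0.20, 0.25, 0.15)))
    expect_identical(a@Nm, 1250L)
    expect_identical(a@draw, c(500L, 250L, 313L, 187L))
    # a tiny block binds the whole mixture
    a <- mixtureAllocation(c(10, 1000, 1000, 1000),
                           populationParams(rep(0.25, 4)))
    expect_identical(a@Nm, 40L)
    expect_error(mixtureAllocation(c(0, 10, 10, 10),
                                   populationParams(rep(0.25, 4))),
                 "cannot represent")
})

test_that("allocation conserves totals and respects caps on random inputs", {
    set.seed(421)
    for (i in 1:200) {
        N <- sample(1:2000, 4, replace = TRUE)
        pop <- randPop()
        a <- mixtureAllocation(N, pop)
        expect_identical(sum(a@draw), a@Nm)
        expect_true(all(a@draw <= N))
        expect_identical(a@Nm, as.integer(floor(min(N / jointProbs(pop)))))
    }
})

test_that("mixture draws are hypergeometric within blocks", {
    bl <- blockCounts(c(40, 80, 40), c(10, 30, 20), c(25, 40, 15),
                      c(0, 60, 0))
    pop <- populationParams(c(0.4, 0.2, 0.25, 0.15))
    # exhaustive draw returns the pooled counts exactly
    full <- new("MixtureAllocation", Nm = as.integer(sum(blockTotals(bl))),
                draw = unname(as.integer(blockTotals(bl))),
                source = unname(as.integer(blockTotals(bl))))
    expect_identical(counts(drawMixtureCounts(bl, full)),
                     setNames(as.integer(rowSums(bl@counts)),
                              c("AA", "Aa", "aa")))
    # Monte-Carlo mean tracks the per-block expectation
    al <- mixtureAllocation(bl, pop)
    set.seed(422)
    R <- 10000
    acc <- matrix(0, R, 3)
    for (i in seq_len(R)) acc[i, ] <- counts(drawMixtureCounts(bl, al))
    expm <- as.numeric(sweep(bl@counts, 2, blockTotals(bl), "/") %*% al@draw)
    for (k in 1:3) {
        se <- sd(acc[, k]) / sqrt(R)
        expect_lt(abs(mean(acc[, k]) - expm[k]), 3 * se + 1e-9)
    }
    # a single-genotype block contributes only that genotype
    one <- blockCounts(c(0, 50, 0), c(10, 10, 10), c(10, 10, 10),
                       c(10, 10, 10))
    a1 <- mixtureAllocation(one, pop)
    g <- counts(drawMixtureCounts(one, a1))
    expect_gte(g[["Aa"]], a1@draw[1])
})

test_that("kde mode finds centers and ignores minority bumps", {
    expect_identical(kdeMode(rep(0.5, 50)), 0.5)
    set.seed(423)
    x <- rbeta(500, 20, 20)
    m <- kdeMode(x)
    expect_lt(abs(m - 0.5), 0.03)
    # histogram-argmax oracle at fine binning agrees to 2 grid cells
    br <- seq(0, 1, length.out = 65)
    h <- hist(x, breaks = br, plot = FALSE)
    expect_lt(abs(m - h$mids[which.max(h$counts)]), 2 / 64)
    # mode discriminates from the mean
    y <- c(rep(0.01, 450), rep(0.9, 50))
    expect_lt(kdeMode(y), 0.06)
    expect_gt(mean(y), 0.09)
})

test_that("mixture tests are deterministic given a seed", {
    bl <- blockCounts(c(330, 490, 180), c(160, 230, 110),
                      c(300, 470, 230), c(290, 500, 210))
    pop <- populationParams(c(0.56, 0.14, 0.16, 0.14))
    cfg <- mixtureConfig(M = 200L, seed = 99L)
    r1 <- emhwpTest(bl, pop, cfg)
    r2 <- emhwpTest(bl, pop, cfg)
    expect_identical(pValue(r1), pValue(r2))
    expect_true(pValue(r1) > 0 && pValue(r1) <= 1)
    m <- collapseBlocks(bl, "disease")
    s1 <- mhwpTest(m[, 2], m[, 1], f = 0.3, cfg)
    s2 <- mhwpTest(m[, 2], m[, 1], f = 0.3, cfg)
    expect_identical(pValue(s1), pValue(s2))
})

test_that("two-stratum mixture uses nearly the whole sample when f matches", {
    r <- mhwpTest(cases = c(160, 480, 360), controls = c(380, 1070, 880),
                  f = 1000 / 3330, cfg = mixtureConfig(M = 50L, seed = 1L))
    expect_gte(r@diagnostics$Nm, 3320)
    expect_error(mhwpTest(c(0, 0, 0), c(10, 10, 10), f = 0.3), "empty group")
})

test_that("emHWP agrees with a pooled exact test for population-proportional HWP data", {
    # blocks already at population proportions and in HWP: the mixture
    # p-value should sit near the single exact test on the pooled sample
    pop <- populationParams(c(0.40, 0.20, 0.25, 0.15))
    bl <- blockCounts(hwpCounts(0.4, 800), hwpCounts(0.4, 400),
                      hwpCounts(0.4, 500), hwpCounts(0.4, 300))
    r <- emhwpTest(bl, pop, mixtureConfig(seed = 5L))
    pooled <- hweExactPvalue(rowSums(bl@counts))
    expect_gt(pValue(r), 0.5)
    expect_gt(pooled, 0.5)
})
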