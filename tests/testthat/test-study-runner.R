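test_that("the study runner is deterministic and schema-stable", {
    scn <- simulationScenario(maf = 0.4, fD = 0.3, fT = 0.3,
                              nCases = 300L, nControls = 300L,
                              poolSize = 4e4)
    run <- function() runTypeIStudy(scn, methods = c("elrt", "lrt_d"),
                                    alpha = c(0.05, 0.0001),
                                    replicates = 100L, seed = 31L, snps = 4L)
    r1 <- run(); r2 <- run()
    expect_identical(r1, r2)
    expect_identical(nrow(r1), 4L)
    expect_true(all(r1$proportion >= 0 & r1$proportion <= 1))
    expect_equal(r1$se,
                 sqrt(r1$proportion * (1 - r1$proportion) / r1$replicates))
    expect_error(runTypeIStudy(scn, replicates = 50L), "replicates")
})

test_that("checkpointed runs resume to the identical table", {
    scn <- simulationScenario(maf = 0.4, fD = 0.3, fT = 0.3,
                              nCases = 200L, nControls = 200L,
                              poolSize = 4e4)
    ck <- tempfile(fileext = ".rds")
    r1 <- runTypeIStudy(scn, methods = "lrt_d", alpha = 0.05,
                        replicates = 100L, seed = 32L, checkpoint = ck)
    expect_true(file.exists(ck))
    # a restart must not recompute: same table even with a different seed
    r2 <- runTypeIStudy(scn, methods = "lrt_d", alpha = 0.05,
                        replicates = 100L, seed = 99L, checkpoint = ck)
    expect_identical(r1, r2)
    unlink(ck)
})

test_that("threshold sweep counts are monotone and near-binomial on null panels", {
    # a null panel: blocks drawn from one HWP multinomial per block at
    # population proportions (no genotyping distortion)
    set.seed(437)
    pop <- populationParams(c(0.56, 0.14, 0.16, 0.14))
    p <- 0.4
    P <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
    mkNull <- function() {
        m <- vapply(round(4000 * jointProbs(pop)), function(n)
            as.numeric(rmultinom(1, n, P)), numeric(3))
        blockCounts(m[, 1], m[, 2], m[, 3], m[, 4])
    }
    panel <- replicate(400, mkNull())
    ths <- c(0.05, 0.005, 5e-4)
    sw <- runThresholdSweep(panel, pop, methods = c("lrt_d", "elrt"),
                            thresholds = ths)
    for (mm in colnames(sw$counts))
        expect_true(all(diff(sw$counts[, mm]) <= 0))
    exp5 <- 400 * 0.005
    for (mm in colnames(sw$counts))
        expect_lt(abs(sw$counts["0.005", mm] - exp5),
                  3 * sqrt(400 * 0.005 * 0.995) + 1e-9)

    # gross genotyping distortion (heterozygote deficit 50%) is always caught
    Pbad <- c(P[1], 0.5 * P[2], P[3]); Pbad <- Pbad / sum(Pbad)
    mkBad <- function() {
        m <- vapply(round(4000 * jointProbs(pop)), function(n)
            as.numeric(rmultinom(1, n, Pbad)), numeric(3))
        blockCounts(m[, 1], m[, 2], m[, 3], m[, 4])
    }
    bad <- replicate(10, mkBad())
    sw2 <- runThresholdSweep(bad, pop,
                             methods = c("lrt_t", "lrt_d", "elrt", "emhwp"),
                             thresholds = 0.005,
                             cfg = mixtureConfig(M = 100L, seed = 2L))
    expect_true(all(sw2$counts == 10))
})
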