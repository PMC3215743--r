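#' @include AllClasses.R
NULL

.METHODS <- c("elrt", "emhwp", "lrt_t", "lrt_d", "mhwp_t", "mhwp_d",
              "exact_controls")

#' Apply one HWP testing method to stratified counts
#'
#' Dispatcher over the tests in this package, sharing one interface: the
#' four-stratum tests use `blocks` and `pop` directly; the two-stratum
#' baselines collapse the blocks by disease (`*_d`) or trait (`*_t`) and
#' use the corresponding marginal prevalence; `exact_controls` runs the
#' plain exact test on the disease controls.
#'
#' @param blocks A [BlockCounts-class] object.
#' @param pop A [PopulationParams-class] object.
#' @param method One of `"elrt"`, `"emhwp"`, `"lrt_t"`, `"lrt_d"`,
#'   `"mhwp_t"`, `"mhwp_d"`, `"exact_controls"`.
#' @param cfg [MixtureConfig-class] for the mixture tests.
#' @return An [HWPTestResult-class].
#' @examples
#' pop <- populationParams(c(0.56, 0.14, 0.16, 0.14))
#' bl <- blockCounts(c(330, 490, 180), c(160, 230, 110),
#'                   c(300, 470, 230), c(290, 500, 210))
#' testHWP(bl, pop, "lrt_d")
#' @export
testHWP <- function(blocks, pop, method = .METHODS, cfg = mixtureConfig()) {
    method <- match.arg(method)
    switch(method,
        elrt = fitELRT(blocks, pop),
        emhwp = emhwpTest(blocks, pop, cfg),
        lrt_t = {
            m <- collapseBlocks(blocks, "trait")
            r <- fitLRT(m[, 1], m[, 2], fT(pop))
            r@method <- "LRT_t"; r
        },
        lrt_d = {
            m <- collapseBlocks(blocks, "disease")
            r <- fitLRT(m[, 1], m[, 2], fD(pop))
            r@method <- "LRT_d"; r
        },
        mhwp_t = {
            m <- collapseBlocks(blocks, "trait")
            r <- mhwpTest(cases = m[, 2], controls = m[, 1], fT(pop), cfg)
            r@method <- "mHWP_t"; r
        },
        mhwp_d = {
            m <- collapseBlocks(blocks, "disease")
            r <- mhwpTest(cases = m[, 2], controls = m[, 1], fD(pop), cfg)
            r@method <- "mHWP_d"; r
        },
        exact_controls = {
            m <- collapseBlocks(blocks, "disease")
            .testResult("exact_controls", p.value = hweExactPvalue(m[, 1]))
        })
}

# tabulate one SNP's genotypes into the four (T,D) blocks given index sets
.blocksFor <- function(geno, Tvec, sel) {
    gcase <- geno[sel$cases]; tcase <- Tvec[sel$cases]
    gctrl <- geno[sel$controls]; tctrl <- Tvec[sel$controls]
    cnt <- function(g) tabulate(g + 1L, 3L)
    m <- cbind(cnt(gctrl[tctrl == 0]), cnt(gctrl[tctrl == 1]),
               cnt(gcase[tcase == 0]), cnt(gcase[tcase == 1]))
    dimnames(m) <- list(.GENOS, .BLOCKS)
    new("BlockCounts", counts = m)
}

#' Monte-Carlo type-I-error study of HWP tests under frequency matching
#'
#' For each scenario: calibrates the logistic intercepts and builds one
#' population pool, estimates the joint probabilities \eqn{K_{ij}} from it,
#' then repeatedly draws a frequency-matched case-control study and applies
#' the requested HWP tests to the chosen SNP columns, recording rejection
#' proportions at each significance level. All SNPs are generated in HWP,
#' so rejections are type-I errors. The whole run is reproducible from
#' `seed`.
#'
#' @param scenarios A [SimulationScenario-class] or a list of them.
#' @param methods Character vector of methods (see [testHWP]).
#' @param alpha Significance levels.
#' @param replicates Number of replicates per scenario (>= 100).
#' @param seed Integer master seed.
#' @param snps SNP columns (1-4) to test in every replicate; under the
#'   default Table-1-style coefficients, SNP 1 is associated with both
#'   disease and trait, SNP 2 with disease only, SNP 3 with trait only and
#'   SNP 4 with neither.
#' @param cfg [MixtureConfig-class] for the mixture tests.
#' @param perturb Optional relative misspecification of the population
#'   parameters handed to the tests (see [perturbPopulationParams]); 0
#'   uses the estimated values unchanged.
#' @param keepPvalues Also return the raw p-values (attribute `pvalues`: one
#'   `replicates` x snp x method array per scenario), e.g. for
#'   uniformity diagnostics.
#' @param checkpoint Optional path; completed scenarios are saved there and
#'   skipped when the run is restarted.
#' @param workers Accepted for interface compatibility; replicates are run
#'   serially (results are order-independent sums either way).
#' @param verbose Print per-scenario progress.
#' @return A data frame with one row per (scenario, snp, method, alpha):
#'   rejection `proportion`, Monte-Carlo standard error `se`
#'   (\eqn{\sqrt{\hat p (1-\hat p)/R}}), `replicates`, and `failures`.
#'   Method failures are excluded from the denominator; more than 0.1%
#'   failures abort the scenario.
#' @export
runTypeIStudy <- function(scenarios, methods = c("elrt", "lrt_t", "lrt_d"),
                          alpha = c(0.05, 1e-4), replicates = 5000L,
                          seed = 1L, snps = 1L, cfg = mixtureConfig(),
                          perturb = 0, keepPvalues = FALSE,
                          checkpoint = NULL, workers = 1L,
                          verbose = FALSE) {
    if (is(scenarios, "SimulationScenario")) scenarios <- list(scenarios)
    stopifnot(length(scenarios) >= 1L, replicates >= 100L,
              all(alpha > 0 & alpha < 1),
              all(methods %in% .METHODS), all(snps %in% 1:4))
    set.seed(seed)
    scenSeeds <- sample.int(.Machine$integer.max, length(scenarios))
    done <- if (!is.null(checkpoint) && file.exists(checkpoint))
        readRDS(checkpoint) else list()
    out <- list()
    for (s in seq_along(scenarios)) {
        key <- paste0("scenario", s)
        if (!is.null(done[[key]])) {
            out[[key]] <- done[[key]]
            next
        }
        scn <- scenarios[[s]]
        set.seed(scenSeeds[s])
        pool <- simulatePopulation(scn)
        popPar <- estimateJointProbs(pool)
        testPar <- if (perturb > 0) perturbPopulationParams(popPar, perturb)
                   else popPar
        caseIdx <- which(pool$D == 1)
        ctrl1 <- which(pool$D == 0 & pool$T == 1)
        ctrl0 <- which(pool$D == 0 & pool$T == 0)
        Tcase <- pool$T[caseIdx]
        Tvec <- pool$T
        gcols <- lapply(snps, function(s) pool[[paste0("snp", s)]])
        rej <- array(0L, dim = c(length(snps), length(methods), length(alpha)))
        fails <- matrix(0L, length(snps), length(methods))
        pvs <- if (keepPvalues)
            array(NA_real_, c(replicates, length(snps), length(methods)),
                  dimnames = list(NULL, paste0("snp", snps), methods))
        for (r in seq_len(replicates)) {
            sel <- .matchIndices(caseIdx, ctrl0, ctrl1, Tcase,
                                 scn@nCases, scn@nControls, scn@c)
            for (gi in seq_along(snps)) {
                bl <- .blocksFor(gcols[[gi]], Tvec, sel)
                for (mi in seq_along(methods)) {
                    p <- tryCatch(pValue(testHWP(bl, testPar, methods[mi],
                                                 cfg)),
                                  error = function(e) NA_real_)
                    if (keepPvalues) pvs[r, gi, mi] <- p
                    if (is.na(p)) {
                        fails[gi, mi] <- fails[gi, mi] + 1L
                    } else {
                        rej[gi, mi, ] <- rej[gi, mi, ] + (p <= alpha)
                    }
                }
            }
            if (verbose && r %% 500L == 0L)
                message("scenario ", s, ": replicate ", r, "/", replicates)
        }
        if (any(fails > 0.001 * replicates))
            stop("method failure rate above 0.1% in scenario ", s)
        rows <- expand.grid(alpha = alpha, method = methods, snp = snps,
                            stringsAsFactors = FALSE)[, 3:1]
        denom <- replicates - fails[cbind(match(rows$snp, snps),
                                          match(rows$method, methods))]
        prop <- rej[cbind(match(rows$snp, snps),
                          match(rows$method, methods),
                          match(rows$alpha, alpha))] / denom
        out[[key]] <- data.frame(
            scenario = s, maf = scn@maf, fD = scn@fD, fT = scn@fT,
            rows, replicates = denom, proportion = prop,
            se = sqrt(prop * (1 - prop) / denom),
            failures = replicates - denom, row.names = NULL)
        if (keepPvalues) attr(out[[key]], "pvalues") <- pvs
        if (!is.null(checkpoint)) {
            done[[key]] <- out[[key]]
            saveRDS(done, checkpoint)
        }
        if (verbose) message("scenario ", s, " done")
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    if (keepPvalues)
        attr(res, "pvalues") <- lapply(unname(out), attr, "pvalues")
    res
}

#' Threshold sweep of HWP rejections over a SNP panel
#'
#' Batch quality-control workflow: compute each method's HWP p-value for
#' every SNP in a panel once, then count how many SNPs each method would
#' reject (and remove) at a ladder of significance thresholds. Counts are
#' monotone non-increasing as the threshold decreases.
#'
#' @param panel A list of [BlockCounts-class] objects (one per SNP,
#'   optionally named).
#' @param pop A [PopulationParams-class] object.
#' @param methods Methods to compare (see [testHWP]).
#' @param thresholds Significance thresholds, e.g.
#'   `c(5e-3, 1e-3, 5e-4, 1e-4, 5e-5, 1e-5, 5e-6, 1e-6)`.
#' @param cfg [MixtureConfig-class] for the mixture tests.
#' @return A list with `counts` (matrix thresholds x methods of rejection
#'   counts) and `pvalues` (matrix SNPs x methods).
#' @export
runThresholdSweep <- function(panel, pop,
                              methods = c("lrt_t", "lrt_d", "elrt", "emhwp"),
                              thresholds = c(5e-3, 1e-3, 5e-4, 1e-4,
                                             5e-5, 1e-5, 5e-6, 1e-6),
                              cfg = mixtureConfig()) {
    stopifnot(length(panel) >= 1L, all(methods %in% .METHODS))
    pv <- vapply(panel, function(bl) {
        vapply(methods, function(mm)
            pValue(testHWP(bl, pop, mm, cfg)), numeric(1))
    }, numeric(length(methods)))
    pv <- matrix(pv, nrow = length(methods),
                 dimnames = list(methods, names(panel)))
    thresholds <- sort(thresholds, decreasing = TRUE)
    cnt <- vapply(methods, function(mm)
        vapply(thresholds, function(th) sum(pv[mm, ] < th, na.rm = TRUE),
               numeric(1)), numeric(length(thresholds)))
    cnt <- matrix(cnt, nrow = length(thresholds),
                  dimnames = list(format(thresholds, scientific = FALSE,
                                         drop0trailing = TRUE), methods))
    list(counts = cnt, pvalues = t(pv))
}
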