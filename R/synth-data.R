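#' @include AllClasses.R
NULL

# bisection on the intercept of a logistic model so that the expected
# prevalence over the pool's linear predictors hits `target`
.calibrateIntercept <- function(eta, target, lower = -20, upper = 20,
                                tol = 1e-10, maxit = 200L) {
    g <- function(c0) mean(plogis(c0 + eta)) - target
    if (g(lower) > 0 || g(upper) < 0)
        stop("target prevalence unreachable within intercept bounds")
    for (i in seq_len(maxit)) {
        mid <- (lower + upper) / 2
        if (g(mid) > 0) upper <- mid else lower <- mid
        if (upper - lower < tol) break
    }
    (lower + upper) / 2
}

#' Simulate a general population under the two-logistic-model design
#'
#' Generates `size` individuals: four independent SNP genotypes drawn from
#' Hardy-Weinberg proportions at the scenario MAF, covariates (sex,
#' ethnicity, a 3-band additive age factor) at their prevalences, then the
#' secondary trait T from a first logistic model of the SNPs (dominant
#' coding) and covariates, and the primary disease D from a second logistic
#' model that additionally includes T. Intercepts that are `NA` in the
#' scenario are calibrated by bisection on the expected prevalence over the
#' generated pool so that the trait and disease hit the scenario's target
#' prevalences.
#'
#' Uses the ambient RNG stream (seed with `set.seed` before calling).
#'
#' @param scn A [SimulationScenario-class].
#' @param size Number of individuals (default the scenario pool size).
#' @return A data frame with columns `snp1..snp4` (minor-allele counts
#'   0/1/2), `sex`, `ethn`, `age` (band 0/1/2), `T`, `D`; attributes
#'   `alpha0` and `beta0` carry the (possibly calibrated) intercepts.
#' @examples
#' set.seed(1)
#' pop <- simulatePopulation(simulationScenario(), size = 5e4)
#' mean(pop$D); mean(pop$T)
#' @export
simulatePopulation <- function(scn, size = scn@poolSize) {
    stopifnot(is(scn, "SimulationScenario"), size >= 1)
    n <- as.integer(size)
    g <- vapply(1:4, function(i) rbinom(n, 2L, scn@maf), integer(n))
    colnames(g) <- paste0("snp", 1:4)
    dom <- g >= 1L                       # dominant coding: carrier indicator
    sex <- rbinom(n, 1L, scn@sexPrev)
    ethn <- rbinom(n, 1L, scn@ethnPrev)
    age <- sample.int(3L, n, replace = TRUE,
                      prob = c(scn@agePrev, 1 - sum(scn@agePrev))) - 1L
    a <- scn@alpha
    etaT <- as.numeric(dom %*% a[2:5]) + a[6] * sex + a[7] * ethn + a[8] * age
    a0 <- if (is.na(a[1])) .calibrateIntercept(etaT, scn@fT) else a[1]
    Tr <- rbinom(n, 1L, plogis(a0 + etaT))
    b <- scn@beta
    etaD <- as.numeric(dom %*% b[2:5]) + b[6] * sex + b[7] * ethn +
        b[8] * age + b[9] * Tr
    b0 <- if (is.na(b[1])) .calibrateIntercept(etaD, scn@fD) else b[1]
    D <- rbinom(n, 1L, plogis(b0 + etaD))
    out <- data.frame(g, sex = sex, ethn = ethn, age = age, T = Tr, D = D)
    attr(out, "alpha0") <- a0
    attr(out, "beta0") <- b0
    out
}

#' Calibrate the logistic intercepts to target prevalences
#'
#' Builds a seeded covariate pool and solves, by bisection, for the
#' trait-model intercept such that the expected trait prevalence equals
#' `fT`, then (with the trait regenerated at the solution) for the
#' disease-model intercept hitting `fD`.
#'
#' @param scn A [SimulationScenario-class] (its `fD`/`fT` are the targets
#'   unless overridden).
#' @param fD,fT Target prevalences in (0, 1).
#' @param poolSize Monte-Carlo pool size (>= 1e6 recommended).
#' @param seed Integer seed for the fixed calibration pool.
#' @return A list with `alpha0`, `beta0`, and the achieved prevalences
#'   `fT.hat`, `fD.hat` (within 0.002 of the targets up to Monte-Carlo
#'   noise at the default pool size).
#' @export
calibrateIntercepts <- function(scn, fD = scn@fD, fT = scn@fT,
                                poolSize = scn@poolSize, seed = 1L) {
    stopifnot(fD > 0, fD < 1, fT > 0, fT < 1)
    scn@fD <- fD; scn@fT <- fT
    scn@alpha[1] <- NA_real_; scn@beta[1] <- NA_real_
    pool <- .withSeed(as.integer(seed), simulatePopulation(scn, poolSize))
    list(alpha0 = attr(pool, "alpha0"), beta0 = attr(pool, "beta0"),
         fT.hat = mean(pool$T), fD.hat = mean(pool$D))
}

#' Estimate population joint probabilities from a simulated population
#'
#' @param pop A population data frame with binary columns `T` and `D`
#'   (e.g., from [simulatePopulation]).
#' @return A [PopulationParams-class] with \eqn{K_{ij}} equal to the cell
#'   fractions.
#' @export
estimateJointProbs <- function(pop) {
    stopifnot(all(c("T", "D") %in% names(pop)))
    cells <- c(sum(pop$T == 0 & pop$D == 0), sum(pop$T == 1 & pop$D == 0),
               sum(pop$T == 0 & pop$D == 1), sum(pop$T == 1 & pop$D == 1))
    if (any(cells == 0)) stop("empty (T,D) cell in population")
    populationParams(cells / nrow(pop))
}

# draw k of n indices without replacement; hashing is much faster than the
# default partial shuffle when k is small relative to a large n
.sampleIdx <- function(n, k) {
    if (k == 0L) return(integer())
    if (n > 1e4 && 2 * k < n) sample.int(n, k, useHash = TRUE)
    else sample.int(n, k)
}

# internal index-level matched sampler shared with the study runner;
# returns list(cases, controls) of row indices
.matchIndices <- function(caseIdx, ctrlIdx0, ctrlIdx1, Tcase,
                          nCases, nControls, c) {
    if (length(caseIdx) < nCases) stop("insufficient cases in pool")
    pos <- .sampleIdx(length(caseIdx), nCases)
    si <- caseIdx[pos]
    q1 <- mean(Tcase[pos])
    for (attempt in 1:2) {
        q0 <- min(max(runif(1, q1 - c, q1 + c), 0), 1)
        n1 <- round(q0 * nControls)
        if (abs(n1 / nControls - q1) <= c + 1 / nControls) break
    }
    n0 <- nControls - n1
    if (n1 > length(ctrlIdx1))
        stop("insufficient controls in stratum T=1")
    if (n0 > length(ctrlIdx0))
        stop("insufficient controls in stratum T=0")
    s1 <- ctrlIdx1[.sampleIdx(length(ctrlIdx1), n1)]
    s0 <- ctrlIdx0[.sampleIdx(length(ctrlIdx0), n0)]
    list(cases = si, controls = c(s1, s0))
}

#' Draw a frequency-matched case-control study from a population pool
#'
#' Samples `nCases` primary-disease cases uniformly, computes their trait
#' fraction \eqn{q_1 = Pr(T=1|D=1)}, draws the target control trait
#' fraction \eqn{q_0} uniformly from \eqn{(q_1 - c, q_1 + c)} (truncated to
#' \[0, 1\]), and samples `round(q0 * nControls)` controls with T = 1 and
#' the remainder with T = 0, uniformly within strata. The realised design
#' satisfies \eqn{|Pr(T=1|D=0) - Pr(T=1|D=1)| \le c + 1/n_{controls}}
#' (matching inequality plus rounding slack; the draw of \eqn{q_0} is
#' repeated once should truncation violate it).
#'
#' @param pop Population data frame (columns `T`, `D`, ...).
#' @param nCases,nControls Arm sizes.
#' @param c Matching tolerance (default 0.02).
#' @param indices Return row indices instead of rows.
#' @return A data frame of sampled rows (cases first), or -- with
#'   `indices = TRUE` -- a list with `cases` and `controls` index vectors.
#' @export
sampleFrequencyMatched <- function(pop, nCases = 2000L, nControls = 2000L,
                                   c = 0.02, indices = FALSE) {
    caseIdx <- which(pop$D == 1)
    ctrl1 <- which(pop$D == 0 & pop$T == 1)
    ctrl0 <- which(pop$D == 0 & pop$T == 0)
    sel <- .matchIndices(caseIdx, ctrl0, ctrl1, pop$T[caseIdx],
                         nCases, nControls, c)
    if (indices) return(sel)
    pop[c(sel$cases, sel$controls), , drop = FALSE]
}

#' Draw an unmatched case-control study from a population pool
#'
#' Cases and controls are sampled uniformly within the disease strata,
#' ignoring the secondary trait.
#'
#' @inheritParams sampleFrequencyMatched
#' @return As in [sampleFrequencyMatched].
#' @export
sampleUnmatched <- function(pop, nCases = 1000L, nControls = 1000L,
                            indices = FALSE) {
    caseIdx <- which(pop$D == 1)
    ctrlIdx <- which(pop$D == 0)
    if (length(caseIdx) < nCases) stop("insufficient cases in pool")
    if (length(ctrlIdx) < nControls) stop("insufficient controls in pool")
    sel <- list(cases = caseIdx[.sampleIdx(length(caseIdx), nCases)],
                controls = ctrlIdx[.sampleIdx(length(ctrlIdx), nControls)])
    if (indices) return(sel)
    pop[c(sel$cases, sel$controls), , drop = FALSE]
}

#' Perturb population parameters to emulate prevalence misspecification
#'
#' Draws the disease prevalence and the two conditional trait probabilities
#' \eqn{Pr(T=1|D=1)} and \eqn{Pr(T=1|D=0)} uniformly within a relative
#' `fraction` of their true values (e.g., 0.2 for a +/-20% band),
#' truncating to (0, 1) with a warning where needed, and reconstitutes a
#' consistent joint distribution \eqn{K_{ij}}.
#'
#' @param pop A [PopulationParams-class] with the true values.
#' @param fraction Relative half-width of the perturbation, in \[0, 1).
#' @return A perturbed [PopulationParams-class]; \eqn{\sum K_{ij} = 1} by
#'   construction.
#' @export
perturbPopulationParams <- function(pop, fraction) {
    stopifnot(is(pop, "PopulationParams"),
              fraction >= 0, fraction < 1)
    if (fraction == 0) return(pop)
    fd <- fD(pop)
    p1 <- unname(pop@K[[4]] / fd)          # Pr(T=1 | D=1)
    p0 <- unname(pop@K[[2]] / (1 - fd))    # Pr(T=1 | D=0)
    eps <- 1e-6
    tr <- function(x) {
        y <- runif(1, x * (1 - fraction), x * (1 + fraction))
        if (y <= 0 || y >= 1) {
            warning("perturbed probability truncated to (0, 1)")
            y <- min(max(y, eps), 1 - eps)
        }
        y
    }
    fd2 <- tr(fd); p12 <- tr(p1); p02 <- tr(p0)
    K <- c((1 - fd2) * (1 - p02), (1 - fd2) * p02,
           fd2 * (1 - p12), fd2 * p12)
    populationParams(K / sum(K))
}
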