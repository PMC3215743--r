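#' @include matchedHWP-package.R
NULL

.BLOCKS <- c("T0D0", "T1D0", "T0D1", "T1D1")
.GENOS <- c("AA", "Aa", "aa")

# ---------------------------------------------------------------------------
# GenotypeCounts
# ---------------------------------------------------------------------------

#' Genotype counts for one diallelic marker in one group
#'
#' Holds the counts of the three genotypes AA, Aa and aa of a diallelic
#' locus in a single group of individuals. With allele frequency p for A,
#' Hardy-Weinberg proportions are \eqn{P_0 = p^2}, \eqn{P_1 = 2p(1-p)},
#' \eqn{P_2 = (1-p)^2}.
#'
#' @slot counts Named integer vector of length 3 (`AA`, `Aa`, `aa`), all
#'   non-negative.
#' @seealso [genotypeCounts()], [hweExactPvalue()]
#' @export
setClass("GenotypeCounts", representation(counts = "integer"))

setValidity("GenotypeCounts", function(object) {
    cn <- object@counts
    if (length(cn) != 3L) return("counts must have length 3 (AA, Aa, aa)")
    if (anyNA(cn)) return("counts must not be NA")
    if (any(cn < 0L)) return("counts must be non-negative")
    TRUE
})

#' Construct genotype counts
#'
#' @param nAA,nAa,naa Non-negative integer counts of the three genotypes.
#' @return A [GenotypeCounts-class] object.
#' @examples
#' genotypeCounts(298, 489, 213)
#' @export
genotypeCounts <- function(nAA, nAa, naa) {
    new("GenotypeCounts",
        counts = setNames(as.integer(c(nAA, nAa, naa)), .GENOS))
}

#' @describeIn genotypeCounts Genotype counts as a named integer vector.
#' @param x A `GenotypeCounts` object.
#' @export
counts <- function(x) {
    if (is(x, "GenotypeCounts")) return(x@counts)
    if (is(x, "BlockCounts")) return(x@counts)
    stop("no counts for this object")
}

#' @describeIn genotypeCounts Number of individuals.
#' @export
sampleSize <- function(x) sum(counts(x))

#' @describeIn genotypeCounts Minor allele frequency of the counted sample.
#' @export
mafOf <- function(x) {
    cn <- if (is(x, "GenotypeCounts")) x@counts else .asCounts3(x)
    n <- sum(cn)
    if (n == 0L) return(NA_real_)
    min(2 * cn[[1]] + cn[[2]], 2 * cn[[3]] + cn[[2]]) / (2 * n)
}

setMethod("show", "GenotypeCounts", function(object) {
    cn <- object@counts
    cat("GenotypeCounts: AA =", cn[[1]], " Aa =", cn[[2]], " aa =", cn[[3]],
        " (n =", sum(cn), ", MAF =", round(mafOf(object), 4), ")\n")
})

# internal: accept GenotypeCounts or a bare length-3 vector
.asCounts3 <- function(x) {
    if (is(x, "GenotypeCounts")) return(as.numeric(x@counts))
    x <- as.numeric(x)
    if (length(x) != 3L || anyNA(x) || any(x < 0))
        stop("genotype counts must be 3 non-negative numbers (AA, Aa, aa)")
    x
}

# ---------------------------------------------------------------------------
# BlockCounts
# ---------------------------------------------------------------------------

#' Genotype counts stratified by trait and disease status
#'
#' Genotype counts of one marker in the four sampling strata of a
#' case-control study with a recorded secondary phenotype: blocks
#' (T = i, D = j) for i, j in \{0, 1\}, ordered `T0D0`, `T1D0`, `T0D1`,
#' `T1D1`. Controls are the D = 0 blocks, cases the D = 1 blocks.
#'
#' @slot counts 3 x 4 integer matrix; rows `AA`, `Aa`, `aa`, columns the
#'   four (T, D) blocks.
#' @seealso [blockCounts()], [fitELRT()], [emhwpTest()]
#' @export
setClass("BlockCounts", representation(counts = "matrix"))

setValidity("BlockCounts", function(object) {
    m <- object@counts
    if (!is.matrix(m) || nrow(m) != 3L || ncol(m) != 4L)
        return("counts must be a 3 x 4 matrix")
    if (anyNA(m) || any(m < 0)) return("counts must be non-negative")
    TRUE
})

#' Construct stratified block counts
#'
#' @param T0D0,T1D0,T0D1,T1D1 Genotype counts for each (trait, disease)
#'   block: [GenotypeCounts-class] objects or length-3 vectors (AA, Aa, aa).
#' @return A [BlockCounts-class] object.
#' @examples
#' blockCounts(T0D0 = c(400, 420, 120), T1D0 = c(110, 95, 30),
#'             T0D1 = c(180, 210, 70),  T1D1 = c(150, 170, 45))
#' @export
blockCounts <- function(T0D0, T1D0, T0D1, T1D1) {
    m <- cbind(.asCounts3(T0D0), .asCounts3(T1D0),
               .asCounts3(T0D1), .asCounts3(T1D1))
    storage.mode(m) <- "integer"
    dimnames(m) <- list(.GENOS, .BLOCKS)
    new("BlockCounts", counts = m)
}

#' @describeIn blockCounts Per-block totals \eqn{N_{ij}}.
#' @param x A `BlockCounts` object.
#' @export
blockTotals <- function(x) colSums(x@counts)

#' @describeIn blockCounts Collapse the four blocks into two strata.
#' @param by `"disease"` (controls D=0 vs cases D=1) or `"trait"`
#'   (T=0 vs T=1).
#' @return For `collapseBlocks`, a 3 x 2 matrix (columns: stratum 0,
#'   stratum 1).
#' @export
collapseBlocks <- function(x, by = c("disease", "trait")) {
    by <- match.arg(by)
    m <- x@counts
    out <- if (by == "disease")
        cbind(m[, 1] + m[, 2], m[, 3] + m[, 4])
    else
        cbind(m[, 1] + m[, 3], m[, 2] + m[, 4])
    dimnames(out) <- list(.GENOS, c("0", "1"))
    out
}

setMethod("show", "BlockCounts", function(object) {
    cat("BlockCounts (rows: genotypes, cols: (T,D) blocks), N =",
        sum(object@counts), "\n")
    print(object@counts)
})

# ---------------------------------------------------------------------------
# PopulationParams
# ---------------------------------------------------------------------------

#' Population joint distribution of trait and disease
#'
#' The joint probabilities \eqn{K_{ij} = Pr(T = i, D = j)} in the general
#' population. Marginals are derived: disease prevalence
#' \eqn{f_D = K_{01} + K_{11}} and trait prevalence
#' \eqn{f_T = K_{10} + K_{11}}.
#'
#' @slot K Named numeric vector of length 4 (`T0D0`, `T1D0`, `T0D1`,
#'   `T1D1`); entries in (0, 1) summing to 1.
#' @seealso [populationParams()], [estimateJointProbs()]
#' @export
setClass("PopulationParams", representation(K = "numeric"))

setValidity("PopulationParams", function(object) {
    K <- object@K
    if (length(K) != 4L || anyNA(K)) return("K must be 4 probabilities")
    if (any(K <= 0) || any(K >= 1)) return("all K_ij must lie in (0, 1)")
    if (abs(sum(K) - 1) > 1e-9) return("K_ij must sum to 1 (tol 1e-9)")
    TRUE
})

#' Construct population joint probabilities
#'
#' @param K Numeric vector of length 4: \eqn{K_{00}, K_{10}, K_{01},
#'   K_{11}} in block order `T0D0`, `T1D0`, `T0D1`, `T1D1`.
#' @return A [PopulationParams-class] object.
#' @examples
#' pop <- populationParams(c(0.56, 0.14, 0.16, 0.14))
#' fD(pop); fT(pop)
#' @export
populationParams <- function(K) {
    new("PopulationParams", K = setNames(as.numeric(K), .BLOCKS))
}

#' @describeIn populationParams The joint probabilities \eqn{K_{ij}}.
#' @param x A `PopulationParams` object.
#' @export
jointProbs <- function(x) x@K

#' @describeIn populationParams Disease prevalence \eqn{f_D = K_{01}+K_{11}}.
#' @export
fD <- function(x) unname(x@K[[3]] + x@K[[4]])

#' @describeIn populationParams Trait prevalence \eqn{f_T = K_{10}+K_{11}}.
#' @export
fT <- function(x) unname(x@K[[2]] + x@K[[4]])

setMethod("show", "PopulationParams", function(object) {
    cat("PopulationParams: K =",
        paste(sprintf("%s=%.4f", names(object@K), object@K), collapse = " "),
        sprintf("| f_D = %.4f, f_T = %.4f\n", fD(object), fT(object)))
})

# ---------------------------------------------------------------------------
# HWPTestResult
# ---------------------------------------------------------------------------

#' Result of an HWP test
#'
#' @slot method Character label (`"eLRT"`, `"emHWP"`, `"LRT_d"`, ...).
#' @slot statistic LRT statistic (`NA` for exact/mixture tests).
#' @slot p.value P-value in \[0, 1\] (`NA` if the fit did not converge).
#' @slot converged Logical convergence flag.
#' @slot df Degrees of freedom of the reference distribution (`NA` when not
#'   applicable).
#' @slot logLikNull,logLikAlt Maximised log-likelihoods (`NA` when not
#'   applicable).
#' @slot diagnostics Named list of method-specific diagnostics (iterations,
#'   flags, mixture sample size, KDE bandwidth, ...).
#' @export
setClass("HWPTestResult",
         representation(method = "character", statistic = "numeric",
                        p.value = "numeric", converged = "logical",
                        df = "numeric", logLikNull = "numeric",
                        logLikAlt = "numeric", diagnostics = "list"))

setValidity("HWPTestResult", function(object) {
    p <- object@p.value
    if (length(p) != 1L) return("p.value must be a scalar")
    if (!is.na(p) && (p < 0 || p > 1)) return("p.value must lie in [0, 1]")
    TRUE
})

.testResult <- function(method, statistic = NA_real_, p.value = NA_real_,
                        converged = TRUE, df = NA_real_,
                        logLikNull = NA_real_, logLikAlt = NA_real_,
                        diagnostics = list()) {
    new("HWPTestResult", method = method, statistic = statistic,
        p.value = p.value, converged = converged, df = df,
        logLikNull = logLikNull, logLikAlt = logLikAlt,
        diagnostics = diagnostics)
}

#' @describeIn HWPTestResult-class Extract the p-value.
#' @param x An `HWPTestResult`.
#' @export
pValue <- function(x) x@p.value

#' @describeIn HWPTestResult-class Extract the test statistic.
#' @export
statistic <- function(x) x@statistic

setMethod("show", "HWPTestResult", function(object) {
    cat(sprintf("HWP test [%s]\n", object@method))
    if (!is.na(object@statistic))
        cat(sprintf("  statistic = %.6g (df = %g)\n",
                    object@statistic, object@df))
    cat(sprintf("  p-value   = %.6g\n", object@p.value))
    if (!object@converged) cat("  WARNING: fit did not converge\n")
    fl <- object@diagnostics$flags
    if (!is.null(fl)) cat("  flags:", paste(fl, collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# MixtureConfig
# ---------------------------------------------------------------------------

#' Configuration of the mixture resampling tests
#'
#' @slot M Number of mixture resamples (default 500).
#' @slot gridSize Grid size of the kernel-density mode search (default 512).
#' @slot bandwidth Bandwidth rule, currently `"silverman"` (`bw.nrd0`).
#' @slot kernel Smoothing kernel, currently `"gaussian"`.
#' @slot seed Optional integer seed making a single test call reproducible;
#'   `NA` uses the ambient RNG stream.
#' @export
setClass("MixtureConfig",
         representation(M = "integer", gridSize = "integer",
                        bandwidth = "character", kernel = "character",
                        seed = "integer"))

setValidity("MixtureConfig", function(object) {
    if (object@M < 2L) return("M must be >= 2")
    if (object@gridSize < 128L) return("gridSize must be >= 128")
    TRUE
})

#' Construct a mixture-test configuration
#'
#' @param M Number of mixture resamples.
#' @param gridSize KDE mode-search grid size.
#' @param bandwidth Bandwidth rule identifier.
#' @param kernel Kernel identifier.
#' @param seed Optional integer seed (`NA` = use the current RNG stream).
#' @return A [MixtureConfig-class] object.
#' @export
mixtureConfig <- function(M = 500L, gridSize = 512L,
                          bandwidth = "silverman", kernel = "gaussian",
                          seed = NA_integer_) {
    new("MixtureConfig", M = as.integer(M), gridSize = as.integer(gridSize),
        bandwidth = bandwidth, kernel = kernel, seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# SimulationScenario
# ---------------------------------------------------------------------------

#' Scenario of the two-logistic-model study generator
#'
#' Describes one simulated frequency-matched case-control study: four
#' independent diallelic SNPs in HWP, environmental covariates, a secondary
#' trait generated from a first logistic model and the primary disease from
#' a second logistic model that includes the trait. SNPs enter both models
#' under a dominant coding (carrier of at least one minor allele).
#'
#' Default log-odds follow the canonical pattern: SNP 1 affects both trait
#' and disease (log OR 0.4055 each), SNP 2 disease only, SNP 3 trait only,
#' SNP 4 neither; sex affects the trait (0.6931), ethnicity both (0.4055),
#' age (3 additive bands) the disease (0.4055 per band step), and the trait
#' carries log OR 1.0983 (OR 3) on the disease. Intercepts `NA` mean
#' "calibrate to the target prevalences".
#'
#' @slot maf Minor allele frequency shared by the four SNPs.
#' @slot alpha Trait-model log-odds, `a0` (intercept) through `a7`.
#' @slot beta Disease-model log-odds, `b0` through `b8` (`b8` = trait).
#' @slot sexPrev,ethnPrev Covariate prevalences.
#' @slot agePrev Frequencies of the first two age bands (third is the
#'   remainder).
#' @slot fD,fT Target prevalences of disease and trait.
#' @slot nCases,nControls Study arm sizes.
#' @slot c Frequency-matching tolerance on
#'   \eqn{|Pr(T=1|D=0) - Pr(T=1|D=1)|}.
#' @slot poolSize Size of the simulated population pool.
#' @export
setClass("SimulationScenario",
         representation(maf = "numeric", alpha = "numeric", beta = "numeric",
                        sexPrev = "numeric", ethnPrev = "numeric",
                        agePrev = "numeric", fD = "numeric", fT = "numeric",
                        nCases = "integer", nControls = "integer",
                        c = "numeric", poolSize = "integer"))

setValidity("SimulationScenario", function(object) {
    if (object@maf <= 0 || object@maf >= 1) return("maf must be in (0, 1)")
    if (length(object@alpha) != 8L) return("alpha must be a0..a7")
    if (length(object@beta) != 9L) return("beta must be b0..b8")
    if (any(!is.finite(object@alpha[-1])) || any(!is.finite(object@beta[-1])))
        return("non-intercept coefficients must be finite")
    if (object@fD <= 0 || object@fD >= 1 || object@fT <= 0 || object@fT >= 1)
        return("target prevalences must be in (0, 1)")
    if (object@c < 0) return("matching tolerance c must be >= 0")
    if (sum(object@agePrev) >= 1 || any(object@agePrev <= 0))
        return("age band frequencies invalid")
    TRUE
})

#' Construct a simulation scenario
#'
#' @param maf Minor allele frequency of the four SNPs (e.g., 0.4 or 0.1).
#' @param fD,fT Target prevalences of primary disease and secondary trait.
#' @param nCases,nControls Per-replicate study arm sizes.
#' @param c Frequency-matching tolerance (default 0.02).
#' @param poolSize Population pool size (default 1e6).
#' @param alpha Trait-model log-odds `a0..a7` (`a0 = NA` calibrates the
#'   intercept to `fT`).
#' @param beta Disease-model log-odds `b0..b8` (`b0 = NA` calibrates to
#'   `fD`). Order: intercept, SNP1-4, sex, ethnicity, age, trait.
#' @param sexPrev,ethnPrev,agePrev Covariate prevalences (age: first two of
#'   three additive bands).
#' @return A [SimulationScenario-class] object.
#' @examples
#' scn <- simulationScenario(maf = 0.4, fD = 0.3, fT = 0.3)
#' @export
simulationScenario <- function(maf = 0.4, fD = 0.3, fT = 0.3,
                               nCases = 2000L, nControls = 2000L, c = 0.02,
                               poolSize = 1e6,
                               alpha = c(NA, 0.4055, 0, 0.4055, 0,
                                         0.6931, 0.4055, 0),
                               beta = c(NA, 0.4055, 0.4055, 0, 0,
                                        0, 0.4055, 0.4055, 1.0983),
                               sexPrev = 0.5, ethnPrev = 0.75,
                               agePrev = c(0.36, 0.39)) {
    new("SimulationScenario", maf = maf,
        alpha = setNames(as.numeric(alpha), paste0("a", 0:7)),
        beta = setNames(as.numeric(beta), paste0("b", 0:8)),
        sexPrev = sexPrev, ethnPrev = ethnPrev, agePrev = agePrev,
        fD = fD, fT = fT, nCases = as.integer(nCases),
        nControls = as.integer(nControls), c = c,
        poolSize = as.integer(poolSize))
}

setMethod("show", "SimulationScenario", function(object) {
    cat(sprintf(
        "SimulationScenario: MAF %.2f | f_D %.2f f_T %.2f | %d cases + %d controls, c = %.3g | pool %d\n",
        object@maf, object@fD, object@fT, object@nCases, object@nControls,
        object@c, object@poolSize))
})

# ---------------------------------------------------------------------------
# MixtureAllocation
# ---------------------------------------------------------------------------

#' Per-stratum draw sizes of one mixture sample
#'
#' @slot Nm Mixture sample size.
#' @slot draw Per-block draw sizes, summing to `Nm` and bounded by `source`.
#' @slot source Per-block source sizes \eqn{N_{ij}}.
#' @export
setClass("MixtureAllocation",
         representation(Nm = "integer", draw = "integer", source = "integer"))

setValidity("MixtureAllocation", function(object) {
    if (any(object@draw > object@source)) return("draws exceed block sizes")
    if (sum(object@draw) != object@Nm) return("draws must sum to Nm")
    if (any(object@draw < 0L)) return("draws must be non-negative")
    TRUE
})

setMethod("show", "MixtureAllocation", function(object) {
    cat("MixtureAllocation: Nm =", object@Nm, "| draws:",
        paste(sprintf("%s=%d/%d", .BLOCKS[seq_along(object@draw)],
                      object@draw, object@source), collapse = " "), "\n")
})
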