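#' @include AllClasses.R
NULL

# largest-remainder apportionment of Nm by weights w, capped at `cap`;
# capped excess is re-distributed to the blocks with the next-largest
# remainders that still have slack
.apportion <- function(Nm, w, cap) {
    raw <- w / sum(w) * Nm
    base <- pmin(floor(raw), cap)
    rem <- raw - floor(raw)
    left <- Nm - sum(base)
    # order: remainder desc, then weight desc, then index; cycle until done
    ord <- order(-rem, -w, seq_along(w))
    while (left > 0) {
        slack <- cap - base
        if (all(slack == 0)) stop("apportionment infeasible: caps too tight")
        placed <- FALSE
        for (b in ord) {
            if (left == 0) break
            if (slack[b] > 0) {
                add <- min(1, left, slack[b])
                base[b] <- base[b] + add
                left <- left - add
                placed <- TRUE
            }
        }
        if (!placed) stop("apportionment infeasible")
    }
    as.integer(base)
}

#' Mixture sample size and per-stratum draw allocation
#'
#' Determines the largest mixture sample that the four (trait, disease)
#' blocks of a frequency-matched study can support while matching the
#' population joint probabilities \eqn{K_{ij}}: the mixture size is
#' \eqn{N_m = \lfloor \min_{ij} N_{ij}/K_{ij} \rfloor}, and the per-block
#' draw sizes apportion \eqn{N_m} by \eqn{K_{ij}} (largest-remainder
#' rounding, capped at the available \eqn{N_{ij}}).
#'
#' @param blockSizes Per-block sample sizes \eqn{N_{ij}} (length 4, order
#'   `T0D0`, `T1D0`, `T0D1`, `T1D1`), or a [BlockCounts-class] object.
#' @param pop A [PopulationParams-class] object.
#' @return A [MixtureAllocation-class] object.
#' @examples
#' pop <- populationParams(c(0.40, 0.20, 0.25, 0.15))
#' mixtureAllocation(c(500, 500, 500, 500), pop)
#' @export
mixtureAllocation <- function(blockSizes, pop) {
    stopifnot(is(pop, "PopulationParams"))
    N <- if (is(blockSizes, "BlockCounts")) blockTotals(blockSizes)
         else as.numeric(blockSizes)
    stopifnot(length(N) == 4L, all(N >= 0))
    K <- unname(pop@K)
    if (any(N == 0))
        stop("design cannot represent population: empty (T,D) block")
    Nm <- as.integer(floor(min(N / K)))
    if (Nm < 1) stop("design cannot represent population: mixture size 0")
    draw <- .apportion(Nm, K, as.integer(N))
    new("MixtureAllocation", Nm = Nm, draw = draw,
        source = as.integer(N))
}

#' Draw one mixture sample's genotype counts
#'
#' Samples `alloc@draw[b]` individuals without replacement within each
#' block (multivariate hypergeometric on the block's genotype triple) and
#' pools the counts. Uses the ambient R random-number stream.
#'
#' @param blocks A [BlockCounts-class] object.
#' @param alloc A [MixtureAllocation-class] for these blocks.
#' @return A [GenotypeCounts-class] with the pooled mixture counts.
#' @export
drawMixtureCounts <- function(blocks, alloc) {
    stopifnot(is(blocks, "BlockCounts"), is(alloc, "MixtureAllocation"))
    if (!all(blockTotals(blocks) == alloc@source))
        stop("allocation does not match block sizes")
    g <- mixtureDrawC(blocks@counts, alloc@draw)
    genotypeCounts(g[1], g[2], g[3])
}

#' Mode of the kernel-density estimate of a p-value sample
#'
#' Gaussian kernel density with Silverman's rule-of-thumb bandwidth,
#' evaluated on a fixed grid spanning the sample; the mode is the grid
#' argmax, clipped into \[0, 1\]. No boundary reflection is applied:
#' under a heavy pile-up of small p-values, reflecting mass at 0 doubles
#' the apparent density there and drags the mode onto the boundary, so the
#' un-reflected estimate (whose leakage beyond 0 instead damps the edge) is
#' the calibrated choice for this estimator. Degenerate samples (all
#' values equal, or zero bandwidth) return the common value.
#'
#' @param pvalues Numeric vector of at least 2 values in \[0, 1\].
#' @param gridSize Number of grid points (>= 128).
#' @return The estimated mode, in \[0, 1\].
#' @examples
#' set.seed(1)
#' kdeMode(rbeta(500, 20, 20))   # close to 0.5
#' @export
kdeMode <- function(pvalues, gridSize = 512L) {
    x <- as.numeric(pvalues)
    stopifnot(length(x) >= 2L, all(x >= 0), all(x <= 1), gridSize >= 128L)
    if (length(unique(x)) == 1L) return(x[1])
    bw <- tryCatch(bw.nrd0(x), error = function(e) 0)
    if (!is.finite(bw) || bw <= 0) return(x[1])
    d <- density(x, bw = bw, kernel = "gaussian", n = as.integer(gridSize))
    mode <- d$x[which.max(d$y)]
    min(max(mode, 0), 1)
}

# run a seeded block without disturbing the caller's RNG stream when a
# seed is requested; otherwise consume the ambient stream
.withSeed <- function(seed, expr) {
    if (is.na(seed)) return(expr)
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
    expr
}

#' Extended mixture HWP exact test (emHWP)
#'
#' Tests Hardy-Weinberg proportions in the general population by physical
#' resampling: `M` mixture samples are drawn from the four (trait, disease)
#' blocks at the population proportions \eqn{K_{ij}} (see
#' [mixtureAllocation]), the allele-count-conditional exact HWP p-value is
#' computed for each, and the final p-value is the mode of the
#' kernel-density estimate of the `M` p-values (the maximum-likelihood
#' point of their empirical distribution).
#'
#' @param blocks A [BlockCounts-class] object.
#' @param pop A [PopulationParams-class] object.
#' @param cfg A [MixtureConfig-class]; `cfg@seed` (if not `NA`) makes the
#'   result reproducible in isolation.
#' @return An [HWPTestResult-class] with `statistic = NA` and diagnostics
#'   `Nm`, `draw`, `M`, and `bw` (KDE bandwidth).
#' @examples
#' pop <- populationParams(c(0.56, 0.14, 0.16, 0.14))
#' bl <- blockCounts(c(330, 490, 180), c(160, 230, 110),
#'                   c(300, 470, 230), c(290, 500, 210))
#' emhwpTest(bl, pop, mixtureConfig(seed = 7))
#' @export
emhwpTest <- function(blocks, pop, cfg = mixtureConfig()) {
    stopifnot(is(blocks, "BlockCounts"), is(pop, "PopulationParams"),
              is(cfg, "MixtureConfig"))
    alloc <- mixtureAllocation(blocks, pop)
    pv <- .withSeed(cfg@seed,
                    mixturePvaluesC(blocks@counts, alloc@draw, cfg@M))
    p <- kdeMode(pv, cfg@gridSize)
    .testResult("emHWP", p.value = p,
                diagnostics = list(Nm = alloc@Nm, draw = alloc@draw,
                                   M = cfg@M,
                                   bw = tryCatch(bw.nrd0(pv),
                                                 error = function(e) NA)))
}

#' Two-stratum mixture HWP exact test (mHWP)
#'
#' The baseline mixture exact test for an unmatched case-control sample:
#' mixture samples combine cases and controls at the population prevalence
#' `f` of the stratifying phenotype, with mixture size
#' \eqn{N_m = \lfloor \min(m/(1-f), n/f) \rfloor} (m controls, n cases) and
#' case draw `round(Nm * f)`. P-value estimation is as in [emhwpTest].
#'
#' @param cases,controls [GenotypeCounts-class] objects or length-3 count
#'   vectors.
#' @param f Population prevalence of the stratifying phenotype.
#' @inheritParams emhwpTest
#' @return An [HWPTestResult-class].
#' @export
mhwpTest <- function(cases, controls, f, cfg = mixtureConfig()) {
    stopifnot(is.numeric(f), length(f) == 1L, f > 0, f < 1,
              is(cfg, "MixtureConfig"))
    ca <- .asCounts3(cases); co <- .asCounts3(controls)
    n <- sum(ca); m <- sum(co)
    if (n < 1 || m < 1) stop("empty group")
    Nm <- floor(min(m / (1 - f), n / f))
    if (Nm < 1) stop("mixture sample size 0")
    nCase <- min(round(Nm * f), n)
    nCtrl <- min(Nm - nCase, m)
    Nm <- as.integer(nCase + nCtrl)
    cm <- cbind(co, ca); storage.mode(cm) <- "integer"
    pv <- .withSeed(cfg@seed,
                    mixturePvaluesC(cm, as.integer(c(nCtrl, nCase)), cfg@M))
    p <- kdeMode(pv, cfg@gridSize)
    .testResult("mHWP", p.value = p,
                diagnostics = list(Nm = Nm, draw = c(nCtrl, nCase),
                                   M = cfg@M,
                                   bw = tryCatch(bw.nrd0(pv),
                                                 error = function(e) NA)))
}
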