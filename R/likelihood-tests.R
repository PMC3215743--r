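#' @include AllClasses.R
NULL

# saturated product-multinomial log-likelihood of a genotype count matrix
# (columns = strata); empty strata and zero cells contribute 0
.satLogLik <- function(m) {
    tot <- colSums(m)
    ll <- 0
    for (j in seq_len(ncol(m))) {
        if (tot[j] == 0) next
        nz <- m[, j] > 0
        ll <- ll + sum(m[nz, j] * log(m[nz, j] / tot[j]))
    }
    ll
}

.hwpP <- function(p) c(p^2, 2 * p * (1 - p), (1 - p)^2)

# deterministic start perturbation: keeps the fitters RNG-silent so that
# simulation streams do not depend on optimizer restarts
.perturb <- function(theta, k) {
    s <- rep_len(c(1, -1), length(theta)) * (-1)^k
    theta + 0.35 * k * s * seq(0.5, 1.5, length.out = length(theta))
}

.clampLog <- function(x, lim = 10) pmin(pmax(x, -lim), lim)

# data-driven starting point of the four-stratum null fit
.elrtStart <- function(counts, K, elim) {
    q <- sweep(counts + 0.5, 2, colSums(counts) + 1.5, "/")
    Phat <- as.numeric(q %*% K)
    phat <- min(max(Phat[1] + Phat[2] / 2, 0.005), 0.995)
    P <- .hwpP(phat)
    th <- qlogis(phat)
    for (b in seq_len(4)[-elim]) {
        r1 <- (q[2, b] / q[1, b]) / (P[2] / P[1])
        r2 <- (q[3, b] / q[1, b]) / (P[3] / P[1])
        th <- c(th, .clampLog(log(r1)), .clampLog(log(r2)))
    }
    th
}

.lrtStart <- function(counts, f) {
    q <- sweep(counts + 0.5, 2, colSums(counts) + 1.5, "/")
    Phat <- (1 - f) * q[, 1] + f * q[, 2]
    phat <- min(max(Phat[1] + Phat[2] / 2, 0.005), 0.995)
    P <- .hwpP(phat)
    c(qlogis(phat),
      .clampLog(log((q[2, 2] / q[1, 2]) / (P[2] / P[1]))),
      .clampLog(log((q[3, 2] / q[1, 2]) / (P[3] / P[1]))))
}

# multi-start null fit; fit() maps a start vector to list(value, fail, ...)
.multiStart <- function(fit, starts0, maxTries = 5L) {
    best <- NULL
    tried <- 0L
    for (th in starts0) {
        res <- fit(th)
        tried <- tried + 1L
        if (is.null(best) || res$value < best$value) best <- res
    }
    k <- 1L
    while ((best$fail != 0L || best$value >= 1e7) && k <= maxTries) {
        # first retry polishes from the incumbent (a fresh simplex there
        # usually converges); later retries perturb deterministically
        th <- if (k == 1L) best$par else .perturb(best$par, k - 1L)
        res <- fit(th)
        tried <- tried + 1L
        if (res$value <= best$value) best <- res
        k <- k + 1L
    }
    best$starts <- tried
    best
}

.degenerate <- function(method, note) {
    .testResult(method, statistic = 0, p.value = 1, converged = TRUE, df = 1,
                diagnostics = list(flags = note))
}

#' Extended likelihood-ratio test of HWP for a frequency-matched study
#'
#' Tests Hardy-Weinberg proportions in the general population using all
#' four (trait, disease) sampling strata of a case-control study
#' frequency-matched on a secondary phenotype. Within stratum (i, j) the
#' genotype distribution is \eqn{Pr(X=k | T=i, D=j) = r_{ijk} P_k / (P_0 +
#' r_{ij1} P_1 + r_{ij2} P_2)} with genotype relative risks
#' \eqn{r_{ijk} = p_{ij|k}/p_{ij|0}}, and the known population joint
#' probabilities \eqn{K_{ij}} tie the strata together through
#' \eqn{\sum_{ij} K_{ij} Pr(X=k|T=i,D=j) = P_k}. The alternative leaves the
#' genotype frequencies \eqn{(P_0, P_1, P_2)} free (8 free parameters); the
#' null constrains them to HWP, \eqn{P_1 = 2p(1-p)}, \eqn{P_2 = (1-p)^2}
#' (7 free parameters). Twice the log-likelihood-ratio is referred to a
#' one-degree-of-freedom chi-square distribution.
#'
#' The alternative is saturated, so its maximum is computed in closed form;
#' the null is maximised by a Nelder-Mead simplex search in unconstrained
#' coordinates (logit allele frequency, log relative risks of three blocks,
#' the fourth block recovered from the population constraint), with
#' deterministic multi-start on non-convergence.
#'
#' @param blocks A [BlockCounts-class] object (strata `T0D0`, `T1D0`,
#'   `T0D1`, `T1D1`).
#' @param pop A [PopulationParams-class] object with the population
#'   \eqn{K_{ij}}.
#' @param maxit,reltol Simplex iteration cap and relative function
#'   tolerance per start.
#' @return An [HWPTestResult-class]; markers with fewer than two observed
#'   genotype classes return p = 1 with a `"degenerate"` flag.
#' @examples
#' pop <- populationParams(c(0.56, 0.14, 0.16, 0.14))
#' bl <- blockCounts(c(330, 490, 180), c(160, 230, 110),
#'                   c(300, 470, 230), c(290, 500, 210))
#' fitELRT(bl, pop)
#' @export
fitELRT <- function(blocks, pop, maxit = 5000L, reltol = 1e-10) {
    stopifnot(is(blocks, "BlockCounts"), is(pop, "PopulationParams"))
    m <- blocks@counts
    if (sum(m) < 1) stop("empty sample")
    if (sum(rowSums(m) > 0) < 2L)
        return(.degenerate("eLRT", "degenerate"))
    K <- unname(pop@K)
    if (any(K <= 0 & colSums(m) > 0)) stop("infeasible population parameters")
    elim <- which.max(K)
    llAlt <- .satLogLik(m)
    cm <- m; storage.mode(cm) <- "double"
    fit <- function(th) elrtNullFitC(cm, K, elim - 1L, th, maxit, reltol)
    th1 <- .elrtStart(m, K, elim)
    best <- .multiStart(fit, list(th1, c(th1[1], rep(0, 6))))
    llNull <- -best$value
    stat <- 2 * (llAlt - llNull)
    conv <- best$fail == 0L && best$value < 1e7 && stat > -1e-4
    stat <- max(stat, 0)
    .testResult("eLRT", statistic = stat,
                p.value = if (conv) pchisq(stat, 1, lower.tail = FALSE)
                          else NA_real_,
                converged = conv, df = 1,
                logLikNull = llNull, logLikAlt = llAlt,
                diagnostics = list(iterations = best$fncount,
                                   starts = best$starts,
                                   maf.null = min(plogis(best$par[1]),
                                                  1 - plogis(best$par[1]))))
}

#' Two-stratum likelihood-ratio test of HWP with a prevalence constraint
#'
#' The baseline likelihood-ratio test of Hardy-Weinberg proportions for an
#' (unmatched) case-control sample: genotype counts in two strata (e.g.,
#' disease cases and controls, or trait present/absent), with the known
#' prevalence `f` of the stratifying phenotype tying the two strata to the
#' population genotype frequencies. The alternative has 4 free parameters
#' (genotype frequencies plus two case relative risks), the null 3 (HWP
#' allele frequency plus the risks); the statistic is referred to
#' chi-square(1).
#'
#' @param controls,cases [GenotypeCounts-class] objects or length-3 count
#'   vectors for the stratum-absent and stratum-present groups.
#' @param f Population prevalence of the stratifying phenotype, in (0, 1).
#' @inheritParams fitELRT
#' @return An [HWPTestResult-class].
#' @examples
#' fitLRT(controls = c(520, 710, 290), cases = c(600, 640, 260), f = 0.3)
#' @export
fitLRT <- function(controls, cases, f, maxit = 5000L, reltol = 1e-10) {
    stopifnot(is.numeric(f), length(f) == 1L, f > 0, f < 1)
    m <- cbind(.asCounts3(controls), .asCounts3(cases))
    dimnames(m) <- list(.GENOS, c("0", "1"))
    if (sum(m) < 1) stop("empty sample")
    if (sum(rowSums(m) > 0) < 2L)
        return(.degenerate("LRT", "degenerate"))
    llAlt <- .satLogLik(m)
    cm <- m; storage.mode(cm) <- "double"
    fit <- function(th) lrtNullFitC(cm, f, th, maxit, reltol)
    best <- .multiStart(fit, list(.lrtStart(m, f),
                                  c(.lrtStart(m, f)[1], 0, 0)))
    llNull <- -best$value
    stat <- 2 * (llAlt - llNull)
    conv <- best$fail == 0L && best$value < 1e7 && stat > -1e-4
    stat <- max(stat, 0)
    .testResult("LRT", statistic = stat,
                p.value = if (conv) pchisq(stat, 1, lower.tail = FALSE)
                          else NA_real_,
                converged = conv, df = 1,
                logLikNull = llNull, logLikAlt = llAlt,
                diagnostics = list(iterations = best$fncount,
                                   starts = best$starts,
                                   maf.null = min(plogis(best$par[1]),
                                                  1 - plogis(best$par[1]))))
}

#' Stratified retrospective negative log-likelihood
#'
#' Evaluates the negative log-likelihood of stratified genotype counts
#' under the relative-risk parametrization used by [fitLRT] and [fitELRT].
#' Within each stratum the genotype distribution is
#' \eqn{q_b(k) = r_{bk} P_k / (P_0 + r_{b1} P_1 + r_{b2} P_2)} with
#' \eqn{r_{b0} = 1}. Zero-count cells contribute zero regardless of the
#' cell probability; a positive count on a zero-probability cell yields
#' `+Inf` (so optimizers retreat rather than error).
#'
#' @param params A list with either `P` (genotype frequencies, length 3,
#'   summing to 1) or -- when `nullConstrained = TRUE` -- `p` (a single
#'   allele frequency, expanded as \eqn{p^2, 2p(1-p), (1-p)^2}), plus `r`:
#'   a matrix of relative risks with one row per stratum and columns
#'   \eqn{(r_1, r_2)} (a single stratum may pass a length-2 vector).
#' @param counts Genotype counts: a [BlockCounts-class] (four strata), or a
#'   3-column-per-stratum matrix (rows AA, Aa, aa).
#' @param model `"four_stratum"` or `"two_stratum"` (only used for
#'   dimension checks).
#' @param nullConstrained Interpret `params$p` as the HWP allele frequency.
#' @return The scalar negative log-likelihood.
#' @examples
#' bl <- blockCounts(c(40, 40, 20), c(10, 20, 10),
#'                   c(20, 30, 10), c(15, 20, 10))
#' negLogLikelihood(list(p = 0.5, r = matrix(1, 4, 2)), bl)
#' @export
negLogLikelihood <- function(params, counts,
                             model = c("four_stratum", "two_stratum"),
                             nullConstrained = !is.null(params$p)) {
    model <- match.arg(model)
    m <- if (is(counts, "BlockCounts")) counts@counts else as.matrix(counts)
    P <- if (nullConstrained) {
        stopifnot(!is.null(params$p), params$p > 0, params$p < 1)
        .hwpP(params$p)
    } else {
        stopifnot(abs(sum(params$P) - 1) < 1e-8, all(params$P >= 0))
        params$P
    }
    r <- params$r
    if (is.null(dim(r))) r <- matrix(r, nrow = 1)
    nb <- ncol(m)
    stopifnot(nrow(r) == nb, ncol(r) == 2, all(r >= 0))
    if (model == "four_stratum" && nb != 4L)
        stop("four_stratum model expects 4 strata")
    nll <- 0
    for (b in seq_len(nb)) {
        S <- P[1] + r[b, 1] * P[2] + r[b, 2] * P[3]
        q <- c(P[1], r[b, 1] * P[2], r[b, 2] * P[3]) / S
        nz <- m[, b] > 0
        if (any(nz & q <= 0)) return(Inf)
        nll <- nll - sum(m[nz, b] * log(q[nz]))
    }
    nll
}

#' Minimise a likelihood objective by a Nelder-Mead simplex search
#'
#' Thin multi-restart wrapper around the simplex optimizer used by the
#' likelihood tests, exposed so parametrized objectives (e.g., built on
#' [negLogLikelihood]) can be minimised with the same convergence policy:
#' restart from the incumbent until the objective improves by less than
#' `fixTol` (fixed-point criterion) or `restarts` is exhausted.
#'
#' @param objective Function of a numeric parameter vector; must be finite
#'   at `start`.
#' @param start Numeric starting vector.
#' @param maxit Iteration cap per start.
#' @param reltol Relative convergence tolerance.
#' @param restarts Maximum number of restarts from the incumbent.
#' @param fixTol Improvement threshold ending the restart loop.
#' @return A list with `par`, `value`, `converged`, and `fncount`.
#' @examples
#' maximizeLikelihood(function(x) sum((x - 2)^2), c(0, 0))$par
#' @export
maximizeLikelihood <- function(objective, start, maxit = 5000L,
                               reltol = 1e-10, restarts = 5L,
                               fixTol = 1e-6) {
    f0 <- objective(start)
    if (!is.finite(f0)) stop("objective not finite at start")
    cur <- list(par = start, value = f0)
    conv <- FALSE
    total <- 0L
    for (i in seq_len(restarts + 1L)) {
        op <- optim(cur$par, objective, method = "Nelder-Mead",
                    control = list(maxit = maxit, reltol = reltol))
        total <- total + op$counts[[1]]
        if (cur$value - op$value < fixTol && op$convergence == 0L) {
            conv <- TRUE
            if (op$value <= cur$value) cur <- op
            break
        }
        if (op$value <= cur$value) cur <- op
    }
    list(par = cur$par, value = cur$value, converged = conv,
         fncount = total)
}
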