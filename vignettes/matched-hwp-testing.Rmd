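---
title: "Testing Hardy-Weinberg proportions under frequency matching"
author: "matchedHWP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing Hardy-Weinberg proportions under frequency matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matchedHWP)
```

## The problem

Genetic association studies screen every marker for deviation from
Hardy-Weinberg proportions (HWP) before analysis: a marker whose genotype
frequencies depart from $P_0 = p^2$, $P_1 = 2p(1-p)$, $P_2 = (1-p)^2$ in
the *general population* is suspected of genotyping error and removed. The
catch is that HWP holds (or not) in the population, while the data come
from a case-control sample. When the primary disease $D$ is common,
controls are not a random draw from the population, and running the test
on controls alone rejects disease-associated markers far too often —
discarding exactly the variants the study was designed to find.

Two-stratum corrections exist for plain case-control designs: a
likelihood-ratio test that ties the case and control genotype
distributions to the population through the known disease prevalence, and
a mixture exact test that re-pools cases and controls at their population
proportions. Both assume the two strata were sampled on $D$ alone.

Many studies, however, are *frequency-matched* on a secondary phenotype
$T$ (smoking status in lung-cancer studies, say): controls are drawn so
that $|\Pr(T{=}1|D{=}0) - \Pr(T{=}1|D{=}1)| \le c$ for a small $c$. The
sample then over-represents individuals with the trait relative to its
population prevalence, and any marker associated with $T$ — or with $D$,
since $T$ and $D$ are correlated — looks HWP-distorted to the two-stratum
tests. This package implements the four-stratum extensions that repair
this: the extended likelihood-ratio test (eLRT) and the extended mixture
HWP exact test (emHWP), together with the two-stratum baselines, the exact
test kernel, a generator of synthetic frequency-matched studies, and a
Monte-Carlo study driver.

## The four-stratum likelihood

Sampling is stratified on the four cells $(T{=}i, D{=}j)$. Within block
$(i,j)$, genotypes $X \in \{0,1,2\}$ are multinomial with

$$\Pr(X{=}k \mid T{=}i, D{=}j) \;=\; \frac{r_{ijk} P_k}{P_0 + r_{ij1}P_1 + r_{ij2}P_2},$$

where $r_{ijk} = p_{ij|k}/p_{ij|0}$ are genotype relative risks
($r_{ij0} = 1$) and $p_{ij|k} = \Pr(T{=}i, D{=}j \mid X{=}k)$. The known
population joint probabilities $K_{ij}$ enter through the constraints
$\sum_{ij} p_{ij|k} = 1$, equivalently
$\sum_{ij} K_{ij} \Pr(X{=}k|T{=}i,D{=}j) = P_k$ for every genotype $k$
(only two of the three are independent, because the $K_{ij}$ sum to one).
Counting parameters: three genotype frequencies on the simplex (2 free)
plus eight relative risks, minus the two independent constraints — 8 free
parameters under the alternative. The null adds HWP, $P_1 = 2p(1-p)$ and
$P_2 = (1-p)^2$, leaving 7. Twice the log-likelihood ratio is referred to
$\chi^2_1$.

The two-stratum baseline is the same construction with a single margin:
$\Pr(X{=}k|j) = r_{jk}P_k / (P_0 + r_{j1}P_1 + r_{j2}P_2)$ and prevalence
$f$ in place of the $K_{ij}$; 4 free parameters under the alternative, 3
under the null.

### Why the alternative needs no optimizer

The alternative's 8 free parameters equal the data's degrees of freedom
(four blocks, two free genotype proportions each), and the map is onto:
given arbitrary per-block genotype distributions $q_{ij}$, setting
$P_k = \sum_{ij} K_{ij}\, q_{ij}(k)$ and
$r_{ijk} = \big(q_{ij}(k)/q_{ij}(0)\big)\big(P_0/P_k\big)$ satisfies every
constraint. The alternative maximum is therefore the saturated
product-multinomial log-likelihood
$\sum_{ij}\sum_k N_{ijk}\log(N_{ijk}/N_{ij})$, which `fitELRT` evaluates
in closed form; a numeric optimization of the constrained parametrization
is kept in the test suite and reproduces this value. The same argument
applies to the two-stratum model. Only the null requires iteration, and
because the null is nested inside a closed-form alternative, the estimated
statistic can only err upward (an under-converged null fit inflates, never
deflates, the statistic) — which is why the null fit gets the multi-start
treatment below.

### Null fit: parametrization and convergence policy

The null is maximised by a Nelder-Mead simplex search in unconstrained
coordinates: $\mathrm{logit}(p)$ for the allele frequency and
$\log r_{ijk}$ for three of the four blocks; the fourth block's genotype
distribution (the block with the largest $K_{ij}$, which has the most
slack) is recovered from the population constraint and a soft penalty
keeps it non-negative. This realises exactly 7 free parameters without
constraint handling inside the optimizer. Settings: relative function
tolerance $10^{-10}$, iteration cap 5000 per start. The first start is
data-driven ($p$ from the constraint-weighted allele frequency, risks from
smoothed block proportions), a neutral start (all $r = 1$) is always tried
as well, and on non-convergence the fit restarts from the incumbent and
then from deterministically perturbed points. Perturbations are
deterministic on purpose: fits never consume random numbers, so simulation
streams are reproducible regardless of optimizer behaviour. Markers with
fewer than two observed genotype classes are returned as `p = 1` with a
`degenerate` flag rather than optimized.

## The mixture tests

The emHWP test avoids likelihood machinery entirely: build a subsample
that *is* (approximately) a general-population sample, and run the plain
exact test on it. The mixture size is
$N_m = \lfloor \min_{ij} N_{ij}/K_{ij} \rfloor$ — the largest sample whose
block quotas $K_{ij}N_m$ all fit inside the available blocks — and the
quotas are apportioned by largest remainder, capped at the block sizes.
Individuals are drawn without replacement within blocks, which at the
genotype-count level is a multivariate hypergeometric draw (equivalent in
distribution to per-individual sampling, and much faster). Each of $M$
(default 500) mixture samples yields an allele-count-conditional exact HWP
p-value; the reported p-value is the mode of the kernel-density estimate
of those $M$ values — the maximum-likelihood point of their empirical
distribution. The two-stratum `mhwpTest` is the same pipeline with
$N_m = \lfloor\min(m/(1-f),\, n/f)\rfloor$ and a case quota of
$\mathrm{round}(N_m f)$.

### The exact test kernel

Conditional on the observed allele counts, the probability of every
attainable heterozygote count is computed by a two-sided recurrence from
the conditional mode (no factorials, no overflow) and the p-value sums all
configurations no more probable than the observed one, with a relative tie
tolerance of $10^{-12}$ and the observed configuration always included —
so $p > 0$ and a monomorphic marker returns $p = 1$. The test is symmetric
in allele labels. `logHweProb` exposes the same distribution through a
cached log-factorial table with an explicit log-sum-exp normalization,
which keeps the probabilities summing to 1 to summation precision even at
$n = 5000$.

### Mode estimation: why no boundary reflection

The kernel density uses a Gaussian kernel with Silverman's rule-of-thumb
bandwidth on a 512-point grid, and the mode is the grid argmax clipped to
$[0,1]$. We deliberately do **not** reflect mass at the boundaries.
Reflection is the textbook correction for estimating a *density* on a
bounded support, but here the estimand is the arg-max: when the $M$
p-values pile up near 0 (the interesting case), reflection doubles the
apparent density at 0 and parks the mode on the boundary, which in our
calibration experiments roughly doubled the test's type-I error at
$\alpha = 0.05$ and inflated it by orders of magnitude at
$\alpha = 10^{-4}$. The un-reflected estimator, whose smoothing leakage
beyond 0 instead damps the edge, reproduces the expected nominal behaviour
(the package's acceptance checks measure exactly this). Degenerate samples
(all values equal) return the common value directly.

## The synthetic study generator

`simulatePopulation` emulates a population in which a secondary trait and
a primary disease arise from two logistic models: four independent SNPs in
HWP (dominant coding — carrier of at least one minor allele), sex
(prevalence 50%), ethnicity (75%), and a three-band age factor entering
additively. The default log-odds give the canonical association pattern —
SNP 1 affects trait and disease (OR 1.5 each), SNP 2 disease only, SNP 3
trait only, SNP 4 neither; sex affects the trait (OR 2), ethnicity both
(OR 1.5), age the disease (OR 1.5 per band), and the trait itself carries
OR 3 on the disease. Since all SNPs are generated in HWP, every rejection
in the study runner is a type-I error, whatever the marker's association
pattern.

Decisions where the design was open:

* **Age bands.** Frequencies 36% / 39% / 25% for bands 0-30 / 31-50 /
  older, coded 0/1/2 with one additive log-odds step; the third band is
  the implied remainder of the first two.
* **Intercepts.** $\alpha_0$ and $\beta_0$ are calibrated by bisection on
  the *expected* prevalence over the generated pool (mean of
  $\mathrm{logit}^{-1}$ over individuals), trait first, then disease with
  the trait regenerated; the expectation is hit exactly, so realized
  prevalences deviate only by binomial noise.
* **Matching.** A replicate draws `nCases` cases, computes their trait
  fraction $q_1$, draws the control target $q_0 \sim
  U(q_1 - c,\, q_1 + c)$ truncated to $[0,1]$ (re-drawn once if rounding
  would break the inequality), and samples
  $\mathrm{round}(q_0\, n_{\mathrm{controls}})$ controls with the trait.
  Every generated design satisfies $|q_0 - q_1| \le c + 1/n$.
* **Population pool.** One pool per scenario (default $10^6$), from which
  $K_{ij}$ are estimated once and all replicates are drawn.

What the generator does *not* emulate: linkage disequilibrium between
markers, genotyping error mechanisms, continuous secondary phenotypes, or
gene-trait interaction effects on the disease. Calibration results on
these synthetic studies therefore say nothing about robustness to, e.g.,
differential genotyping error — they establish that the tests hold their
level under the matching mechanism itself.

## Problem sizes, reproducibility, and known limitations

The package's own calibration checks run the full pipeline at reduced
scale: 800-5000 replicates per scenario (the reference rates they are
compared against come from million-replicate runs of the same design), and
comparisons are made in Monte-Carlo standard-error units.
`scripts/acceptance.R` recomputes the headline rates at 5000 replicates
per scenario with a $4\times10^6$ pool.

Two numerical points deserve emphasis:

* **Shared-pool inheritance.** Because all replicates of a scenario are
  drawn from one finite pool, the pool's own sampling deviation from HWP
  is inherited by every replicate as a common shift of size
  $\sqrt{n_{\mathrm{rep}}/n_{\mathrm{pool}}}$ standard units. For the
  already-inflated baseline tests, whose rejection rates sit on the steep
  part of the power curve, this adds a seed-to-seed spread beyond binomial
  noise (≈0.015 at a $10^6$ pool for the trait-stratified LRT).
  The larger default pool in the acceptance script exists to damp this
  term; it does not move any rate's center.
* **Replicate failure policy.** The study runner counts per-replicate
  method failures (e.g., a flagged non-converged fit), excludes them from
  the denominator while they stay below 0.1%, and aborts beyond that.

Known limitations, consistent with what the calibration runs show: the
emHWP test grows conservative when the trait or disease is very common
(the binding block shrinks $N_m$, discretising the p-values), and the eLRT
inherits the usual $\chi^2$ approximation caveats for rare alleles at very
small $\alpha$. The mixture tests report no statistic, only a p-value, and
the package provides no confidence interval on the KDE mode. Prevalence
inputs ($K_{ij}$, $f$) are treated as known; `perturbPopulationParams`
exists to study sensitivity to their misspecification.
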