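#include <Rcpp.h>
#include <R_ext/Applic.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// log-factorial table, grown on demand and cached for the whole batch
// ---------------------------------------------------------------------------

static std::vector<double> lf_tab(1, 0.0);

static void ensure_lf(int n) {
    int old = (int) lf_tab.size();
    if (n < old) return;
    lf_tab.resize(n + 1);
    for (int i = old; i <= n; ++i) lf_tab[i] = lf_tab[i - 1] + std::log((double) i);
}

static double log_hwe_term(int h, int nA, int n) {
    long nB = 2L * n - nA;
    int homA = (nA - h) / 2;          // homozygotes for the allele counted by nA
    int homB = n - h - homA;
    return lf_tab[n] - lf_tab[homA] - lf_tab[h] - lf_tab[homB]
        + h * M_LN2 + lf_tab[nA] + lf_tab[(size_t) nB] - lf_tab[2 * n];
}

// [[Rcpp::export(rng = false)]]
double logHweProbC(int h, int nA, int n) {
    if (n < 0 || nA < 0 || nA > 2 * n)
        stop("invalid allele/sample counts");
    if ((h % 2) != (nA % 2))
        stop("heterozygote count parity inconsistent with allele count");
    long nB = 2L * n - nA;
    if (h < 0 || h > nA || h > nB)
        stop("heterozygote count out of range");
    ensure_lf(2 * n);
    // normalise explicitly (log-sum-exp over attainable h) so that the
    // conditional distribution sums to 1 to summation precision
    int hmin = nA % 2;
    int hmax = (int) std::min((long) nA, nB);
    double mx = R_NegInf;
    for (int hh = hmin; hh <= hmax; hh += 2)
        mx = std::max(mx, log_hwe_term(hh, nA, n));
    double z = 0.0;
    for (int hh = hmin; hh <= hmax; hh += 2)
        z += std::exp(log_hwe_term(hh, nA, n) - mx);
    return log_hwe_term(h, nA, n) - mx - std::log(z);
}

// ---------------------------------------------------------------------------
// allele-count-conditional exact HWP p-value
//
// Probabilities over the attainable heterozygote counts are built by the
// stable two-sided recurrence from the conditional mode, then normalised;
// the p-value sums every configuration whose probability is <= that of the
// observed one (relative tie tolerance 1e-12, observed always included).
// ---------------------------------------------------------------------------

static double hwe_exact_p(long nAA, long nAa, long naa) {
    long n = nAA + nAa + naa;
    if (n < 1) stop("empty sample");
    long a1 = 2L * nAA + nAa;
    long rare = std::min(a1, 2L * n - a1);
    long hmin = rare % 2;
    long hmax = std::min(rare, 2L * n - rare);
    int m = (int) ((hmax - hmin) / 2 + 1);
    if (m <= 1) return 1.0;

    std::vector<double> pr(m, 0.0);
    // start near the conditional mode (expected het count given allele counts)
    long mid = (long) std::floor((double) rare * (2.0 * n - rare) / (2.0 * n));
    if ((mid % 2) != (rare % 2)) mid++;
    if (mid > hmax) mid = hmax;
    if (mid < hmin) mid = hmin;
    pr[(mid - hmin) / 2] = 1.0;

    for (long h = mid; h - 2 >= hmin; h -= 2) {
        double homr = (rare - h) / 2.0;
        double homc = n - h - homr;
        pr[(h - 2 - hmin) / 2] = pr[(h - hmin) / 2] *
            h * (h - 1.0) / (4.0 * (homr + 1.0) * (homc + 1.0));
    }
    for (long h = mid; h + 2 <= hmax; h += 2) {
        double homr = (rare - h) / 2.0;
        double homc = n - h - homr;
        pr[(h + 2 - hmin) / 2] = pr[(h - hmin) / 2] *
            4.0 * homr * homc / ((h + 2.0) * (h + 1.0));
    }

    double tot = 0.0;
    for (int i = 0; i < m; ++i) tot += pr[i];
    double pobs = pr[(nAa - hmin) / 2];
    double cut = pobs * (1.0 + 1e-12);
    double tail = 0.0;
    for (int i = 0; i < m; ++i) if (pr[i] <= cut) tail += pr[i];
    double p = tail / tot;
    return p > 1.0 ? 1.0 : p;
}

// [[Rcpp::export(rng = false)]]
double hweExactPvalueC(int nAA, int nAa, int naa) {
    if (nAA < 0 || nAa < 0 || naa < 0) stop("negative genotype count");
    return hwe_exact_p(nAA, nAa, naa);
}

// [[Rcpp::export(rng = false)]]
NumericVector hweExactBatchC(IntegerMatrix counts) {
    if (counts.nrow() != 3) stop("counts must have 3 rows (AA, Aa, aa)");
    int nsnp = counts.ncol();
    NumericVector out(nsnp);
    for (int j = 0; j < nsnp; ++j)
        out[j] = hwe_exact_p(counts(0, j), counts(1, j), counts(2, j));
    return out;
}

// ---------------------------------------------------------------------------
// negative log-likelihoods for the null (HWP-constrained) fits
//
// Free parameters live in unconstrained space: logit of the allele
// frequency and log genotype relative risks for all strata but one; the
// remaining stratum's conditional genotype distribution is recovered from
// the population constraint sum_ij K_ij q_ij(k) = P_k(p) and must be
// non-negative (soft penalty otherwise so the simplex can retreat).
// ---------------------------------------------------------------------------

static inline double clamp(double x, double lo, double hi) {
    return x < lo ? lo : (x > hi ? hi : x);
}

struct ENullData {
    double N[4][3];   // genotype counts, blocks (T,D) = 00,10,01,11
    double K[4];      // joint probabilities
    int elim;         // block whose distribution is derived from the others
};

static double elrt_nll(int npar, double *th, void *ex) {
    ENullData *d = (ENullData *) ex;
    double p = 1.0 / (1.0 + std::exp(-clamp(th[0], -30.0, 30.0)));
    double P[3] = { p * p, 2.0 * p * (1.0 - p), (1.0 - p) * (1.0 - p) };
    double q[4][3];
    double acc[3] = { 0.0, 0.0, 0.0 };
    int ip = 1;
    for (int b = 0; b < 4; ++b) {
        if (b == d->elim) continue;
        double r1 = std::exp(clamp(th[ip++], -15.0, 15.0));
        double r2 = std::exp(clamp(th[ip++], -15.0, 15.0));
        double S = P[0] + r1 * P[1] + r2 * P[2];
        q[b][0] = P[0] / S;
        q[b][1] = r1 * P[1] / S;
        q[b][2] = r2 * P[2] / S;
        for (int k = 0; k < 3; ++k) acc[k] += d->K[b] * q[b][k];
    }
    double pen = 0.0;
    for (int k = 0; k < 3; ++k) {
        q[d->elim][k] = (P[k] - acc[k]) / d->K[d->elim];
        if (q[d->elim][k] < 0.0) pen -= q[d->elim][k];
    }
    if (pen > 0.0) return 1e8 * (1.0 + pen);
    double nll = 0.0;
    for (int b = 0; b < 4; ++b)
        for (int k = 0; k < 3; ++k) {
            double Nb = d->N[b][k];
            if (Nb > 0.0) {
                if (q[b][k] <= 0.0) return 1e9;
                nll -= Nb * std::log(q[b][k]);
            }
        }
    return nll;
}

struct LNullData {
    double N[2][3];   // genotype counts: stratum 0 (prob 1-f), stratum 1 (prob f)
    double f;
};

static double lrt_nll(int npar, double *th, void *ex) {
    LNullData *d = (LNullData *) ex;
    double p = 1.0 / (1.0 + std::exp(-clamp(th[0], -30.0, 30.0)));
    double P[3] = { p * p, 2.0 * p * (1.0 - p), (1.0 - p) * (1.0 - p) };
    double r1 = std::exp(clamp(th[1], -15.0, 15.0));
    double r2 = std::exp(clamp(th[2], -15.0, 15.0));
    double S = P[0] + r1 * P[1] + r2 * P[2];
    double q1[3] = { P[0] / S, r1 * P[1] / S, r2 * P[2] / S };
    double q0[3];
    double pen = 0.0;
    for (int k = 0; k < 3; ++k) {
        q0[k] = (P[k] - d->f * q1[k]) / (1.0 - d->f);
        if (q0[k] < 0.0) pen -= q0[k];
    }
    if (pen > 0.0) return 1e8 * (1.0 + pen);
    double nll = 0.0;
    for (int k = 0; k < 3; ++k) {
        if (d->N[0][k] > 0.0) {
            if (q0[k] <= 0.0) return 1e9;
            nll -= d->N[0][k] * std::log(q0[k]);
        }
        if (d->N[1][k] > 0.0) {
            if (q1[k] <= 0.0) return 1e9;
            nll -= d->N[1][k] * std::log(q1[k]);
        }
    }
    return nll;
}

static List run_nmmin(int npar, std::vector<double> &start, optimfn fn, void *ex,
                      int maxit, double reltol) {
    std::vector<double> xout(npar);
    double fmin = 0.0;
    int fail = 0, fncount = 0;
    nmmin(npar, start.data(), xout.data(), &fmin, fn, &fail,
          R_NegInf, reltol, ex, 1.0, 0.5, 2.0, 0, &fncount, maxit);
    return List::create(_["par"] = NumericVector(xout.begin(), xout.end()),
                        _["value"] = fmin,
                        _["fail"] = fail,
                        _["fncount"] = fncount);
}

// [[Rcpp::export(rng = false)]]
List elrtNullFitC(NumericMatrix counts, NumericVector K, int elim,
                  NumericVector start, int maxit = 5000, double reltol = 1e-10) {
    if (counts.nrow() != 3 || counts.ncol() != 4) stop("counts must be 3 x 4");
    if (K.size() != 4 || start.size() != 7) stop("bad parameter dimensions");
    ENullData d;
    for (int b = 0; b < 4; ++b) {
        d.K[b] = K[b];
        for (int k = 0; k < 3; ++k) d.N[b][k] = counts(k, b);
    }
    d.elim = elim;
    std::vector<double> th(start.begin(), start.end());
    return run_nmmin(7, th, elrt_nll, &d, maxit, reltol);
}

// [[Rcpp::export(rng = false)]]
double elrtNullObjC(NumericMatrix counts, NumericVector K, int elim,
                    NumericVector theta) {
    ENullData d;
    for (int b = 0; b < 4; ++b) {
        d.K[b] = K[b];
        for (int k = 0; k < 3; ++k) d.N[b][k] = counts(k, b);
    }
    d.elim = elim;
    std::vector<double> th(theta.begin(), theta.end());
    return elrt_nll(7, th.data(), &d);
}

// [[Rcpp::export(rng = false)]]
List lrtNullFitC(NumericMatrix counts, double f, NumericVector start,
                 int maxit = 5000, double reltol = 1e-10) {
    if (counts.nrow() != 3 || counts.ncol() != 2) stop("counts must be 3 x 2");
    if (start.size() != 3) stop("start must have length 3");
    LNullData d;
    d.f = f;
    for (int j = 0; j < 2; ++j)
        for (int k = 0; k < 3; ++k) d.N[j][k] = counts(k, j);
    std::vector<double> th(start.begin(), start.end());
    return run_nmmin(3, th, lrt_nll, &d, maxit, reltol);
}

// ---------------------------------------------------------------------------
// mixture resampling: without-replacement genotype draws per stratum
// (multivariate hypergeometric), pooled and fed to the exact test
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector mixtureDrawC(IntegerMatrix counts, IntegerVector draw) {
    int B = counts.ncol();
    if (counts.nrow() != 3 || draw.size() != B) stop("bad dimensions");
    long c0 = 0, c1 = 0, c2 = 0;
    for (int b = 0; b < B; ++b) {
        int nAA = counts(0, b), nAa = counts(1, b), naa = counts(2, b);
        int dd = draw[b];
        if (dd < 0 || dd > nAA + nAa + naa) stop("draw size exceeds stratum");
        int xAA = (int) ::Rf_rhyper(nAA, nAa + naa, dd);
        int xAa = (int) ::Rf_rhyper(nAa, naa, dd - xAA);
        c0 += xAA; c1 += xAa; c2 += dd - xAA - xAa;
    }
    return IntegerVector::create(c0, c1, c2);
}

// [[Rcpp::export]]
NumericVector mixturePvaluesC(IntegerMatrix counts, IntegerVector draw, int M) {
    int B = counts.ncol();
    if (counts.nrow() != 3 || draw.size() != B) stop("bad dimensions");
    if (M < 1) stop("M must be >= 1");
    NumericVector out(M);
    for (int m = 0; m < M; ++m) {
        long c0 = 0, c1 = 0, c2 = 0;
        for (int b = 0; b < B; ++b) {
            int nAA = counts(0, b), nAa = counts(1, b), naa = counts(2, b);
            int dd = draw[b];
            if (dd < 0 || dd > nAA + nAa + naa) stop("draw size exceeds stratum");
            int xAA = (int) ::Rf_rhyper(nAA, nAa + naa, dd);
            int xAa = (int) ::Rf_rhyper(nAa, naa, dd - xAA);
            c0 += xAA; c1 += xAa; c2 += dd - xAA - xAa;
        }
        out[m] = hwe_exact_p(c0, c1, c2);
    }
    return out;
}
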