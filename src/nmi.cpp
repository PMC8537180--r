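#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Weighted normalized mutual information between all column pairs of an
// integer-coded alignment. codes(i, c) in 1..K for residues, 0 for gap/X
// (missing; the row is dropped pairwise-complete for that pair). Entropies
// are in bits. A pair is masked (NA) when fewer than min_pairs rows remain
// or when either column entropy on the shared rows is below h_min.
static inline double entropy_bits(const std::vector<double>& p, double tot) {
    double h = 0.0;
    for (double x : p) {
        if (x > 0.0) {
            double q = x / tot;
            h -= q * std::log2(q);
        }
    }
    return h;
}

static double pair_nmi(const IntegerMatrix& codes, const NumericVector& w,
                       int i, int j, int K, int min_pairs, double h_min) {
    const int n = codes.nrow();
    std::vector<double> joint((size_t)K * K, 0.0), pi(K, 0.0), pj(K, 0.0);
    int n_used = 0;
    double tot = 0.0;
    for (int r = 0; r < n; ++r) {
        int a = codes(r, i), b = codes(r, j);
        if (a == 0 || b == 0) continue;
        double wr = w[r];
        joint[(size_t)(a - 1) * K + (b - 1)] += wr;
        pi[a - 1] += wr;
        pj[b - 1] += wr;
        tot += wr;
        ++n_used;
    }
    if (n_used < min_pairs || tot <= 0.0) return NA_REAL;
    double hi = entropy_bits(pi, tot);
    double hj = entropy_bits(pj, tot);
    if (hi < h_min || hj < h_min) return NA_REAL;
    double hij = entropy_bits(joint, tot);
    double nmi = (hi + hj - hij) / std::min(hi, hj);
    if (nmi < 0.0) nmi = 0.0;
    if (nmi > 1.0) nmi = 1.0;
    return nmi;
}

// [[Rcpp::export]]
NumericMatrix nmi_matrix_cpp(IntegerMatrix codes, NumericVector w, int K,
                             int min_pairs, double h_min) {
    const int L = codes.ncol();
    NumericMatrix out(L, L);
    std::fill(out.begin(), out.end(), NA_REAL);
    for (int i = 0; i < L; ++i) {
        for (int j = i + 1; j < L; ++j) {
            double v = pair_nmi(codes, w, i, j, K, min_pairs, h_min);
            out(i, j) = v;
            out(j, i) = v;
        }
        Rcpp::checkUserInterrupt();
    }
    return out;
}

// [[Rcpp::export]]
double nmi_pair_cpp(IntegerMatrix codes, NumericVector w, int i, int j, int K,
                    int min_pairs, double h_min) {
    return pair_nmi(codes, w, i - 1, j - 1, K, min_pairs, h_min);
}
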