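#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Circular binary segmentation on one chromosome's log2 values.
//
// For a window (i, j] of the sequence the statistic is the two-sample
// t-like contrast between the arc and its complement,
//   |mean_in - mean_out| / (sd * sqrt(1/k + 1/m)),
// maximised over all arcs with both sides at least min_width long.  The
// split is accepted when fewer than alpha * (nperm + 1) - 1 permutations
// of the values reach the observed maximum (early-stopped permutation
// test, R's RNG).  Accepted arcs contribute one or two breakpoints and
// both sides are segmented recursively.

struct ArcStat {
    double stat;
    int i, j;  // arc is (i, j], 0-based; -1 when no admissible arc
};

static ArcStat max_arc_stat(const double* x, int n, int min_width) {
    ArcStat best = { -1.0, -1, -1 };
    if (n < 2 * min_width) return best;
    std::vector<double> cs(n + 1, 0.0);
    for (int t = 0; t < n; ++t) cs[t + 1] = cs[t] + x[t];
    const double total = cs[n];
    const double mean = total / n;
    double ss = 0.0;
    for (int t = 0; t < n; ++t) { double d = x[t] - mean; ss += d * d; }
    double sd = std::sqrt(ss / (n > 1 ? n - 1 : 1));
    if (sd < 1e-12) return best;  // constant profile: no changepoint
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j <= n; ++j) {
            const int k = j - i, m = n - k;
            if (k < min_width || m < min_width) continue;
            const double mean_in = (cs[j] - cs[i]) / k;
            const double mean_out = (total - (cs[j] - cs[i])) / m;
            const double z = std::fabs(mean_in - mean_out) /
                (sd * std::sqrt(1.0 / k + 1.0 / m));
            if (z > best.stat) { best.stat = z; best.i = i; best.j = j; }
        }
    }
    return best;
}

// permutation p-value with early stopping: once the exceedance count
// guarantees p >= alpha the split can be rejected without finishing
static bool split_significant(const double* x, int n, int min_width,
                              double obs, double alpha, int nperm) {
    std::vector<double> perm(x, x + n);
    const double limit = alpha * (nperm + 1) - 1.0;  // max allowed exceedances
    int count = 0;
    for (int b = 0; b < nperm; ++b) {
        for (int t = n - 1; t > 0; --t) {  // Fisher-Yates via R's RNG
            int u = (int)(unif_rand() * (t + 1));
            if (u > t) u = t;
            std::swap(perm[t], perm[u]);
        }
        ArcStat s = max_arc_stat(perm.data(), n, min_width);
        if (s.stat >= obs) {
            if (++count > limit) return false;
        }
    }
    return (count + 1.0) / (nperm + 1.0) < alpha;
}

static void segment_recurse(const double* x, int lo, int hi, int min_width,
                            double alpha, int nperm,
                            std::vector<int>& breaks) {
    const int n = hi - lo;
    ArcStat s = max_arc_stat(x + lo, n, min_width);
    if (s.i < 0) return;
    if (!split_significant(x + lo, n, min_width, s.stat, alpha, nperm)) return;
    const int a = lo + s.i, b = lo + s.j;
    if (s.i > 0) breaks.push_back(a);
    if (s.j < n) breaks.push_back(b);
    if (s.i > 0) segment_recurse(x, lo, a, min_width, alpha, nperm, breaks);
    segment_recurse(x, a, b, min_width, alpha, nperm, breaks);
    if (s.j < n) segment_recurse(x, b, hi, min_width, alpha, nperm, breaks);
}

// [[Rcpp::export]]
IntegerVector cbs_changepoints_cpp(NumericVector x, double alpha,
                                   int nperm, int min_width) {
    const int n = x.size();
    std::vector<int> breaks;
    if (n >= 2 * min_width) {
        segment_recurse(REAL(x), 0, n, min_width, alpha, nperm, breaks);
    }
    std::sort(breaks.begin(), breaks.end());
    breaks.erase(std::unique(breaks.begin(), breaks.end()), breaks.end());
    return wrap(breaks);  // split positions: segment ends before x[pos]
}

// exhaustive single best arc, exposed for oracle cross-checks
// [[Rcpp::export]]
List cbs_max_stat_cpp(NumericVector x, int min_width) {
    ArcStat s = max_arc_stat(REAL(x), x.size(), min_width);
    return List::create(_["stat"] = s.stat, _["i"] = s.i, _["j"] = s.j);
}
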