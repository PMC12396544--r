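#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// One-vs-all random forest restricted to what marker ranking needs: binary
// classification with the Gini criterion and mean-decrease-in-impurity
// feature importances. Single-threaded and driven by R's RNG so that results
// are reproducible via set.seed(). Class weights follow the "balanced"
// convention w_c = n / (2 * n_c) computed on the full training data.
//
// Splits are searched over equal-frequency histogram bins (up to 256 per
// feature, computed once per forest on the full data), so node processing is
// a linear pass instead of a sort. Importance ranking is insensitive to the
// sub-bin placement of thresholds.

namespace {

constexpr int MAX_BINS = 256;

struct Frame {
    int lo, hi, depth;
};

inline int rand_index(int n) {
    // draw from {0, ..., n-1} using R's RNG
    int k = (int)(unif_rand() * n);
    return k >= n ? n - 1 : k;
}

inline double gini2(double w0, double w1) {
    double w = w0 + w1;
    if (w <= 0.0) return 0.0;
    double p0 = w0 / w, p1 = w1 / w;
    return 1.0 - p0 * p0 - p1 * p1;
}

} // namespace

// [[Rcpp::export(name = ".rf_gini_importance")]]
NumericVector rf_gini_importance(NumericMatrix X, IntegerVector y,
                                 int n_trees, int mtry, int min_node,
                                 int max_depth, bool balanced) {
    const int n = X.nrow(), p = X.ncol();
    if (y.size() != n) stop("length(y) must match nrow(X)");
    if (mtry < 1) mtry = 1;
    if (mtry > p) mtry = p;
    if (min_node < 1) min_node = 1;
    if (max_depth <= 0) max_depth = INT_MAX;

    int n1 = 0;
    for (int i = 0; i < n; ++i) {
        if (y[i] != 0 && y[i] != 1) stop("y must be 0/1");
        n1 += y[i];
    }
    if (n1 == 0 || n1 == n)
        stop("one-vs-all target is single-class; cannot fit a forest");

    const double w1 = balanced ? (double)n / (2.0 * n1) : 1.0;
    const double w0 = balanced ? (double)n / (2.0 * (n - n1)) : 1.0;

    // equal-frequency binning per feature on the full data
    std::vector<std::vector<uint16_t> > bins(p, std::vector<uint16_t>(n));
    std::vector<int> nbins(p);
    {
        std::vector<int> ord(n);
        const int target = n / MAX_BINS + 1;
        for (int f = 0; f < p; ++f) {
            for (int i = 0; i < n; ++i) ord[i] = i;
            NumericMatrix::Column col = X(_, f);
            std::sort(ord.begin(), ord.end(),
                      [&](int a, int b) { return col[a] < col[b]; });
            int b = 0, cnt = 0;
            for (int r = 0; r < n; ++r) {
                if (r > 0 && col[ord[r]] != col[ord[r - 1]] &&
                    cnt >= target && b < MAX_BINS - 1) {
                    ++b;
                    cnt = 0;
                }
                bins[f][ord[r]] = (uint16_t)b;
                ++cnt;
            }
            nbins[f] = b + 1;
        }
    }

    NumericVector importance(p);
    std::vector<double> tree_imp(p);
    std::vector<int> idx(n), feat(p);
    double h0[MAX_BINS], h1[MAX_BINS];
    int hc[MAX_BINS];
    std::vector<Frame> stack;
    stack.reserve(256);

    for (int t = 0; t < n_trees; ++t) {
        // bootstrap sample
        for (int i = 0; i < n; ++i) idx[i] = rand_index(n);
        std::fill(tree_imp.begin(), tree_imp.end(), 0.0);

        // weighted size of the root, for sklearn-style importance scaling
        double root_w = 0.0;
        for (int i = 0; i < n; ++i) root_w += (y[idx[i]] ? w1 : w0);

        stack.clear();
        stack.push_back(Frame{0, n, 0});
        while (!stack.empty()) {
            Frame fr = stack.back();
            stack.pop_back();
            const int m = fr.hi - fr.lo;

            double c0 = 0.0, c1 = 0.0;
            for (int i = fr.lo; i < fr.hi; ++i) {
                if (y[idx[i]]) c1 += w1; else c0 += w0;
            }
            const double node_w = c0 + c1;
            const double node_g = gini2(c0, c1);
            if (node_g <= 0.0 || m < 2 * min_node || fr.depth >= max_depth)
                continue;

            // sample mtry candidate features without replacement
            for (int j = 0; j < p; ++j) feat[j] = j;
            int best_f = -1, best_bin = -1;
            double best_dec = 0.0;
            for (int j = 0; j < mtry; ++j) {
                int k = j + rand_index(p - j);
                std::swap(feat[j], feat[k]);
                const int f = feat[j];
                const int nb = nbins[f];
                if (nb < 2) continue;

                std::fill(h0, h0 + nb, 0.0);
                std::fill(h1, h1 + nb, 0.0);
                std::fill(hc, hc + nb, 0);
                const std::vector<uint16_t>& bf = bins[f];
                for (int i = fr.lo; i < fr.hi; ++i) {
                    const int b = bf[idx[i]];
                    if (y[idx[i]]) h1[b] += w1; else h0[b] += w0;
                    ++hc[b];
                }
                double l0 = 0.0, l1 = 0.0;
                int nl = 0;
                for (int b = 0; b < nb - 1; ++b) {
                    l0 += h0[b];
                    l1 += h1[b];
                    nl += hc[b];
                    if (nl < min_node || m - nl < min_node) continue;
                    const double wl = l0 + l1, wr = node_w - wl;
                    if (wl <= 0.0 || wr <= 0.0) continue;
                    const double dec = node_g -
                        (wl * gini2(l0, l1) + wr * gini2(c0 - l0, c1 - l1)) /
                            node_w;
                    if (dec > best_dec + 1e-12) {
                        best_dec = dec;
                        best_f = f;
                        best_bin = b;
                    }
                }
            }
            if (best_f < 0) continue;

            tree_imp[best_f] += (node_w / root_w) * best_dec;

            // partition idx[lo..hi) on the chosen split
            const std::vector<uint16_t>& bf = bins[best_f];
            int mid = fr.lo;
            for (int i = fr.lo; i < fr.hi; ++i) {
                if (bf[idx[i]] <= best_bin) {
                    std::swap(idx[i], idx[mid]);
                    ++mid;
                }
            }
            if (mid == fr.lo || mid == fr.hi) continue;
            stack.push_back(Frame{fr.lo, mid, fr.depth + 1});
            stack.push_back(Frame{mid, fr.hi, fr.depth + 1});
        }

        double s = 0.0;
        for (int j = 0; j < p; ++j) s += tree_imp[j];
        if (s > 0.0)
            for (int j = 0; j < p; ++j) importance[j] += tree_imp[j] / s;
    }

    for (int j = 0; j < p; ++j) importance[j] /= n_trees;
    return importance;
}
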