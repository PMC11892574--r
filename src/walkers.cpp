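#include <Rcpp.h>
using namespace Rcpp;

// Sample a column index (0-based) proportional to w[j] over valid entries.
// Returns -1 when the total mass is zero.
static int sample_direction(const double *w, int n, double total) {
    if (total <= 0.0) return -1;
    double u = unif_rand() * total;
    double cum = 0.0;
    for (int j = 0; j < n; ++j) {
        cum += w[j];
        if (u <= cum && w[j] > 0.0) return j;
    }
    // numerical edge: return last positive entry
    for (int j = n - 1; j >= 0; --j) if (w[j] > 0.0) return j;
    return -1;
}

// Random walk toward the tumor. Rows of W/nb index eligible voxels (1-based
// in nb, 0 = no eligible neighbor in that direction). d holds the step
// distance per row. The walk ends on entering a voxel with d == 1 (tumor
// margin). After stall_limit consecutive steps with unchanged d, the next
// draw is restricted to strictly-decreasing-d neighbors (renormalized).
// [[Rcpp::export]]
List walk_toward_cpp(int start, NumericMatrix W, IntegerMatrix nb,
                     IntegerVector d, int stall_limit, int max_steps) {
    int ndir = W.ncol();
    std::vector<int> path;
    path.reserve(64);
    int cur = start;             // 1-based row
    path.push_back(cur);
    bool reached = (d[cur - 1] == 1);
    bool failed = false;
    int stall = 0;
    std::vector<double> w(ndir);
    for (int step = 0; !reached && step < max_steps; ++step) {
        bool force = (stall >= stall_limit);
        double total = 0.0;
        int dcur = d[cur - 1];
        for (int j = 0; j < ndir; ++j) {
            double wij = W(cur - 1, j);
            int r = nb(cur - 1, j);
            if (r > 0 && wij > 0.0 && (!force || d[r - 1] < dcur)) {
                w[j] = wij;
                total += wij;
            } else w[j] = 0.0;
        }
        int j = sample_direction(w.data(), ndir, total);
        if (j < 0) { failed = true; break; }
        int nxt = nb(cur - 1, j);
        if (d[nxt - 1] == dcur) ++stall; else stall = 0;
        cur = nxt;
        path.push_back(cur);
        if (d[cur - 1] == 1) reached = true;
    }
    if (!reached && !failed) failed = true;  // max_steps exhausted
    return List::create(_["path"] = wrap(path),
                        _["reached_margin"] = reached,
                        _["failed"] = failed);
}

// Random walk away from the tumor under the away-mode matrix. Ends at an
// all-zero row (local distance maximum) or after stall_limit consecutive
// equal-d steps; always returns at least the start voxel.
// [[Rcpp::export]]
List walk_away_cpp(int start, NumericMatrix W, IntegerMatrix nb,
                   IntegerVector d, int stall_limit, int max_steps) {
    int ndir = W.ncol();
    std::vector<int> path;
    path.reserve(64);
    int cur = start;
    path.push_back(cur);
    int stall = 0;
    std::vector<double> w(ndir);
    for (int step = 0; step < max_steps; ++step) {
        if (stall >= stall_limit) break;
        double total = 0.0;
        for (int j = 0; j < ndir; ++j) {
            double wij = W(cur - 1, j);
            int r = nb(cur - 1, j);
            if (r > 0 && wij > 0.0) { w[j] = wij; total += wij; }
            else w[j] = 0.0;
        }
        int j = sample_direction(w.data(), ndir, total);
        if (j < 0) break;  // terminal row: local maximum of d
        int nxt = nb(cur - 1, j);
        if (d[nxt - 1] == d[cur - 1]) ++stall; else stall = 0;
        cur = nxt;
        path.push_back(cur);
    }
    return List::create(_["path"] = wrap(path));
}

// Sliding median with window `order`. Interior window for sample i (0-based)
// is [i - floor((order-1)/2), i + floor(order/2)], truncated at the profile
// ends; the median of an even count is the mean of the two central order
// statistics (matching stats::median).
// [[Rcpp::export]]
NumericVector sliding_median_cpp(NumericVector x, int order) {
    int n = x.size();
    NumericVector out(n);
    if (order < 1) order = 1;
    int hl = (order - 1) / 2, hr = order / 2;
    std::vector<double> buf;
    buf.reserve(order);
    for (int i = 0; i < n; ++i) {
        int lo = std::max(0, i - hl);
        int hi = std::min(n - 1, i + hr);
        buf.assign(x.begin() + lo, x.begin() + hi + 1);
        std::sort(buf.begin(), buf.end());
        int m = (int) buf.size();
        out[i] = (m % 2 == 1) ? buf[m / 2]
                              : 0.5 * (buf[m / 2 - 1] + buf[m / 2]);
    }
    return out;
}
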