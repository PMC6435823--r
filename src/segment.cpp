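#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Descending-intensity flood segmentation, the semantics of ImageJ's
// Find Maxima with "segmented particles" output: pixels are visited from
// brightest to dimmest; regions grow around local maxima and two regions
// merge where the dip separating them is no deeper than `tolerance`.
// Coordinates here are 1-based (row, col); the R wrappers convert to the
// package-wide 0-based (x, y) convention.

static inline int find_root(std::vector<int> &parent, int i) {
    while (parent[i] != i) {
        parent[i] = parent[parent[i]];
        i = parent[i];
    }
    return i;
}

// order pixels by decreasing value; ties by increasing row then column so
// that a plateau's representative is its lexicographically smallest (y, x)
static std::vector<int> ordered_pixels(const NumericMatrix &img,
                                       double min_intensity) {
    const int H = img.nrow();
    const int N = H * img.ncol();
    std::vector<int> idx;
    idx.reserve(N);
    for (int i = 0; i < N; i++)
        if (img[i] >= min_intensity) idx.push_back(i);
    std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
        if (img[a] != img[b]) return img[a] > img[b];
        int ra = a % H, rb = b % H;
        if (ra != rb) return ra < rb;
        return a / H < b / H;
    });
    return idx;
}

// [[Rcpp::export]]
List cpp_find_maxima(NumericMatrix img, double tolerance,
                     double min_intensity) {
    const int H = img.nrow(), W = img.ncol(), N = H * W;
    std::vector<int> idx = ordered_pixels(img, min_intensity);
    std::vector<int> parent(N);
    std::vector<char> visited(N, 0);
    std::vector<double> peakval(N);

    for (size_t k = 0; k < idx.size(); k++) {
        const int p = idx[k];
        const int r = p % H, c = p / H;
        int roots[8];
        int nr = 0;
        for (int dc = -1; dc <= 1; dc++) {
            for (int dr = -1; dr <= 1; dr++) {
                if (dr == 0 && dc == 0) continue;
                const int rr = r + dr, cc = c + dc;
                if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
                const int q = rr + cc * H;
                if (!visited[q]) continue;
                const int rt = find_root(parent, q);
                bool seen = false;
                for (int j = 0; j < nr; j++)
                    if (roots[j] == rt) { seen = true; break; }
                if (!seen) roots[nr++] = rt;
            }
        }
        if (nr == 0) {
            parent[p] = p;
            peakval[p] = img[p];
            visited[p] = 1;
            continue;
        }
        // target: the neighbouring region with the highest peak;
        // ties broken toward the smaller (row, col) root pixel
        int target = roots[0];
        for (int j = 1; j < nr; j++) {
            const int rt = roots[j];
            if (peakval[rt] > peakval[target] ||
                (peakval[rt] == peakval[target] &&
                 (rt % H < target % H ||
                  (rt % H == target % H && rt / H < target / H))))
                target = rt;
        }
        parent[p] = target;
        visited[p] = 1;
        for (int j = 0; j < nr; j++) {
            const int rt = roots[j];
            if (rt == target) continue;
            // dip between region rt's peak and this saddle pixel
            if (peakval[rt] - img[p] <= tolerance) parent[rt] = target;
        }
    }

    // surviving roots = maxima; label them in (row, col) order
    std::vector<int> roots;
    for (size_t k = 0; k < idx.size(); k++) {
        const int p = idx[k];
        if (parent[p] == p) roots.push_back(p);
    }
    std::sort(roots.begin(), roots.end(), [&](int a, int b) {
        int ra = a % H, rb = b % H;
        if (ra != rb) return ra < rb;
        return a / H < b / H;
    });
    std::vector<int> lab_of(N, 0);
    const int nlab = (int)roots.size();
    for (int j = 0; j < nlab; j++) lab_of[roots[j]] = j + 1;

    IntegerMatrix labels(H, W);
    for (size_t k = 0; k < idx.size(); k++) {
        const int p = idx[k];
        labels[p] = lab_of[find_root(parent, p)];
    }
    IntegerMatrix peaks(nlab, 2);
    NumericVector values(nlab);
    for (int j = 0; j < nlab; j++) {
        peaks(j, 0) = roots[j] % H + 1;
        peaks(j, 1) = roots[j] / H + 1;
        values[j] = img[roots[j]];
    }
    return List::create(_["labels"] = labels, _["peaks"] = peaks,
                        _["values"] = values);
}

// Seeded variant: the maxima are given; every pixel >= min_intensity is
// assigned to exactly one seed by the same descending flood. Regions that
// never meet a seeded region are attached to the seed nearest their peak.
// [[Rcpp::export]]
IntegerMatrix cpp_segment_seeded(NumericMatrix img, IntegerVector seed_row,
                                 IntegerVector seed_col,
                                 double min_intensity) {
    const int H = img.nrow(), W = img.ncol(), N = H * W;
    const int ns = seed_row.size();
    std::vector<int> idx = ordered_pixels(img, min_intensity);
    std::vector<int> parent(N);
    std::vector<char> visited(N, 0);
    std::vector<double> peakval(N);
    std::vector<int> seedlab(N, 0);

    for (int j = 0; j < ns; j++) {
        const int p = (seed_row[j] - 1) + (seed_col[j] - 1) * H;
        parent[p] = p;
        peakval[p] = img[p];
        seedlab[p] = j + 1;
        visited[p] = 1;
    }

    for (size_t k = 0; k < idx.size(); k++) {
        const int p = idx[k];
        if (visited[p] && parent[p] == p && seedlab[p] > 0) continue;
        if (visited[p]) continue;
        const int r = p % H, c = p / H;
        int roots[8];
        int nr = 0;
        for (int dc = -1; dc <= 1; dc++) {
            for (int dr = -1; dr <= 1; dr++) {
                if (dr == 0 && dc == 0) continue;
                const int rr = r + dr, cc = c + dc;
                if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
                const int q = rr + cc * H;
                if (!visited[q]) continue;
                const int rt = find_root(parent, q);
                bool seen = false;
                for (int j = 0; j < nr; j++)
                    if (roots[j] == rt) { seen = true; break; }
                if (!seen) roots[nr++] = rt;
            }
        }
        if (nr == 0) {
            parent[p] = p;
            peakval[p] = img[p];
            visited[p] = 1;
            continue;
        }
        int target = -1;
        bool have_seed = false;
        for (int j = 0; j < nr; j++) {
            const int rt = roots[j];
            const bool s = seedlab[rt] > 0;
            if (target < 0 || (s && !have_seed) ||
                (s == have_seed &&
                 (peakval[rt] > peakval[target] ||
                  (peakval[rt] == peakval[target] &&
                   (rt % H < target % H ||
                    (rt % H == target % H && rt / H < target / H)))))) {
                target = rt;
                have_seed = have_seed || s;
            }
        }
        parent[p] = target;
        visited[p] = 1;
        for (int j = 0; j < nr; j++) {
            const int rt = roots[j];
            if (rt == target) continue;
            if (seedlab[rt] > 0 && have_seed) continue;  // seeded stay apart
            if (peakval[rt] > peakval[target]) peakval[target] = peakval[rt];
            parent[rt] = target;
        }
    }

    // attach any surviving unseeded region to the nearest seed
    IntegerMatrix labels(H, W);
    for (size_t k = 0; k < idx.size(); k++) {
        const int p = idx[k];
        const int rt = find_root(parent, p);
        int lab = seedlab[rt];
        if (lab == 0) {
            const int r = rt % H, c = rt / H;
            double best = -1.0;
            for (int j = 0; j < ns; j++) {
                const double dr = (double)(seed_row[j] - 1 - r);
                const double dc = (double)(seed_col[j] - 1 - c);
                const double d = dr * dr + dc * dc;
                if (best < 0 || d < best) {
                    best = d;
                    lab = j + 1;
                }
            }
            seedlab[rt] = lab;
        }
        labels[p] = lab;
    }
    return labels;
}
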