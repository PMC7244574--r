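#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int>& parent, int i) {
    while (parent[i] != i) {
        parent[i] = parent[parent[i]];
        i = parent[i];
    }
    return i;
}

// Single-linkage components for preclusters under the relation
// |dTSS| < window AND |dPAS| < window (strict). `five` must be sorted
// ascending; candidate links are enumerated over the sliding 5' window,
// which bounds the work by window occupancy. Returns 1-based component ids.
// [[Rcpp::export(name = ".merge_components")]]
IntegerVector merge_components(IntegerVector five, IntegerVector three,
                               int window) {
    const int n = five.size();
    std::vector<int> parent(n);
    for (int i = 0; i < n; ++i) parent[i] = i;
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n && five[j] - five[i] < window; ++j) {
            int dp = three[j] - three[i];
            if (dp < 0) dp = -dp;
            if (dp < window) {
                int ri = uf_find(parent, i), rj = uf_find(parent, j);
                if (ri != rj) parent[ri] = rj;
            }
        }
    }
    IntegerVector comp(n);
    std::vector<int> label(n, 0);
    int next = 0;
    for (int i = 0; i < n; ++i) {
        int r = uf_find(parent, i);
        if (label[r] == 0) label[r] = ++next;
        comp[i] = label[r];
    }
    return comp;
}
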