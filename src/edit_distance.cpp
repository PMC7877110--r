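#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// Levenshtein distance, unit costs, two-row DP.
// Base case D(i,0)=i, D(0,j)=j; recurrence min(del+1, ins+1, sub + [a!=b]).
static int lev(const std::string &a, const std::string &b) {
    const int n = static_cast<int>(a.size());
    const int m = static_cast<int>(b.size());
    if (n == 0) return m;
    if (m == 0) return n;
    std::vector<int> prev(m + 1), cur(m + 1);
    for (int j = 0; j <= m; ++j) prev[j] = j;
    for (int i = 1; i <= n; ++i) {
        cur[0] = i;
        const char ai = a[i - 1];
        for (int j = 1; j <= m; ++j) {
            const int sub = prev[j - 1] + (ai != b[j - 1] ? 1 : 0);
            cur[j] = std::min(std::min(prev[j] + 1, cur[j - 1] + 1), sub);
        }
        std::swap(prev, cur);
    }
    return prev[m];
}

// [[Rcpp::export(name = ".editDistancePairs")]]
IntegerVector editDistancePairs(CharacterVector a, CharacterVector b) {
    if (a.size() != b.size())
        stop("'a' and 'b' must have the same length");
    const R_xlen_t n = a.size();
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = lev(as<std::string>(a[i]), as<std::string>(b[i]));
    return out;
}

// [[Rcpp::export(name = ".editDistanceCross")]]
IntegerMatrix editDistanceCross(CharacterVector a, CharacterVector b) {
    const R_xlen_t n = a.size(), m = b.size();
    std::vector<std::string> va(n), vb(m);
    for (R_xlen_t i = 0; i < n; ++i) va[i] = as<std::string>(a[i]);
    for (R_xlen_t j = 0; j < m; ++j) vb[j] = as<std::string>(b[j]);
    IntegerMatrix out(n, m);
    for (R_xlen_t i = 0; i < n; ++i)
        for (R_xlen_t j = 0; j < m; ++j)
            out(i, j) = lev(va[i], vb[j]);
    return out;
}
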