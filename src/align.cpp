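#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Glocal ("global-local") alignment: the shorter sequence is aligned in
// full, terminal gaps are free only on the longer sequence and contribute
// no columns. Identity = matches / alignment columns over the aligned
// region (internal gaps count as columns). This keeps identity meaningful
// in every place it is used: unrelated same-length reads score ~0.25
// instead of hitting a spurious short perfect overlap, while a truncated
// cluster representative still matches its own full-length read at ~1.
// One scoring scheme everywhere: match +1, mismatch -1, linear gap -2.
// 'N' never matches.
static const int SC_MATCH = 1, SC_MISMATCH = -1, SC_GAP = -2;

static void align_stats(const std::string& sa, const std::string& sb,
                        int& matches, int& columns) {
    // s = shorter (rows, consumed fully), l = longer (columns, free ends)
    const std::string& s = (sa.size() <= sb.size()) ? sa : sb;
    const std::string& l = (sa.size() <= sb.size()) ? sb : sa;
    const int n = (int)s.size(), m = (int)l.size();
    matches = 0; columns = 0;
    if (n == 0 || m == 0) return;

    std::vector<int> prev(m + 1), cur(m + 1);
    // traceback codes: 1 diagonal, 2 up (gap in l), 3 left (gap in s)
    std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);
    for (int j = 0; j <= m; ++j) prev[j] = 0;  // free leading gap in l

    for (int i = 1; i <= n; ++i) {
        cur[0] = i * SC_GAP;  // skipping bases of s is penalized
        const char si = s[i - 1];
        for (int j = 1; j <= m; ++j) {
            const bool eq = (si == l[j - 1]) && si != 'N';
            int best = prev[j - 1] + (eq ? SC_MATCH : SC_MISMATCH);
            unsigned char t = 1;
            if (prev[j] + SC_GAP > best) { best = prev[j] + SC_GAP; t = 2; }
            if (cur[j - 1] + SC_GAP > best) { best = cur[j - 1] + SC_GAP; t = 3; }
            cur[j] = best;
            tb[(size_t)i * (m + 1) + j] = t;
        }
        std::swap(prev, cur);
    }

    // end anywhere on the last row (free trailing gap in l)
    int bj = m, best = prev[m];
    for (int j = m - 1; j >= 0; --j)
        if (prev[j] > best) { best = prev[j]; bj = j; }

    int i = n, j = bj;
    while (i > 0) {
        const unsigned char t = (j > 0) ? tb[(size_t)i * (m + 1) + j] : 2;
        if (t == 1) {
            ++columns;
            if (s[i - 1] == l[j - 1] && s[i - 1] != 'N') ++matches;
            --i; --j;
        } else if (t == 2) { ++columns; --i; }
        else               { ++columns; --j; }
    }
}

// [[Rcpp::export]]
NumericVector cpp_identity(CharacterVector queries, std::string subject) {
    const int n = queries.size();
    NumericVector out(n);
    for (int k = 0; k < n; ++k) {
        if (CharacterVector::is_na(queries[k])) { out[k] = NA_REAL; continue; }
        int matches, columns;
        align_stats(as<std::string>(queries[k]), subject, matches, columns);
        out[k] = columns > 0 ? (double)matches / columns : 0.0;
    }
    return out;
}

// [[Rcpp::export]]
List cpp_align_pair(std::string a, std::string b) {
    int matches, columns;
    align_stats(a, b, matches, columns);
    return List::create(_["matches"] = matches, _["columns"] = columns,
                        _["identity"] = columns > 0 ? (double)matches / columns : 0.0);
}

// matches + columns for many queries against one subject (hit-table builder)
// [[Rcpp::export]]
DataFrame cpp_align_many(CharacterVector queries, std::string subject) {
    const int n = queries.size();
    IntegerVector matches(n), columns(n);
    for (int k = 0; k < n; ++k) {
        int mt, cl;
        align_stats(as<std::string>(queries[k]), subject, mt, cl);
        matches[k] = mt; columns[k] = cl;
    }
    return DataFrame::create(_["matches"] = matches, _["columns"] = columns);
}

// Hamming distance of each string in x (already cut to nchar(y)) against y;
// strings shorter than y get NA
// [[Rcpp::export]]
IntegerVector cpp_hamming(CharacterVector x, std::string y) {
    const int n = x.size(); const size_t L = y.size();
    IntegerVector out(n);
    for (int k = 0; k < n; ++k) {
        std::string s = as<std::string>(x[k]);
        if (s.size() < L) { out[k] = NA_INTEGER; continue; }
        int d = 0;
        for (size_t i = 0; i < L; ++i) if (s[i] != y[i]) ++d;
        out[k] = d;
    }
    return out;
}

// longest single-nucleotide run per sequence
// [[Rcpp::export]]
IntegerVector cpp_max_run(CharacterVector x) {
    const int n = x.size();
    IntegerVector out(n);
    for (int k = 0; k < n; ++k) {
        std::string s = as<std::string>(x[k]);
        int best = 0, run = 0; char prevc = 0;
        for (size_t i = 0; i < s.size(); ++i) {
            run = (s[i] == prevc) ? run + 1 : 1;
            prevc = s[i];
            if (run > best) best = run;
        }
        out[k] = best;
    }
    return out;
}
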