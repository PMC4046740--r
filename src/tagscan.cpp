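#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Characters outside {A,C,G,T} (e.g. N) never match anything, themselves
// included: ambiguity codes are counted as mismatches, conservatively.
static inline bool base_match(char a, char b) {
    if (a != b) return false;
    return a == 'A' || a == 'C' || a == 'G' || a == 'T';
}

// Banded Levenshtein distance, capped at `limit`. Returns -1 when the true
// distance exceeds the cap. Rows over `a`, columns over `b`; only cells with
// |i - j| <= limit can hold a value <= limit, so the band suffices.
static int bounded_lev(const char *a, int na, const char *b, int nb, int limit) {
    if (std::abs(na - nb) > limit) return -1;
    const int INF = limit + 1;
    std::vector<int> prev(nb + 1), cur(nb + 1);
    for (int j = 0; j <= nb; ++j) prev[j] = (j <= limit) ? j : INF;
    for (int i = 1; i <= na; ++i) {
        int lo = std::max(1, i - limit), hi = std::min(nb, i + limit);
        cur[0] = (i <= limit) ? i : INF;
        if (lo > 1) cur[lo - 1] = INF;
        int best = cur[0];
        for (int j = lo; j <= hi; ++j) {
            int sub = prev[j - 1] + (base_match(a[i - 1], b[j - 1]) ? 0 : 1);
            int del = (prev[j] < INF) ? prev[j] + 1 : INF;        // delete from a
            int ins = (j > lo && cur[j - 1] < INF) ? cur[j - 1] + 1 : INF;
            int v = std::min(sub, std::min(del, ins));
            cur[j] = (v > limit) ? INF : v;
            if (cur[j] < best) best = cur[j];
        }
        if (hi < nb) cur[hi + 1] = INF;
        if (best > limit) return -1;
        std::swap(prev, cur);
    }
    return (prev[nb] <= limit) ? prev[nb] : -1;
}

// [[Rcpp::export]]
IntegerVector bounded_edit_distance_cpp(CharacterVector a, CharacterVector b,
                                        int limit) {
    int n = a.size();
    if (b.size() != n) stop("'a' and 'b' must have equal length");
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        std::string sa = as<std::string>(a[i]), sb = as<std::string>(b[i]);
        int d = bounded_lev(sa.c_str(), sa.size(), sb.c_str(), sb.size(), limit);
        out[i] = (d < 0) ? NA_INTEGER : d;
    }
    return out;
}

struct Hit { int start, end, variant, nvar, window; };

// Best hit at one offset. `windows` and `variants` are in preference order:
// ties on n_variations go to the earlier window, then the earlier variant.
static bool best_at(const char *seq, int len, int pos,
                    const std::vector<std::string> &variants,
                    const IntegerVector &windows, int max_var, Hit &out) {
    bool found = false;
    Hit best = {0, 0, 0, max_var + 1, 0};
    for (int wi = 0; wi < windows.size(); ++wi) {
        int w = windows[wi];
        if (pos + w > len) continue;
        for (int vi = 0; vi < (int) variants.size(); ++vi) {
            int d = bounded_lev(seq + pos, w, variants[vi].c_str(),
                                variants[vi].size(), max_var);
            if (d >= 0 && d < best.nvar) {
                best = {pos, pos + w, vi + 1, d, w};
                found = true;
                if (d == 0) return (out = best, true);
            }
        }
    }
    if (found) out = best;
    return found;
}

// [[Rcpp::export]]
IntegerMatrix match_window_cpp(std::string seq, int pos,
                               CharacterVector variants, IntegerVector windows,
                               int max_var) {
    std::vector<std::string> vs;
    for (int i = 0; i < variants.size(); ++i) vs.push_back(as<std::string>(variants[i]));
    Hit h;
    bool ok = best_at(seq.c_str(), seq.size(), pos, vs, windows, max_var, h);
    IntegerMatrix m(ok ? 1 : 0, 5);
    colnames(m) = CharacterVector::create("start", "end", "variant", "n_variations",
                                          "window_length");
    if (ok) { m(0,0)=h.start; m(0,1)=h.end; m(0,2)=h.variant; m(0,3)=h.nvar; m(0,4)=h.window; }
    return m;
}

// Greedy 5'->3' scan: at each offset try every window/variant combination; on
// a hit emit it and resume at the hit's end, otherwise advance one base.
// [[Rcpp::export]]
IntegerMatrix scan_read_cpp(std::string seq, CharacterVector variants,
                            IntegerVector windows, int max_var) {
    std::vector<std::string> vs;
    for (int i = 0; i < variants.size(); ++i) vs.push_back(as<std::string>(variants[i]));
    int len = seq.size(), minw = windows[0];
    for (int i = 1; i < windows.size(); ++i) minw = std::min(minw, (int) windows[i]);
    std::vector<Hit> hits;
    int pos = 0;
    while (pos <= len - minw) {
        Hit h;
        if (best_at(seq.c_str(), len, pos, vs, windows, max_var, h)) {
            // Exact matches dominate: an imperfect candidate (flanking
            // sequence absorbed as part of the window) must not pre-empt a
            // cleaner hit starting inside its own span, since accepting it
            // would destroy the overlapping better hit.
            for (int q = pos + 1;
                 h.nvar > 0 && q < h.end && q <= len - minw; ++q) {
                Hit h2;
                if (best_at(seq.c_str(), len, q, vs, windows, max_var, h2) &&
                    h2.nvar < h.nvar)
                    h = h2;
            }
            hits.push_back(h);
            pos = h.end;
        } else {
            ++pos;
        }
    }
    IntegerMatrix m(hits.size(), 5);
    colnames(m) = CharacterVector::create("start", "end", "variant", "n_variations",
                                          "window_length");
    for (size_t i = 0; i < hits.size(); ++i) {
        m(i,0)=hits[i].start; m(i,1)=hits[i].end; m(i,2)=hits[i].variant;
        m(i,3)=hits[i].nvar;  m(i,4)=hits[i].window;
    }
    return m;
}
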