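#include <Rcpp.h>
#include <chrono>
#include <climits>
#include <vector>

using namespace Rcpp;

// Hamming distance between two equal-length strings; early exit once the
// count exceeds `cap` (pass -1 for no cap: exact count is returned).
static inline int hamming_capped(const char *u, const char *v, int l, int cap) {
    int dcnt = 0;
    for (int t = 0; t < l; ++t) {
        if (u[t] != v[t]) {
            ++dcnt;
            if (cap >= 0 && dcnt > cap) return dcnt;
        }
    }
    return dcnt;
}

// [[Rcpp::export(name = ".hamming_cpp")]]
int hamming_cpp(std::string u, std::string v) {
    if (u.size() != v.size())
        stop("Hamming distance requires equal-length strings (got %d and %d)",
             (int)u.size(), (int)v.size());
    return hamming_capped(u.c_str(), v.c_str(), (int)u.size(), -1);
}

// Pairwise <= threshold test on 2-bit-free integer codes (0..3; 4 = invalid).
static inline bool within_threshold(const int *a, int ja, const int *b, int jb,
                                    int l, int thr) {
    int dcnt = 0;
    for (int t = 0; t < l; ++t) {
        if (a[ja + t] != b[jb + t]) {
            if (++dcnt > thr) return false;
        }
    }
    return true;
}

struct SearchCtx {
    std::vector<const int *> seq;  // coded sequences, values 0..3 (4 = skip)
    int m, l, thr;
    long long first_k;             // stop after this many cliques (LLONG_MAX = all)
    double deadline;               // seconds since start; <0 = none
    std::chrono::steady_clock::time_point t0;
    bool timed_out;
    unsigned long long ticks;
    std::vector<int> instance;     // current path, one start per sequence
    std::vector<std::vector<int>> out;
};

static inline bool budget_hit(SearchCtx &c) {
    if (++c.ticks % 4096 == 0) {
        Rcpp::checkUserInterrupt();
        if (c.deadline >= 0) {
            std::chrono::duration<double> el =
                std::chrono::steady_clock::now() - c.t0;
            if (el.count() > c.deadline) {
                c.timed_out = true;
                return true;
            }
        }
    }
    return false;
}

// Recursive reference-vertex selection. `pools[k]` (k >= level) holds the
// candidate start offsets of sequence k compatible with every reference
// vertex chosen at depths 0..level-1. Returns true when the search must stop
// (clique quota reached or deadline passed).
static bool recurse(SearchCtx &c, int level,
                    const std::vector<std::vector<int>> &pools) {
    if (level == c.m) {
        c.out.push_back(c.instance);
        return (long long)c.out.size() >= c.first_k;
    }
    for (int v : pools[level]) {
        if (budget_hit(c)) return true;
        bool valid = true;
        std::vector<std::vector<int>> next(c.m);
        for (int k = level + 1; k < c.m; ++k) {
            const std::vector<int> &pool = pools[k];
            std::vector<int> &sel = next[k];
            for (int j : pool) {
                if (within_threshold(c.seq[level], v, c.seq[k], j, c.l, c.thr))
                    sel.push_back(j);
            }
            if (sel.empty()) { valid = false; break; }
        }
        if (valid) {
            c.instance[level] = v;
            if (recurse(c, level + 1, next)) return true;
        }
    }
    return false;
}

// Exhaustive clique enumeration over integer-coded sequences.
//
// seqs: list of integer vectors with codes 0..3 (anything else marks an
//       ambiguous base; windows touching one are dropped from the initial
//       candidate sets).
// Returns list(starts = 0-based integer matrix [cliques x m],
//              complete = logical).
// [[Rcpp::export(name = ".clique_search_cpp")]]
List clique_search_cpp(List seqs, int l, int threshold, double first_k,
                  double max_seconds) {
    int m = seqs.size();
    if (m < 2) stop("need at least two sequences");
    if (l < 1) stop("motif length must be positive");
    if (threshold < 0) stop("distance threshold must be non-negative");

    SearchCtx c;
    c.m = m;
    c.l = l;
    c.thr = threshold;
    c.first_k = R_FINITE(first_k) ? (long long)first_k : LLONG_MAX;
    if (c.first_k < 1) c.first_k = 1;
    c.deadline = max_seconds;
    c.t0 = std::chrono::steady_clock::now();
    c.timed_out = false;
    c.ticks = 0;
    c.instance.assign(m, -1);

    std::vector<IntegerVector> keep(m);   // protects the coded sequences
    std::vector<std::vector<int>> pools(m);
    for (int i = 0; i < m; ++i) {
        keep[i] = seqs[i];
        int n = keep[i].size();
        if (n < l)
            stop("sequence %d is shorter than the motif length", i + 1);
        c.seq.push_back(INTEGER(keep[i]));
        const int *s = c.seq[i];
        // initial vertex set P_{0,i}: every window free of ambiguous bases
        int bad = -1;  // rightmost invalid base seen in the current window
        for (int t = 0; t < l - 1; ++t)
            if (s[t] < 0 || s[t] > 3) bad = t;
        for (int j = 0; j + l <= n; ++j) {
            int t = j + l - 1;
            if (s[t] < 0 || s[t] > 3) bad = t;
            if (bad < j) pools[i].push_back(j);
        }
        if (pools[i].empty())
            stop("sequence %d has no valid length-l window", i + 1);
    }

    recurse(c, 0, pools);

    int nc = (int)c.out.size();
    IntegerMatrix starts(nc, m);
    for (int r = 0; r < nc; ++r)
        for (int k = 0; k < m; ++k) starts(r, k) = c.out[r][k];
    return List::create(_["starts"] = starts,
                        _["complete"] = !c.timed_out);
}
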