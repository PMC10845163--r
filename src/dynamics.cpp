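#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Shared helper: fill succ[s] = tau(s) for the threshold rule.
// Wl is the n x n trit matrix flattened row-major: entry (i,j) = Wl[i*n + j],
// the sign of the edge from node i to node j.  Bit i of a state is node i
// (LSB-first).  A node becomes active iff its signed input sum is > 0.
// Enumerates states in Gray-code order so each step toggles a single node
// and the n input sums update in O(n), giving O(N n) per network.
static void build_succ_signed(const int *Wl, int n, int N, int *succ,
                              int *sums) {
    for (int j = 0; j < n; ++j) sums[j] = 0;
    succ[0] = 0;                            // zero sums, strict threshold
    int state = 0;
    for (int t = 1; t < N; ++t) {
        int g = t ^ (t >> 1);
        int b = 0;
        { int d = g ^ state; while (!((d >> b) & 1)) ++b; }
        const int *row = Wl + b * n;
        if ((g >> b) & 1)
            for (int j = 0; j < n; ++j) sums[j] += row[j];
        else
            for (int j = 0; j < n; ++j) sums[j] -= row[j];
        state = g;
        int out = 0;
        for (int j = 0; j < n; ++j)
            if (sums[j] > 0) out |= (1 << j);
        succ[g] = out;
    }
}

// [[Rcpp::export]]
IntegerVector tm_signed_cpp(IntegerMatrix W) {
    int n = W.nrow();
    if (n != W.ncol()) stop("W must be square");
    if (n > 30) stop("state space too large for a materialized map");
    int N = 1 << n;
    std::vector<int> Wl(n * n);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j) Wl[i * n + j] = W(i, j);
    IntegerVector succ(N);
    std::vector<int> sums(n);
    build_succ_signed(Wl.data(), n, N, INTEGER(succ), sums.data());
    return succ;
}

// Cycles and basins of a functional graph by iterative pointer chasing
// (no recursion; O(N) total work).  succ holds 0-based states.
// [[Rcpp::export]]
List attractors_cpp(IntegerVector succ) {
    R_xlen_t N = succ.size();
    std::vector<int> color(N, -1);          // cycle id once resolved
    std::vector<R_xlen_t> mark(N, -1);      // id of the walk that visited
    std::vector<std::vector<int> > cyc;
    for (R_xlen_t s0 = 0; s0 < N; ++s0) {
        if (color[s0] != -1) continue;
        R_xlen_t s = s0;
        while (color[s] == -1 && mark[s] != s0) {
            mark[s] = s0;
            s = succ[s];
        }
        if (color[s] == -1) {               // closed a brand-new cycle at s
            int cid = (int)cyc.size();
            cyc.push_back(std::vector<int>());
            R_xlen_t t = s;
            do {
                cyc[cid].push_back((int)t);
                color[t] = cid;
                t = succ[t];
            } while (t != s);
        }
        int cid = color[s];
        R_xlen_t t = s0;
        while (color[t] == -1) {            // resolve the tail
            color[t] = cid;
            t = succ[t];
        }
    }
    int ncyc = (int)cyc.size();
    IntegerVector basin(ncyc);
    for (R_xlen_t s = 0; s < N; ++s) basin[color[s]]++;
    List cycles(ncyc);
    for (int c = 0; c < ncyc; ++c) cycles[c] = wrap(cyc[c]);
    return List::create(_["cycles"] = cycles, _["basin_size"] = basin);
}

// Longest cycle length of the functional graph for each network in a batch.
// Wb: one network per row, n*n trits row-major (source node = row of W).
// [[Rcpp::export]]
IntegerVector batch_max_cycle_cpp(IntegerMatrix Wb, int n) {
    int m = Wb.nrow();
    if (Wb.ncol() != n * n) stop("each row must hold n*n entries");
    if (n > 22) stop("n too large for batch evaluation");
    int N = 1 << n;
    std::vector<int> succ(N), Wl(n * n), sums(n);
    std::vector<int> resolved(N, -1);
    std::vector<long long> walk(N, -1);
    std::vector<int> pos(N, 0);
    long long tag = 0;
    IntegerVector out(m);
    for (int g = 0; g < m; ++g) {
        for (int p = 0; p < n * n; ++p) Wl[p] = Wb(g, p);
        build_succ_signed(Wl.data(), n, N, succ.data(), sums.data());
        int best = 1;
        for (int s0 = 0; s0 < N; ++s0) {
            if (resolved[s0] == g) continue;
            ++tag;
            int s = s0, p = 0;
            while (resolved[s] != g && walk[s] != tag) {
                walk[s] = tag;
                pos[s] = p++;
                s = succ[s];
            }
            if (walk[s] == tag) {           // new cycle on this walk
                int len = p - pos[s];
                if (len > best) best = len;
            }
            s = s0;
            while (resolved[s] != g) {
                resolved[s] = g;
                s = succ[s];
            }
        }
        out[g] = best;
    }
    return out;
}

// Count of fully reflection-symmetric states, tau(~x) == ~tau(x), for each
// network in a batch (same layout as batch_max_cycle_cpp).
// [[Rcpp::export]]
IntegerVector batch_full_sym_cpp(IntegerMatrix Wb, int n) {
    int m = Wb.nrow();
    if (Wb.ncol() != n * n) stop("each row must hold n*n entries");
    if (n > 22) stop("n too large for batch evaluation");
    int N = 1 << n;
    int mask = N - 1;
    std::vector<int> succ(N), Wl(n * n), sums(n);
    IntegerVector out(m);
    for (int g = 0; g < m; ++g) {
        for (int p = 0; p < n * n; ++p) Wl[p] = Wb(g, p);
        build_succ_signed(Wl.data(), n, N, succ.data(), sums.data());
        int cnt = 0;
        for (int s = 0; s < N; ++s)
            if (succ[mask ^ s] == (mask ^ succ[s])) ++cnt;
        out[g] = cnt;
    }
    return out;
}
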